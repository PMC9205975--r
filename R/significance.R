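#' Derive a reproducible per-pair seed
#'
#' Hashes a master seed together with the source and target gene names into a
#' 31-bit integer seed. Whole-matrix transfer-entropy runs use this so that
#' each pair's permutation null is reproducible on its own, independent of the
#' order in which pairs are computed (and hence of any parallel scheduling).
#'
#' @param master_seed Integer master seed for the whole run.
#' @param source,target Gene names (character scalars).
#' @return An integer in `[0, 2^31 - 1)`.
#' @export
pair_seed <- function(master_seed, source, target) {
  stopifnot(length(source) == 1L, length(target) == 1L)
  mod <- 2147483647
  h <- as.numeric(master_seed) %% mod
  for (code in utf8ToInt(paste(source, target, sep = "\t"))) {
    h <- (h * 31 + code) %% mod
  }
  as.integer(h)
}

# Run fn() under a temporary RNG state seeded with `seed`, restoring the
# caller's RNG afterwards so package functions never disturb user randomness.
with_local_seed <- function(seed, fn) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  fn()
}

#' Permutation p-value for a directed transfer-entropy score
#'
#' Builds a null distribution for the transfer entropy from `source` to
#' `target` by randomly permuting the source series while leaving the target
#' untouched. Shuffling destroys any cross-series coupling but preserves the
#' target's autocorrelation through its own history term, so the null measures
#' exactly the directed dependence of interest. The p-value uses the add-one
#' rule \eqn{p = (1 + \#\{T_{perm} \ge T_{obs}\}) / (1 + n_{perm})}, which is
#' never exactly zero.
#'
#' @inheritParams transfer_entropy
#' @param n_permutations Number of source shuffles (default 1000).
#' @param seed Integer seed; identical inputs and seed give identical results.
#' @return A one-row tibble: `observed_te`, `p_value`, `n_permutations`,
#'   `seed`.
#' @examples
#' set.seed(42)
#' permutation_pvalue(rnorm(50), rnorm(50), n_permutations = 99, seed = 7)
#' @export
permutation_pvalue <- function(source, target, n_permutations = 1000,
                               seed = 1, k = 1, l = 1, n_bins = 8, base = 2) {
  n_permutations <- as.integer(n_permutations)
  if (is.na(n_permutations) || n_permutations < 1L) {
    stop("`n_permutations` must be >= 1.", call. = FALSE)
  }
  k <- as.integer(k)
  l <- as.integer(l)
  # Validate and discretize once; permutations act on the source symbols.
  te_prepare(source, target, k, l, n_bins) # validation side effects
  sx <- discretize_series(target, n_bins)
  sy <- discretize_series(source, n_bins)
  observed <- te_symbols(sx, sy, k, l, n_bins, base)
  exceed <- with_local_seed(seed, function() {
    sum(vapply(seq_len(n_permutations), function(i) {
      te_symbols(sx, sample(sy), k, l, n_bins, base)
    }, numeric(1)) >= observed)
  })
  tibble(
    observed_te = observed,
    p_value = (1 + exceed) / (1 + n_permutations),
    n_permutations = n_permutations,
    seed = as.integer(seed)
  )
}

# TE from already-discretized symbol vectors (shared by observed and
# permuted computations so both use the identical estimator).
te_symbols <- function(sx, sy, k, l, n_bins, base) {
  codes <- align_codes(sx, sy, k, l, n_bins)
  te_from_codes(codes$f, codes$xh, codes$yh, n_bins, k, l, base)
}
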