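#' Number of ordered gene pairs
#'
#' Transfer entropy is asymmetric, so both directions of every gene pair must
#' be computed: `n` genes give \eqn{m = n (n - 1) = n^2 - n} ordered pairs.
#'
#' @param n_genes Number of genes, `>= 2`.
#' @return Integer pair count.
#' @examples
#' pair_count(124) # 15252
#' @export
pair_count <- function(n_genes) {
  n_genes <- as.integer(n_genes)
  if (is.na(n_genes) || n_genes < 2L) {
    stop("`n_genes` must be >= 2.", call. = FALSE)
  }
  n_genes * (n_genes - 1L)
}

#' Transfer entropy and significance for every ordered gene pair
#'
#' Computes the directed transfer entropy, and optionally a permutation
#' p-value, for all `n (n - 1)` ordered pairs of genes in an expression
#' table. Each gene is discretized once; each pair's permutation null uses a
#' seed derived from the master seed and the two gene names (see
#' [pair_seed()]), so every entry is reproducible in isolation and the whole
#' matrix is identical regardless of computation order.
#'
#' @param df Expression table (gene column first, `>= 2` genes, equal-length
#'   series).
#' @inheritParams transfer_entropy
#' @param n_permutations Permutations per pair for the p-value; `0` skips
#'   significance testing (`p_value` becomes `NA`).
#' @param seed Master seed for all permutation nulls.
#' @return A tibble with one row per ordered pair: `source`, `target`, `te`
#'   (bits), `p_value`.
#' @export
all_pairs_te <- function(df, k = 1, l = 1, n_bins = 8, base = 2,
                         n_permutations = 1000, seed = 1) {
  m <- expr_matrix(df)
  if (nrow(m) < 2L) stop("Need at least 2 genes.", call. = FALSE)
  genes <- rownames(m)
  k <- as.integer(k)
  l <- as.integer(l)
  symbols <- lapply(seq_len(nrow(m)), function(i) {
    discretize_series(m[i, ], n_bins)
  })
  pairs <- tidyr::expand_grid(source = genes, target = genes) |>
    dplyr::filter(.data$source != .data$target)
  res <- purrr::pmap_dfr(pairs, function(source, target) {
    sy <- symbols[[match(source, genes)]]
    sx <- symbols[[match(target, genes)]]
    te <- te_symbols(sx, sy, k, l, n_bins, base)
    if (n_permutations > 0L) {
      ps <- pair_seed(seed, source, target)
      exceed <- with_local_seed(ps, function() {
        sum(vapply(seq_len(n_permutations), function(i) {
          te_symbols(sx, sample(sy), k, l, n_bins, base)
        }, numeric(1)) >= te)
      })
      p <- (1 + exceed) / (1 + n_permutations)
    } else {
      p <- NA_real_
    }
    tibble(source = source, target = target, te = te, p_value = p)
  })
  res
}

tag_stage <- function(edges, stage) {
  edges$stage <- stage
  edges
}

#' Keep the dominant direction of each gene pair
#'
#' For every unordered gene pair, retains only the direction with the larger
#' transfer entropy — the direction of net information flow, which by the
#' asymmetry of transfer entropy identifies the driver. Exact ties keep the
#' edge whose `(source, target)` sorts first lexicographically, so the result
#' is deterministic. The output always has exactly `n (n - 1) / 2` edges.
#'
#' @param te_tbl Tibble of all ordered pairs (`source`, `target`, `te`,
#'   optionally `p_value`), as from [all_pairs_te()].
#' @return Edge tibble tagged with `stage = "one_way"`.
#' @export
one_way_screen <- function(te_tbl) {
  te_tbl |>
    dplyr::mutate(
      pair_lo = pmin(.data$source, .data$target),
      pair_hi = pmax(.data$source, .data$target)
    ) |>
    dplyr::group_by(.data$pair_lo, .data$pair_hi) |>
    dplyr::arrange(dplyr::desc(.data$te), .data$source, .data$target,
                   .by_group = TRUE) |>
    dplyr::slice(1L) |>
    dplyr::ungroup() |>
    dplyr::select(-"pair_lo", -"pair_hi") |>
    dplyr::arrange(.data$source, .data$target) |>
    tag_stage("one_way")
}

#' Keep edges with significant information transfer
#'
#' Retains edges whose permutation p-value is strictly below `alpha`
#' (default 0.001), keeping only regulatory relationships with highly
#' significant information transfer.
#'
#' @param edges Edge tibble carrying a `p_value` column.
#' @param alpha Significance level; the comparison is strict (`p < alpha`).
#' @return Filtered edge tibble tagged `stage = "pvalue"`.
#' @export
pvalue_screen <- function(edges, alpha = 0.001) {
  if (!"p_value" %in% names(edges)) {
    stop("Edges carry no `p_value` column.", call. = FALSE)
  }
  tag_stage(dplyr::filter(edges, .data$p_value < alpha), "pvalue")
}

#' Keep edges with strong information transfer
#'
#' Retains edges whose transfer entropy is at least `min_te` (inclusive).
#' The default threshold is 0.5 bits; thresholds here are on the log2 scale
#' used throughout the package.
#'
#' @param edges Edge tibble.
#' @param min_te Inclusive lower bound on `te`.
#' @return Filtered edge tibble tagged `stage = "te_threshold"`.
#' @export
te_threshold_screen <- function(edges, min_te = 0.5) {
  tag_stage(dplyr::filter(edges, .data$te >= min_te), "te_threshold")
}

#' Strongest outgoing edge of each gene
#'
#' Reduces an edge list to at most one edge per source gene: its
#' maximum-transfer-entropy outgoing edge (ties broken lexicographically by
#' target). This isolates each gene's dominant regulatory influence.
#'
#' @param edges Edge tibble.
#' @return Edge tibble tagged `stage = "strongest_out"`.
#' @export
strongest_per_source <- function(edges) {
  edges |>
    dplyr::group_by(.data$source) |>
    dplyr::arrange(dplyr::desc(.data$te), .data$target, .by_group = TRUE) |>
    dplyr::slice(1L) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$source, .data$target) |>
    tag_stage("strongest_out")
}

#' Strongest incoming edge of each gene
#'
#' Mirror of [strongest_per_source()]: keeps, for each target gene, its
#' maximum-transfer-entropy incoming edge (ties broken lexicographically by
#' source), isolating each gene's dominant regulator.
#'
#' @param edges Edge tibble.
#' @return Edge tibble tagged `stage = "strongest_in"`.
#' @export
strongest_per_target <- function(edges) {
  edges |>
    dplyr::group_by(.data$target) |>
    dplyr::arrange(dplyr::desc(.data$te), .data$source, .by_group = TRUE) |>
    dplyr::slice(1L) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$source, .data$target) |>
    tag_stage("strongest_in")
}
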