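# Independent oracles used across the suite. These deliberately avoid the
# package's internal code paths: probabilities are estimated by explicit
# enumeration over all symbol combinations.

# Brute-force transfer entropy for integer symbol series (values 0..B-1),
# k = l = 1: enumerate every (x_{n+1}, x_n, y_n) cell, estimate each
# probability by direct relative frequency over the aligned tuples, and sum
# p(x1,x0,y0) * log2( p(x1,x0,y0) p(x0) / (p(x1,x0) p(x0,y0)) ).
brute_te <- function(source_sym, target_sym, n_bins) {
  n <- length(target_sym)
  f <- target_sym[2:n]
  xh <- target_sym[1:(n - 1)]
  yh <- source_sym[1:(n - 1)]
  total <- 0
  for (b1 in 0:(n_bins - 1)) {
    for (b2 in 0:(n_bins - 1)) {
      for (b3 in 0:(n_bins - 1)) {
        p_joint <- mean(f == b1 & xh == b2 & yh == b3)
        if (p_joint == 0) next
        p_xh <- mean(xh == b2)
        p_fxh <- mean(f == b1 & xh == b2)
        p_xhyh <- mean(xh == b2 & yh == b3)
        total <- total + p_joint * log2(p_joint * p_xh / (p_fxh * p_xhyh))
      }
    }
  }
  total
}

# Rank-statistic AUROC: brute force over every (positive, negative) score
# pair, ties at half credit.
rank_auroc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  cmp <- outer(pos, neg, function(p, n) (p > n) + 0.5 * (p == n))
  mean(cmp)
}

# Sinusoidal expression table: one gene per row of `phases` (hours),
# sampled over 24 h at `n_time` points, plus seeded Gaussian noise.
sinusoid_expression <- function(phases, n_time = 48, noise_sd = 0.05,
                                seed = 1, genes = NULL) {
  if (is.null(genes)) genes <- sprintf("g%02d", seq_along(phases))
  hours <- seq(0, 24, length.out = n_time)
  set.seed(seed)
  vals <- t(vapply(phases, function(ph) {
    cos(2 * pi * (hours - ph) / 24) + rnorm(n_time, sd = noise_sd)
  }, numeric(n_time)))
  rownames(vals) <- genes
  colnames(vals) <- sprintf("t%02d", seq_len(n_time))
  dplyr::bind_cols(
    tibble::tibble(gene = genes),
    tibble::as_tibble(vals)
  )
}

# Small deterministic edge tibble for screening tests.
toy_edges <- function() {
  tibble::tibble(
    source  = c("A", "A", "B", "B", "C", "C", "D", "D", "E", "E"),
    target  = c("B", "C", "C", "D", "D", "E", "E", "A", "A", "B"),
    te      = c(0.9, 0.45, 0.5, 0.2, 0.75, 0.05, 0.6, 0.55, 0.3, 0.5),
    p_value = c(1e-4, 5e-3, 1e-5, 0.2, 1e-4, 0.5, 1e-3, 9e-4, 2e-4, 0.05)
  )
}
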