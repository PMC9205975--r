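#' Shannon entropy of a discrete distribution
#'
#' Computes \eqn{H = -\sum_i p_i \log_2 p_i} for a probability vector, with the
#' usual convention \eqn{0 \log 0 = 0}. Entropy quantifies the uncertainty of a
#' discrete random variable: it is zero for a degenerate distribution and
#' maximal (\eqn{\log_2} of the support size) for the uniform one.
#'
#' @param p Numeric vector of probabilities. Must be non-negative and sum to 1
#'   (within `tol`).
#' @param base Logarithm base; `2` (the default) gives bits, `exp(1)` nats.
#' @param tol Tolerance on `sum(p) == 1`.
#' @return Entropy as a single non-negative number, in units set by `base`.
#' @examples
#' shannon_entropy(c(0.5, 0.5)) # 1 bit
#' shannon_entropy(c(1))        # 0
#' @export
shannon_entropy <- function(p, base = 2, tol = 1e-8) {
  if (!is.numeric(p) || length(p) == 0L || anyNA(p)) {
    stop("`p` must be a non-empty numeric vector without NA.", call. = FALSE)
  }
  if (any(p < 0)) {
    stop("Invalid distribution: negative probability.", call. = FALSE)
  }
  if (abs(sum(p) - 1) > tol) {
    stop("Invalid distribution: probabilities sum to ", format(sum(p)),
         ", not 1.", call. = FALSE)
  }
  pos <- p[p > 0]
  -sum(pos * log(pos)) / log(base)
}

#' Discretize a numeric series into equal-width bins
#'
#' Maps a numeric time series to integer symbols `0 .. n_bins - 1` using
#' `n_bins` equal-width bins spanning `[min(x), max(x)]`. Bins are half-open on
#' the right except the top bin, whose upper edge is closed so the maximum is
#' always assigned. A constant series maps to a single symbol (0).
#'
#' @param x Numeric vector; all values must be finite.
#' @param n_bins Number of bins, an integer `>= 2`.
#' @return Integer vector of the same length with values in `[0, n_bins)`.
#' @examples
#' discretize_series(c(1, 2, 3, 4), 2) # 0 0 1 1
#' @export
discretize_series <- function(x, n_bins = 8) {
  if (length(x) == 0L) stop("Cannot discretize an empty series.", call. = FALSE)
  if (!all(is.finite(x))) stop("Series contains non-finite values.", call. = FALSE)
  n_bins <- as.integer(n_bins)
  if (is.na(n_bins) || n_bins < 2L) stop("`n_bins` must be >= 2.", call. = FALSE)
  rng <- range(x)
  if (rng[1] == rng[2]) {
    return(integer(length(x)))
  }
  breaks <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  findInterval(x, breaks, rightmost.closed = TRUE, all.inside = TRUE) - 1L
}

# Encode sliding histories of a 0-based symbol vector as base-B integers.
# Row t of embed(s, ord) is (s[t], s[t-1], ..., s[t-ord+1]) for t = ord..n,
# so codes[t - ord + 1] encodes the ord-long history ending at t.
history_codes <- function(symbols, ord, n_bins) {
  if (ord == 1L) return(symbols)
  stats::embed(symbols, ord) %*% n_bins^(0:(ord - 1L))
}

# Transfer entropy from pre-aligned symbol codes.
# f:  future target symbol in [0, B)
# xh: target-history code in [0, B^k)
# yh: source-history code in [0, B^l)
# All probabilities are read off one joint count table so the plug-in
# estimate is a true conditional mutual information, hence >= 0.
te_from_codes <- function(f, xh, yh, n_bins, k, l, base = 2) {
  bk <- n_bins^k
  bl <- n_bins^l
  code <- f + n_bins * (xh + bk * yh)
  counts <- tabulate(code + 1L, nbins = n_bins * bk * bl)
  joint <- array(counts, dim = c(n_bins, bk, bl))
  n_tuples <- length(f)

  m_fxh  <- rowSums(joint, dims = 2)          # counts over (future, target hist)
  m_xhyh <- colSums(joint)                    # counts over (target hist, source hist)
  m_xh   <- rowSums(m_xhyh)                   # counts over target hist

  nz <- which(joint > 0, arr.ind = TRUE)
  cts <- joint[nz]
  ratio <- cts * m_xh[nz[, 2L]] /
    (m_fxh[nz[, 1:2, drop = FALSE]] * m_xhyh[nz[, 2:3, drop = FALSE]])
  te <- sum(cts / n_tuples * log(ratio)) / log(base)
  max(te, 0)
}

# Validate a pair of series and return their aligned symbol codes.
te_prepare <- function(source, target, k, l, n_bins) {
  if (!is.numeric(source) || !is.numeric(target)) {
    stop("`source` and `target` must be numeric series.", call. = FALSE)
  }
  if (length(source) != length(target)) {
    stop("Series length mismatch: source has ", length(source),
         " points, target has ", length(target), ".", call. = FALSE)
  }
  if (k < 1L || l < 1L) stop("Lags `k` and `l` must be >= 1.", call. = FALSE)
  n <- length(target)
  t0 <- max(k, l)
  if (n - t0 < 1L) {
    stop("Series too short: need length > max(k, l).", call. = FALSE)
  }
  sx <- discretize_series(target, n_bins)
  sy <- discretize_series(source, n_bins)
  align_codes(sx, sy, k, l, n_bins)
}

# Align future / target-history / source-history codes for tuples
# t = max(k, l) .. n - 1 (futures at t + 1).
align_codes <- function(sx, sy, k, l, n_bins) {
  n <- length(sx)
  t0 <- max(k, l)
  ts <- t0:(n - 1L)
  xh_all <- history_codes(sx, k, n_bins)   # index t - k + 1 holds history at t
  yh_all <- history_codes(sy, l, n_bins)
  list(
    f  = sx[ts + 1L],
    xh = as.vector(xh_all)[ts - k + 1L],
    yh = as.vector(yh_all)[ts - l + 1L]
  )
}

#' Transfer entropy between two time series
#'
#' Estimates the transfer entropy from `source` to `target`: the reduction in
#' uncertainty about the target's next value obtained from the source's recent
#' past, beyond what the target's own past already provides. With history
#' lengths \eqn{k = l = 1} (a first-order Markov reduction) this is
#' \deqn{T_{source \to target} = \sum p(x_{n+1}, x_n, y_n)\,
#'   \log_2 \frac{p(x_{n+1}, x_n, y_n)\, p(x_n)}{p(x_{n+1}, x_n)\, p(x_n, y_n)}}
#' where \eqn{x} is the target and \eqn{y} the source. Probabilities are
#' plug-in estimates from an equal-width histogram discretization; all
#' marginals are derived from one joint count table, so the estimate is a
#' genuine conditional mutual information and therefore non-negative. Empty
#' cells contribute zero to the sum.
#'
#' @param source,target Numeric time series of equal length.
#' @param k Target history length (number of past target states conditioned on).
#' @param l Source history length.
#' @param n_bins Number of equal-width discretization bins (default 8).
#' @param base Logarithm base; 2 (default) yields bits.
#' @return Transfer entropy in bits (or the units of `base`), `>= 0`.
#' @examples
#' set.seed(1)
#' y <- rnorm(200)
#' x <- c(0, 0.9 * y[-200]) + rnorm(200, sd = 0.1) # y drives x at lag 1
#' transfer_entropy(y, x) > transfer_entropy(x, y)
#' @export
transfer_entropy <- function(source, target, k = 1, l = 1, n_bins = 8,
                             base = 2) {
  k <- as.integer(k)
  l <- as.integer(l)
  codes <- te_prepare(source, target, k, l, n_bins)
  te_from_codes(codes$f, codes$xh, codes$yh, n_bins, k, l, base)
}

#' Net information flow between two series
#'
#' The difference \eqn{T_{y \to x} - T_{x \to y}} of the two directed transfer
#' entropies. A positive value means information flows from `y` to `x` (`y`
#' drives `x`); negative means the reverse; zero leaves the pair undirected.
#' The quantity is antisymmetric under swapping the two series.
#'
#' @param te_y_to_x,te_x_to_y Directed transfer entropies in bits.
#' @return A one-row tibble with `net_flow` (bits, signed) and `direction`
#'   (`"y->x"`, `"x->y"`, or `"none"`).
#' @examples
#' net_information_flow(0.3, 0.1) # flow y->x, +0.2 bits
#' @export
net_information_flow <- function(te_y_to_x, te_x_to_y) {
  stopifnot(is.numeric(te_y_to_x), is.numeric(te_x_to_y),
            length(te_y_to_x) == 1L, length(te_x_to_y) == 1L)
  net <- te_y_to_x - te_x_to_y
  tibble(
    net_flow = net,
    direction = if (net > 0) "y->x" else if (net < 0) "x->y" else "none"
  )
}
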