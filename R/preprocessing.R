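#' Centered moving-average smoothing of a series
#'
#' Replaces each point by the mean of the window of `window` values centered
#' on it: \eqn{F_t = (A_{t-n} + \dots + A_t + \dots + A_{t+n}) / (2n + 1)}.
#' Raw expression time courses carry sporadic outliers from sampling and
#' measurement; a short centered window suppresses them while preserving the
#' underlying trend. Output length equals input length.
#'
#' Boundary handling, where the full window does not fit:
#' * `"shrink"` (default): average only the in-range neighbors, so the first
#'   point of a window-5 smooth is the mean of points 1..3.
#' * `"reflect"`: mirror the series about its endpoints before averaging.
#'
#' @param x Numeric vector.
#' @param window Odd integer window size `>= 1`, at most `length(x)`.
#' @param boundary `"shrink"` or `"reflect"`.
#' @return Numeric vector, same length as `x`.
#' @examples
#' moving_average(c(1, 2, 3, 4, 5), window = 5)
#' @export
moving_average <- function(x, window = 5, boundary = c("shrink", "reflect")) {
  boundary <- match.arg(boundary)
  window <- as.integer(window)
  if (is.na(window) || window < 1L || window %% 2L == 0L) {
    stop("`window` must be an odd integer >= 1.", call. = FALSE)
  }
  n <- length(x)
  if (window > n) stop("`window` exceeds series length.", call. = FALSE)
  if (window == 1L) return(as.numeric(x))
  h <- (window - 1L) %/% 2L
  if (boundary == "reflect") {
    padded <- c(x[(h + 1L):2L], x, x[(n - 1L):(n - h)])
    cs <- c(0, cumsum(padded))
    return((cs[(1L:n) + 2L * h + 1L] - cs[1L:n]) / window)
  }
  # shrink: divisor is the count of in-range neighbors
  cs <- c(0, cumsum(x))
  lo <- pmax(1L, seq_len(n) - h)
  hi <- pmin(n, seq_len(n) + h)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Smooth every gene in an expression table
#'
#' Applies [moving_average()] to each gene's time course. The default window
#' of 5 points suits densely sampled series where outliers span single time
#' points.
#'
#' @param df Expression table: first column gene names, remaining columns
#'   ordered numeric time points.
#' @inheritParams moving_average
#' @return A tibble of the same shape with smoothed values.
#' @export
smooth_expression <- function(df, window = 5,
                              boundary = c("shrink", "reflect")) {
  boundary <- match.arg(boundary)
  m <- expr_matrix(df)
  sm <- t(apply(m, 1L, moving_average, window = window, boundary = boundary))
  dimnames(sm) <- dimnames(m)
  out <- matrix_to_expr(sm)
  names(out)[1L] <- names(df)[1L]
  out
}

#' Drop genes with flat, uninformative expression
#'
#' Removes genes whose temporal standard deviation is at or below `min_sd`
#' (default 0, i.e. exactly constant profiles). Constant genes carry no
#' temporal information, break z-scoring and cosine similarity, and can only
#' contribute spurious zero-entropy pairs downstream.
#'
#' The removed genes are reported in the `removed` attribute of the result,
#' a tibble with columns `gene`, `sd`, `reason`.
#'
#' @param df Expression table (gene column first).
#' @param min_sd Genes with `sd <= min_sd` are removed.
#' @return The filtered tibble; `attr(, "removed")` lists the removals.
#'   Warns (rather than failing silently) if every gene is removed.
#' @export
filter_flat_genes <- function(df, min_sd = 0) {
  m <- expr_matrix(df)
  sds <- apply(m, 1L, sd)
  drop <- sds <= min_sd
  removed <- tibble(
    gene = rownames(m)[drop],
    sd = unname(sds[drop]),
    reason = unname(ifelse(sds[drop] == 0, "constant expression",
                           paste0("sd <= ", format(min_sd))))
  )
  out <- as_tibble(df[!drop, , drop = FALSE])
  if (nrow(out) == 0L) {
    warning("All genes removed by the variance filter (min_sd = ",
            format(min_sd), ").", call. = FALSE)
  }
  attr(out, "removed") <- removed
  out
}
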