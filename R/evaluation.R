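#' Read a gold-standard directed edge list
#'
#' Parses the tab-separated gold-standard dialect used by the DREAM network
#' challenges: one line per pair, `regulator TAB target TAB label` with label
#' 0 or 1. If a `universe` of gene names is supplied, every ordered non-self
#' pair absent from the file is added with label 0; without a universe,
#' absent pairs stay unknown.
#'
#' @param path Path to the TSV file (no header).
#' @param universe Optional character vector of gene names spanning the
#'   evaluation universe.
#' @return Tibble (`regulator`, `target`, `label`) of unique directed pairs;
#'   the universe (if any) is kept in the `universe` attribute.
#' @export
read_gold_standard <- function(path, universe = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) != 3L)
  if (length(bad)) {
    stop("Malformed gold-standard line ", bad[1L], " in '", path,
         "': expected 'regulator<TAB>target<TAB>{0,1}'.", call. = FALSE)
  }
  gold <- tibble(
    regulator = vapply(parts, `[[`, character(1), 1L),
    target = vapply(parts, `[[`, character(1), 2L),
    label = vapply(parts, `[[`, character(1), 3L)
  )
  if (length(lines) && !all(gold$label %in% c("0", "1"))) {
    bad <- which(!gold$label %in% c("0", "1"))[1L]
    stop("Malformed gold-standard line ", bad, " in '", path,
         "': label must be 0 or 1.", call. = FALSE)
  }
  gold$label <- as.integer(gold$label)
  if (any(gold$regulator == gold$target)) {
    stop("Gold standard contains self-loops.", call. = FALSE)
  }
  if (anyDuplicated(gold[c("regulator", "target")])) {
    stop("Gold standard contains duplicate pairs.", call. = FALSE)
  }
  if (!is.null(universe)) {
    all_pairs <- tidyr::expand_grid(regulator = universe, target = universe) |>
      dplyr::filter(.data$regulator != .data$target)
    gold <- all_pairs |>
      dplyr::left_join(gold, by = c("regulator", "target")) |>
      dplyr::mutate(label = dplyr::coalesce(.data$label, 0L))
    attr(gold, "universe") <- universe
  }
  gold
}

# Join predicted scores onto gold labels over the directed non-self universe.
# Gold pairs never scored by the predictor are ranked last (score -Inf) with
# a coverage warning; scored pairs without a gold label are an error.
resolve_scores <- function(scores, gold) {
  stopifnot(all(c("source", "target") %in% names(scores)))
  score_col <- if ("te" %in% names(scores)) "te" else "score"
  if (!score_col %in% names(scores)) {
    stop("Scores must carry a `te` or `score` column.", call. = FALSE)
  }
  scored <- scores |>
    dplyr::filter(.data$source != .data$target) |>
    dplyr::transmute(regulator = .data$source, target = .data$target,
                     score = .data[[score_col]])
  merged <- gold |>
    dplyr::left_join(scored, by = c("regulator", "target"))
  unresolved <- dplyr::anti_join(scored, gold, by = c("regulator", "target"))
  if (nrow(unresolved)) {
    stop("Scored pair without a gold label: ",
         unresolved$regulator[1L], " -> ", unresolved$target[1L],
         ". Supply a gene universe when reading the gold standard.",
         call. = FALSE)
  }
  n_missing <- sum(is.na(merged$score))
  if (n_missing > 0L) {
    warning(n_missing, " gold pair(s) not scored by the predictor; ",
            "ranked last (score -Inf).", call. = FALSE)
    merged$score[is.na(merged$score)] <- -Inf
  }
  merged
}

#' ROC and precision-recall evaluation of a predicted network
#'
#' Sweeps a threshold over the predicted edge scores against a gold-standard
#' directed edge list and computes the ROC and precision-recall curves plus
#' their areas. Identical scores are grouped into a single threshold step, so
#' tied positives and negatives receive half credit; AUROC from this sweep
#' (trapezoidal integration) equals the rank statistic
#' \eqn{P(S_{pos} > S_{neg}) + \frac{1}{2} P(S_{pos} = S_{neg})}. AUPRC is
#' the trapezoidal area under the precision-recall points of the same sweep.
#'
#' @param scores Edge tibble (`source`, `target`, and a `te` or `score`
#'   column), e.g. from [all_pairs_te()] or any screening stage.
#' @param gold Gold-standard tibble from [read_gold_standard()] (or any data
#'   frame with `regulator`, `target`, `label`). Must contain at least one
#'   positive and one negative pair.
#' @return A `grn_benchmark` object: `auroc`, `auprc`, `n_pos`, `n_neg`, and
#'   `curve` — a tibble of threshold sweep points (`threshold`, `tp`, `fp`,
#'   `tpr`, `fpr`, `precision`, `recall`). Use [tidy()] for the curve,
#'   [glance()] for the summary row, [autoplot()] to plot both curves.
#' @export
benchmark_network <- function(scores, gold) {
  merged <- resolve_scores(scores, gold)
  n_pos <- sum(merged$label == 1L)
  n_neg <- sum(merged$label == 0L)
  if (n_pos == 0L || n_neg == 0L) {
    stop("Undefined metric: gold standard has ", n_pos, " positive and ",
         n_neg, " negative pairs.", call. = FALSE)
  }
  by_score <- merged |>
    dplyr::group_by(.data$score) |>
    dplyr::summarise(pos = sum(.data$label == 1L),
                     neg = sum(.data$label == 0L)) |>
    dplyr::arrange(dplyr::desc(.data$score))
  curve <- by_score |>
    dplyr::mutate(
      tp = cumsum(.data$pos),
      fp = cumsum(.data$neg),
      tpr = .data$tp / n_pos,
      fpr = .data$fp / n_neg,
      precision = .data$tp / (.data$tp + .data$fp),
      recall = .data$tpr
    ) |>
    dplyr::transmute(threshold = .data$score, tp = .data$tp, fp = .data$fp,
                     tpr = .data$tpr, fpr = .data$fpr,
                     precision = .data$precision, recall = .data$recall)
  auroc <- trapezoid(c(0, curve$fpr), c(0, curve$tpr))
  auprc <- trapezoid(c(0, curve$recall), c(curve$precision[1L],
                                           curve$precision))
  structure(
    list(auroc = auroc, auprc = auprc, n_pos = n_pos, n_neg = n_neg,
         curve = curve),
    class = "grn_benchmark"
  )
}

trapezoid <- function(x, y) {
  sum(diff(x) * (head(y, -1) + y[-1]) / 2)
}

#' @export
print.grn_benchmark <- function(x, ...) {
  cat("Network benchmark:", x$n_pos, "positive /", x$n_neg,
      "negative pairs\n")
  cat(sprintf("  AUROC: %.4f\n  AUPRC: %.4f\n", x$auroc, x$auprc))
  invisible(x)
}

#' @rdname benchmark_network
#' @param x A `grn_benchmark` object.
#' @param ... Unused.
#' @export
tidy.grn_benchmark <- function(x, ...) {
  x$curve
}

#' @rdname benchmark_network
#' @export
glance.grn_benchmark <- function(x, ...) {
  tibble(auroc = x$auroc, auprc = x$auprc, n_pos = x$n_pos, n_neg = x$n_neg)
}

#' Confusion-matrix metrics at a fixed score threshold
#'
#' Classifies every resolvable directed pair as predicted-positive when its
#' score is at least `threshold`, tallies the confusion matrix against the
#' gold labels, and reports positive predictive value
#' \eqn{PPV = TP / (TP + FP)} and sensitivity \eqn{Se = TP / (TP + FN)}.
#' Metrics whose denominator is zero are returned as `NA` with a warning.
#'
#' @inheritParams benchmark_network
#' @param threshold Score threshold (inclusive) for calling an edge.
#' @return One-row tibble: `tp`, `fp`, `fn`, `tn`, `ppv`, `sensitivity`.
#' @export
confusion_at_threshold <- function(scores, gold, threshold) {
  merged <- resolve_scores(scores, gold)
  pred <- merged$score >= threshold
  tp <- sum(pred & merged$label == 1L)
  fp <- sum(pred & merged$label == 0L)
  fn <- sum(!pred & merged$label == 1L)
  tn <- sum(!pred & merged$label == 0L)
  ppv <- if (tp + fp > 0L) tp / (tp + fp) else NA_real_
  se <- if (tp + fn > 0L) tp / (tp + fn) else NA_real_
  if (is.na(ppv)) {
    warning("PPV undefined: no predicted positives at threshold ",
            format(threshold), ".", call. = FALSE)
  }
  if (is.na(se)) {
    warning("Sensitivity undefined: gold standard has no positives.",
            call. = FALSE)
  }
  tibble(tp = tp, fp = fp, fn = fn, tn = tn, ppv = ppv, sensitivity = se)
}
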