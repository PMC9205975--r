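# Internal helpers for the expression-table representation: a tibble whose
# first column (`gene`) holds unique gene names and whose remaining columns
# are ordered numeric time points.

validate_expression <- function(df, arg = "expression table") {
  if (!is.data.frame(df) || ncol(df) < 2L || nrow(df) < 1L) {
    stop(arg, " must be a data frame with a gene column and >= 1 time column.",
         call. = FALSE)
  }
  genes <- df[[1L]]
  if (anyDuplicated(genes)) {
    dup <- genes[duplicated(genes)][1L]
    stop("Duplicate gene name: ", dup, call. = FALSE)
  }
  vals <- df[-1L]
  bad <- which(!vapply(vals, is.numeric, logical(1)))
  if (length(bad)) {
    stop("Non-numeric time-point column: ", names(vals)[bad[1L]],
         call. = FALSE)
  }
  invisible(df)
}

# genes x time numeric matrix with gene rownames
expr_matrix <- function(df) {
  validate_expression(df)
  m <- as.matrix(df[-1L])
  rownames(m) <- as.character(df[[1L]])
  m
}

matrix_to_expr <- function(m, time_names = colnames(m)) {
  out <- as_tibble(m, .name_repair = "minimal")
  if (!is.null(time_names)) names(out) <- time_names
  dplyr::bind_cols(tibble(gene = rownames(m)), out)
}
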