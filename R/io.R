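#' Read a gene expression time-series matrix
#'
#' Reads a TSV whose first column holds gene identifiers and whose remaining
#' columns are ordered time points. Column order in the file is preserved as
#' temporal order.
#'
#' @param path TSV file path (with header row).
#' @return Tibble with first column `gene` and numeric time columns.
#' @export
read_expression_matrix <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (ncol(df) < 2L) {
    stop("Expression file needs a gene column plus >= 1 time column.",
         call. = FALSE)
  }
  names(df)[1L] <- "gene"
  df$gene <- as.character(df$gene)
  dup <- which(duplicated(df$gene))
  if (length(dup)) {
    stop("Duplicate gene name '", df$gene[dup[1L]], "' at row ", dup[1L],
         " of '", path, "'.", call. = FALSE)
  }
  for (j in 2:ncol(df)) {
    if (!is.numeric(df[[j]])) {
      bad_row <- which(is.na(suppressWarnings(as.numeric(df[[j]]))))[1L]
      stop("Non-numeric expression value at row ",
           ifelse(is.na(bad_row), 1L, bad_row), ", column '", names(df)[j],
           "' of '", path, "'.", call. = FALSE)
    }
  }
  df
}

#' Write a gene expression matrix as TSV
#'
#' @param df Expression table (gene column first).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(df, path) {
  validate_expression(df)
  readr::write_tsv(df, path, progress = FALSE)
  invisible(path)
}

#' Pipeline configuration
#'
#' Bundles every tunable of the inference pipeline with its default:
#' discretization bins and history lengths for transfer entropy, log base,
#' smoothing window and boundary policy, the variance filter, clustering
#' parameters, the screening thresholds, the permutation count, and the
#' master seed.
#'
#' @param n_bins Discretization bins for transfer entropy (default 8).
#' @param k,l Target / source history lengths (default 1, first-order
#'   Markov).
#' @param base Logarithm base (default 2: bits).
#' @param window Smoothing window size (odd, default 5).
#' @param boundary Smoothing boundary policy, `"shrink"` or `"reflect"`.
#' @param min_sd Variance-filter threshold (default 0).
#' @param n_clusters Clusters for both pattern clusterings (default 12).
#' @param fuzzifier Fuzzy c-means fuzziness exponent (default 2).
#' @param alpha Strict p-value cutoff (default 0.001).
#' @param min_te Inclusive transfer-entropy cutoff in bits (default 0.5).
#' @param n_permutations Permutations per pair (default 1000).
#' @param seed Master seed (default 1).
#' @return A named list of class `run_config`.
#' @export
run_config <- function(n_bins = 8, k = 1, l = 1, base = 2, window = 5,
                       boundary = "shrink", min_sd = 0, n_clusters = 12,
                       fuzzifier = 2, alpha = 0.001, min_te = 0.5,
                       n_permutations = 1000, seed = 1) {
  structure(
    list(n_bins = n_bins, k = k, l = l, base = base, window = window,
         boundary = boundary, min_sd = min_sd, n_clusters = n_clusters,
         fuzzifier = fuzzifier, alpha = alpha, min_te = min_te,
         n_permutations = n_permutations, seed = seed),
    class = "run_config"
  )
}

#' Write a pipeline configuration as a flat key=value file
#'
#' @param config A [run_config()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  writeLines(paste0(names(config), "=",
                    vapply(config, format, character(1))), path)
  invisible(path)
}

#' Read a pipeline configuration written by [write_run_config()]
#'
#' Unknown keys are rejected; missing keys take their defaults, so a partial
#' file is valid and the loaded configuration is always fully populated.
#'
#' @param path Config file path.
#' @return A [run_config()].
#' @export
read_run_config <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  kv <- strsplit(lines, "=", fixed = TRUE)
  bad <- which(lengths(kv) != 2L)
  if (length(bad)) {
    stop("Malformed config line ", bad[1L], " in '", path, "'.",
         call. = FALSE)
  }
  keys <- trimws(vapply(kv, `[[`, character(1), 1L))
  vals <- trimws(vapply(kv, `[[`, character(1), 2L))
  defaults <- run_config()
  unknown <- setdiff(keys, names(defaults))
  if (length(unknown)) {
    stop("Unknown config key: ", unknown[1L], call. = FALSE)
  }
  out <- defaults
  for (i in seq_along(keys)) {
    out[[keys[i]]] <- if (keys[i] == "boundary") {
      vals[i]
    } else {
      as.numeric(vals[i])
    }
  }
  out
}
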