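#' Build a directed graph from a screened edge list
#'
#' Converts an edge tibble into an [igraph][igraph::graph_from_data_frame]
#' directed graph whose node set is exactly the genes incident to at least
#' one edge. Edge attributes (`te`, `p_value`, `stage`) are carried over.
#'
#' @param edges Edge tibble (`source`, `target`, `te`, ...). Self-loops and
#'   duplicate `(source, target)` rows are rejected.
#' @return An `igraph` directed graph.
#' @export
build_network <- function(edges) {
  stopifnot(all(c("source", "target") %in% names(edges)))
  if (any(edges$source == edges$target)) {
    stop("Edge list contains self-loops.", call. = FALSE)
  }
  if (anyDuplicated(edges[c("source", "target")])) {
    stop("Edge list contains duplicate (source, target) pairs.",
         call. = FALSE)
  }
  igraph::graph_from_data_frame(edges, directed = TRUE)
}

#' Write an edge list in Cytoscape SIF format
#'
#' One line per edge: `source TAB TE TAB target`, loadable directly by
#' Cytoscape. An empty edge list produces a valid empty file.
#'
#' @param edges Edge tibble.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_sif <- function(edges, path) {
  lines <- if (nrow(edges)) {
    paste(edges$source, "TE", edges$target, sep = "\t")
  } else {
    character(0)
  }
  tryCatch(
    writeLines(lines, path),
    error = function(e) {
      stop("Failed to write SIF file '", path, "': ", conditionMessage(e),
           call. = FALSE)
    },
    warning = function(w) {
      stop("Failed to write SIF file '", path, "': ", conditionMessage(w),
           call. = FALSE)
    }
  )
  invisible(path)
}

#' Read a SIF edge list written by [write_sif()]
#'
#' @param path SIF file path.
#' @return Tibble with `source` and `target` columns.
#' @export
read_sif <- function(path) {
  lines <- readLines(path)
  if (!length(lines)) return(tibble(source = character(), target = character()))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) != 3L)
  if (length(bad)) {
    stop("Malformed SIF line ", bad[1L], " in '", path, "'.", call. = FALSE)
  }
  tibble(
    source = vapply(parts, `[[`, character(1), 1L),
    target = vapply(parts, `[[`, character(1), 3L)
  )
}

#' Write a scored edge list as TSV
#'
#' Columns: `source`, `target`, `te`, `p_value`, `stage` (those present).
#' The companion reader is [read_edge_tsv()].
#'
#' @param edges Edge tibble.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_edge_tsv <- function(edges, path) {
  tryCatch(
    readr::write_tsv(edges, path, progress = FALSE),
    error = function(e) {
      stop("Failed to write edge list '", path, "': ", conditionMessage(e),
           call. = FALSE)
    }
  )
  invisible(path)
}

#' Read a scored edge list written by [write_edge_tsv()]
#'
#' @param path TSV file path.
#' @return Edge tibble.
#' @export
read_edge_tsv <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
}
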