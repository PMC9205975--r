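#' Run the full network-inference pipeline
#'
#' Executes every stage of directed-network inference on an expression
#' table:
#' 1. moving-average smoothing;
#' 2. variance filtering of flat genes;
#' 3. (optional, when `reference_gene` is given) target selection — fuzzy
#'    c-means and cosine clustering, intersected around the reference gene;
#' 4. all-pairs transfer entropy with permutation p-values;
#' 5. the screening cascade: one-way direction selection, the strict
#'    p-value screen, the inclusive transfer-entropy screen;
#' 6. strongest-outgoing and strongest-incoming network reduction.
#'
#' Every stage's edge list is kept, each tagged with its stage, together
#' with a per-stage count log. All randomness flows from `config$seed`, so a
#' rerun with the same inputs is identical.
#'
#' @param df Expression table (gene column first).
#' @param config A [run_config()].
#' @param reference_gene Optional reference gene name for target selection;
#'   `NULL` skips the selection stage and uses all retained genes.
#' @param out_dir Optional directory; when given, every intermediate table,
#'   both networks (TSV + SIF), the configuration, and the stage-count log
#'   are written there.
#' @return A `grn_run` object (list): `config`, `genes`, `selected_genes`,
#'   `te_matrix`, `edges` (named list of stage edge tibbles), `network_out`
#'   and `network_in` (igraph), `stage_counts` tibble.
#' @export
run_pipeline <- function(df, config = run_config(), reference_gene = NULL,
                         out_dir = NULL) {
  stopifnot(inherits(config, "run_config"))
  stage <- function(name, fn) {
    tryCatch(fn(), error = function(e) {
      stop("Pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  smoothed <- stage("smoothing", function() {
    smooth_expression(df, window = config$window, boundary = config$boundary)
  })
  filtered <- stage("variance_filter", function() {
    filter_flat_genes(smoothed, min_sd = config$min_sd)
  })

  selected <- filtered
  selected_genes <- filtered$gene
  if (!is.null(reference_gene)) {
    selected_genes <- stage("target_selection", function() {
      fcm <- fuzzy_cmeans_cluster(filtered, n_clusters = config$n_clusters,
                                  fuzzifier = config$fuzzifier,
                                  seed = config$seed)
      cos <- cosine_cluster(filtered, n_clusters = config$n_clusters)
      select_by_reference(fcm, cos, reference_gene)
    })
    selected <- filtered[filtered$gene %in% selected_genes, , drop = FALSE]
  }

  te_matrix <- stage("transfer_entropy", function() {
    all_pairs_te(selected, k = config$k, l = config$l,
                 n_bins = config$n_bins, base = config$base,
                 n_permutations = config$n_permutations, seed = config$seed)
  })
  one_way <- stage("one_way_screen", function() one_way_screen(te_matrix))
  sig <- stage("pvalue_screen", function() {
    if (config$n_permutations > 0) pvalue_screen(one_way, config$alpha)
    else tag_stage(one_way, "pvalue")
  })
  strong <- stage("te_threshold_screen", function() {
    te_threshold_screen(sig, config$min_te)
  })
  out_edges <- stage("strongest_out", function() strongest_per_source(strong))
  in_edges <- stage("strongest_in", function() strongest_per_target(strong))

  edges <- list(one_way = one_way, pvalue = sig, te_threshold = strong,
                strongest_out = out_edges, strongest_in = in_edges)
  stage_counts <- tibble(
    stage = c("input_genes", "filtered_genes", "selected_genes",
              "te_pairs", names(edges)),
    n = c(nrow(df), nrow(filtered), length(selected_genes),
          nrow(te_matrix), vapply(edges, nrow, integer(1)))
  )

  run <- structure(
    list(config = config, genes = filtered$gene,
         selected_genes = selected_genes, te_matrix = te_matrix,
         edges = edges,
         network_out = build_network(out_edges),
         network_in = build_network(in_edges),
         stage_counts = stage_counts),
    class = "grn_run"
  )

  if (!is.null(out_dir)) {
    stage("write_outputs", function() write_run(run, out_dir))
  }
  run
}

# Write every artifact of a pipeline run into a directory.
write_run <- function(run, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(...) file.path(out_dir, ...)
  write_run_config(run$config, p("config.txt"))
  readr::write_tsv(run$te_matrix, p("te_matrix.tsv"), progress = FALSE)
  for (nm in names(run$edges)) {
    write_edge_tsv(run$edges[[nm]], p(paste0("edges_", nm, ".tsv")))
  }
  write_sif(run$edges$strongest_out, p("network_out.sif"))
  write_sif(run$edges$strongest_in, p("network_in.sif"))
  readr::write_tsv(run$stage_counts, p("stage_counts.tsv"), progress = FALSE)
  writeLines(run$selected_genes, p("selected_genes.txt"))
  invisible(out_dir)
}

#' @export
print.grn_run <- function(x, ...) {
  cat("Directed network inference run (seed ", x$config$seed, ")\n",
      sep = "")
  print(x$stage_counts, n = Inf)
  invisible(x)
}

#' Stage-tagged edge lists of a pipeline run
#'
#' @param x A `grn_run` from [run_pipeline()].
#' @param ... Unused.
#' @return Tibble of all edges from all stages, tagged by `stage`.
#' @export
tidy.grn_run <- function(x, ...) {
  dplyr::bind_rows(x$edges)
}

#' One-row summary of a pipeline run
#'
#' @param x A `grn_run`.
#' @param ... Unused.
#' @return One-row tibble of per-stage counts and the master seed.
#' @export
glance.grn_run <- function(x, ...) {
  wide <- stats::setNames(as.list(x$stage_counts$n), x$stage_counts$stage)
  dplyr::bind_cols(as_tibble(wide), tibble(seed = x$config$seed))
}
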