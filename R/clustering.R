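# Per-gene z-scoring of expression profiles. Pattern clustering should group
# genes by the shape of their time course, not its amplitude, so every
# profile is centered and scaled before any distance is computed.
zscore_profiles <- function(m) {
  sds <- apply(m, 1L, sd)
  if (any(sds == 0)) {
    stop("Zero-variance profile for gene: ",
         rownames(m)[sds == 0][1L],
         ". Run filter_flat_genes() first.", call. = FALSE)
  }
  (m - rowMeans(m)) / sds
}

new_cluster_assignment <- function(df, genes, cluster, membership, method,
                                   n_clusters, extra = list()) {
  out <- tibble(gene = genes, cluster = as.integer(cluster))
  attr(out, "membership") <- membership
  attr(out, "method") <- method
  attr(out, "n_clusters") <- as.integer(n_clusters)
  for (nm in names(extra)) attr(out, nm) <- extra[[nm]]
  class(out) <- c("cluster_assignment", class(out))
  out
}

#' Fuzzy c-means clustering of expression patterns
#'
#' Groups genes by temporal expression pattern with fuzzy c-means on per-gene
#' z-scored profiles. Each gene receives a graded membership across all
#' clusters (rows of the membership matrix sum to 1); its hard label is the
#' argmax membership. The algorithm alternates membership and centroid
#' updates for the standard objective
#' \eqn{J = \sum_{i,c} u_{ic}^m \lVert x_i - v_c \rVert^2}, which is
#' non-increasing across iterations, until the largest membership change
#' falls below `tol`.
#'
#' @param df Expression table (gene column first); must contain at least
#'   `n_clusters` genes and no constant profiles.
#' @param n_clusters Number of clusters (default 12, suited to partitioning
#'   genome-wide rhythmic patterns into distinct phase/shape families).
#' @param fuzzifier Fuzziness exponent `m > 1` (default 2).
#' @param seed Integer seed for the membership initialization.
#' @param tol Convergence tolerance on the maximum membership change.
#' @param max_iter Iteration cap; non-convergence warns and returns the
#'   best-so-far assignment.
#' @return A `cluster_assignment` tibble (`gene`, `cluster`) with attributes
#'   `membership` (gene x cluster matrix), `method = "fcm"`, `n_clusters`,
#'   and `objective` (per-iteration objective trace).
#' @export
fuzzy_cmeans_cluster <- function(df, n_clusters = 12, fuzzifier = 2,
                                 seed = 1, tol = 1e-5, max_iter = 1000) {
  m <- expr_matrix(df)
  n_clusters <- as.integer(n_clusters)
  if (n_clusters < 1L) stop("`n_clusters` must be >= 1.", call. = FALSE)
  if (nrow(m) < n_clusters) {
    stop("Need at least `n_clusters` genes (have ", nrow(m), ").",
         call. = FALSE)
  }
  if (fuzzifier <= 1) stop("`fuzzifier` must be > 1.", call. = FALSE)
  x <- zscore_profiles(m)
  ng <- nrow(x)

  if (n_clusters == 1L) {
    u <- matrix(1, ng, 1L)
    rownames(u) <- rownames(x)
    return(new_cluster_assignment(df, rownames(x), rep(1L, ng), u, "fcm",
                                  1L, list(objective = numeric(0))))
  }

  u <- with_local_seed(seed, function() {
    u0 <- matrix(stats::runif(ng * n_clusters), ng, n_clusters)
    u0 / rowSums(u0)
  })
  expo <- 2 / (fuzzifier - 1)
  objective <- numeric(0)
  converged <- FALSE
  for (iter in seq_len(max_iter)) {
    um <- u^fuzzifier
    centers <- (t(um) %*% x) / colSums(um)
    # squared Euclidean distances gene x cluster
    d2 <- outer(rowSums(x^2), rep(1, n_clusters)) -
      2 * x %*% t(centers) + outer(rep(1, ng), rowSums(centers^2))
    d2 <- pmax(d2, 0)
    objective <- c(objective, sum(um * d2))
    zero <- d2 < .Machine$double.eps
    u_new <- 1 / (d2^(1 / (fuzzifier - 1)) *
                    rowSums(d2^(-1 / (fuzzifier - 1))))
    if (any(zero)) {
      for (i in which(rowSums(zero) > 0)) {
        u_new[i, ] <- as.numeric(zero[i, ]) / sum(zero[i, ])
      }
    }
    delta <- max(abs(u_new - u))
    u <- u_new
    if (delta < tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    warning("Fuzzy c-means did not converge in ", max_iter,
            " iterations; returning best-so-far assignment.", call. = FALSE)
  }
  rownames(u) <- rownames(x)
  hard <- max.col(u, ties.method = "first")
  new_cluster_assignment(df, rownames(x), hard, u, "fcm", n_clusters,
                         list(objective = objective))
}

#' Cosine-similarity clustering of expression patterns
#'
#' Hierarchical (average-linkage) clustering of per-gene z-scored profiles
#' under cosine distance \eqn{1 - \cos(x_i, x_j)}, cut into `n_clusters`
#' groups. Cosine distance ignores profile magnitude, so a profile and any
#' positive scalar multiple of it always land in the same cluster. The
#' procedure is deterministic.
#'
#' @inheritParams fuzzy_cmeans_cluster
#' @return A `cluster_assignment` tibble with a hard 0/1 membership matrix
#'   and `method = "cosine"`.
#' @export
cosine_cluster <- function(df, n_clusters = 12) {
  m <- expr_matrix(df)
  n_clusters <- as.integer(n_clusters)
  if (n_clusters < 1L) stop("`n_clusters` must be >= 1.", call. = FALSE)
  if (nrow(m) < n_clusters) {
    stop("Need at least `n_clusters` genes (have ", nrow(m), ").",
         call. = FALSE)
  }
  x <- zscore_profiles(m)
  norms <- sqrt(rowSums(x^2))
  sim <- (x %*% t(x)) / outer(norms, norms)
  d <- stats::as.dist(pmax(1 - sim, 0))
  hc <- stats::hclust(d, method = "average")
  labels <- stats::cutree(hc, k = n_clusters)
  u <- matrix(0, nrow(x), n_clusters, dimnames = list(rownames(x), NULL))
  u[cbind(seq_len(nrow(x)), labels)] <- 1
  new_cluster_assignment(df, rownames(x), labels, u, "cosine", n_clusters)
}

#' Select genes sharing the reference gene's pattern under two clusterings
#'
#' Returns the intersection of the two clusters — one from each clustering —
#' that contain `reference_gene`. Requiring agreement between two unrelated
#' clustering methods makes the selected co-pattern set robust to the
#' idiosyncrasies of either method. The reference gene is always a member of
#' the result, and the result is invariant to any relabeling of clusters.
#'
#' @param assign_a,assign_b `cluster_assignment` tibbles (or any data frames
#'   with `gene` and `cluster` columns).
#' @param reference_gene Name of the reference gene; must be present in both
#'   assignments.
#' @return Sorted character vector of selected gene names.
#' @export
select_by_reference <- function(assign_a, assign_b, reference_gene) {
  members <- function(a, label) {
    if (!reference_gene %in% a$gene) {
      stop("Reference gene '", reference_gene, "' absent from ", label,
           " assignment.", call. = FALSE)
    }
    ref_cluster <- a$cluster[a$gene == reference_gene]
    a$gene[a$cluster == ref_cluster]
  }
  sort(intersect(members(assign_a, "first"), members(assign_b, "second")))
}

#' Apply an explicit curation list to a gene set
#'
#' Refines a selected gene set with documented include/exclude lists instead
#' of untraceable manual pruning: excluded genes are dropped, included genes
#' are added, and the result is reported so no gene disappears silently.
#'
#' @param genes Character vector of gene names.
#' @param include,exclude Character vectors (or `NULL`). A gene in both lists
#'   is an error.
#' @return Sorted character vector after curation.
#' @export
curate_genes <- function(genes, include = NULL, exclude = NULL) {
  both <- intersect(include, exclude)
  if (length(both)) {
    stop("Genes in both include and exclude lists: ",
         paste(both, collapse = ", "), call. = FALSE)
  }
  sort(union(setdiff(genes, exclude), include))
}
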