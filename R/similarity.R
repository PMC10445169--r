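#' Pearson correlation of two vectors
#'
#' Product-moment correlation with explicit validation: the vectors must have
#' equal length of at least 3 and neither may be constant (the correlation is
#' undefined there).
#'
#' @param u,v Numeric vectors.
#' @return Correlation in `[-1, 1]`.
#' @export
pearson <- function(u, v) {
  if (length(u) != length(v)) stop("vectors must have equal length")
  if (length(u) < 3) stop("need at least 3 observations")
  if (stats::sd(u) == 0 || stats::sd(v) == 0) {
    stop("correlation undefined for a constant vector")
  }
  stats::cor(u, v)
}

#' Sample-sample similarity as Pearson correlation of PAS vectors
#'
#' For each pair of samples, correlates their PAS values over the selected
#' pathways; the resulting correlation matrix is the molecular similarity
#' measure used to match tissue samples to cell lines. Samples whose selected
#' PAS vector is constant have no defined correlation and are excluded with a
#' warning.
#'
#' @param pas PAS matrix (pathways x samples).
#' @param pathways Pathways to use, e.g. `selection$selected`; default all.
#' @return Symmetric matrix of correlations with unit diagonal, class
#'   `similarity_matrix`.
#' @export
similarity_matrix <- function(pas, pathways = rownames(pas)) {
  pathways <- intersect(rownames(pas), pathways)
  if (length(pathways) < 3) stop("need at least 3 selected pathways")
  if (ncol(pas) < 2) stop("need at least 2 samples")
  sub <- unclass(pas)[pathways, , drop = FALSE]
  const <- apply(sub, 2, function(x) stats::sd(x) == 0)
  if (any(const)) {
    warning("excluding sample(s) with constant PAS vector: ",
            paste(colnames(sub)[const], collapse = ", "))
    sub <- sub[, !const, drop = FALSE]
    if (ncol(sub) < 2) stop("fewer than 2 samples with non-constant PAS")
  }
  pcc <- stats::cor(sub)
  diag(pcc) <- 1
  class(pcc) <- c("similarity_matrix", class(pcc))
  pcc
}

#' Hierarchically cluster samples on correlation distance
#'
#' Agglomerative clustering on distance `1 - PCC`. Average linkage is the
#' default; the merge heights and leaf order are deterministic for a fixed
#' similarity matrix.
#'
#' @param sim Similarity matrix from [similarity_matrix()].
#' @param linkage One of `"average"`, `"complete"`, `"single"`.
#' @return List with the `hclust` object (`tree`), `order` (leaf indices),
#'   `labels` (leaf labels in dendrogram order), `merge`, `height`, and a
#'   `newick` string for external plotting.
#' @export
cluster_samples <- function(sim, linkage = c("average", "complete", "single")) {
  linkage <- match.arg(linkage)
  if (nrow(sim) < 2) stop("need at least 2 samples to cluster")
  d <- 1 - unclass(sim)
  if (any(!is.finite(d))) stop("non-finite distance in similarity matrix")
  hc <- stats::hclust(stats::as.dist(d), method = linkage)
  newick <- ape::write.tree(ape::as.phylo(hc))
  list(tree = hc, order = hc$order, labels = hc$labels[hc$order],
       merge = hc$merge, height = hc$height, newick = newick)
}

#' Cut a sample dendrogram into k clusters
#'
#' @param clust Result of [cluster_samples()].
#' @param k Number of clusters.
#' @return Named integer cluster assignment per sample.
#' @export
cut_clusters <- function(clust, k) {
  stats::cutree(clust$tree, k = k)
}

#' Write a similarity matrix (optionally dendrogram-ordered) as TSV
#'
#' @param sim Similarity matrix.
#' @param path Output path.
#' @param order Optional leaf order (integer indices) to apply to rows and
#'   columns, e.g. from [cluster_samples()].
#' @return Invisibly, `path`.
#' @export
write_similarity <- function(sim, path, order = NULL) {
  m <- unclass(sim)
  if (!is.null(order)) m <- m[order, order, drop = FALSE]
  df <- data.frame(sample_id = rownames(m), m, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
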