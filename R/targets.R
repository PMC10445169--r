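#' Significantly downregulated genes from a DE table
#'
#' Genes with adjusted p below `p_thresh` and log2 fold change below
#' `-lfc_thresh`.
#'
#' @param table DE data.frame with columns `feature_id`, `log2fc`, `padj`.
#' @param p_thresh Adjusted-p threshold (default 0.05).
#' @param lfc_thresh Fold-change threshold (default 1).
#' @return Character vector of gene identifiers.
#' @export
downregulated_genes <- function(table, p_thresh = 0.05, lfc_thresh = 1) {
  table$feature_id[table$padj < p_thresh & table$log2fc < -lfc_thresh]
}

#' Significantly upregulated genes from a DE table
#'
#' @inheritParams downregulated_genes
#' @return Character vector of gene identifiers.
#' @export
upregulated_genes <- function(table, p_thresh = 0.05, lfc_thresh = 1) {
  table$feature_id[table$padj < p_thresh & table$log2fc > lfc_thresh]
}

#' Read a flat target-prediction file
#'
#' Two tab-separated columns, `mirna` and `gene`, one predicted pair per line.
#'
#' @param path Path to the TSV file.
#' @param source Source name (e.g. `"TargetScan"`).
#' @param mirna Optional miRNA id to restrict to.
#' @return List with `source`, `mirna`, `genes` (unique character vector).
#' @export
read_target_predictions <- function(path, source, mirna = NULL) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("target prediction file needs mirna and gene columns")
  if (!is.null(mirna)) df <- df[df[[1]] == mirna, , drop = FALSE]
  list(source = source, mirna = mirna %||% unique(df[[1]]),
       genes = unique(as.character(df[[2]])))
}

#' Multi-source target consensus over a downregulated gene list
#'
#' Intersects each prediction source with the downregulated gene set; the
#' consensus is the genes found in every source, the union the genes found in
#' at least one. Order of sources does not matter and duplicated sources do
#' not change the result.
#'
#' @param down Character vector of downregulated genes.
#' @param predictions List of prediction sets, each a list with `source` and
#'   `genes` (see [read_target_predictions()]).
#' @return List of class `target_consensus` with `per_source` (named list of
#'   intersections), `consensus`, `union`, and `counts` (per source, consensus
#'   and union sizes).
#' @export
consensus_targets <- function(down, predictions) {
  if (length(predictions) == 0) stop("need at least one prediction source")
  nms <- vapply(predictions, function(p) p$source, "")
  if (anyDuplicated(nms)) {
    dup <- duplicated(nms)
    predictions <- predictions[!dup]
    nms <- nms[!dup]
  }
  per_source <- lapply(predictions, function(p) sort(intersect(down, p$genes)))
  names(per_source) <- nms
  consensus <- sort(Reduce(intersect, per_source))
  union_all <- sort(Reduce(union, per_source))
  structure(list(per_source = per_source, consensus = consensus,
                 union = union_all,
                 counts = c(vapply(per_source, length, 1L),
                            consensus = length(consensus),
                            union = length(union_all))),
            class = "target_consensus")
}

#' @export
print.target_consensus <- function(x, ...) {
  cat("target consensus over", length(x$per_source), "sources:\n")
  print(x$counts)
  invisible(x)
}

#' Hypergeometric over-representation test with enrichment ratio
#'
#' Upper-tail hypergeometric probability `P(X >= k)` of observing `k` category
#' members in a list of size `n` drawn from a universe of `N` genes of which
#' `K` belong to the category, and the enrichment ratio `(k/n)/(K/N)`
#' (observed over expected fraction).
#'
#' @param k Hits (category members in the list).
#' @param n List size.
#' @param K Category size in the universe.
#' @param N Universe size.
#' @return List with `p_value` and `enrichment_ratio`.
#' @export
hypergeom_enrichment <- function(k, n, K, N) {
  if (k < 0 || n < 0 || K < 0 || N < 1) stop("counts must be nonnegative, N >= 1")
  if (k > min(n, K) || n > N || K > N) {
    stop("inconsistent counts: need 0 <= k <= min(n, K) <= N")
  }
  p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  list(p_value = p, enrichment_ratio = (k / n) / (K / N))
}

#' Over-representation of gene-set categories within a gene list
#'
#' Applies [hypergeom_enrichment()] to every category and adjusts p-values by
#' Benjamini-Hochberg.
#'
#' @param genes Character vector (the list of interest, e.g. consensus
#'   targets).
#' @param sets Named list of category gene sets.
#' @param universe Character vector of all genes considered (defaults should
#'   be the genes of the DE table the list came from).
#' @return Data.frame with one row per category: hits, list/category/universe
#'   sizes, enrichment ratio, p-value and BH-adjusted p, sorted by p.
#' @export
category_enrichment <- function(genes, sets, universe) {
  validate_gene_sets(sets)
  genes <- intersect(genes, universe)
  res <- lapply(names(sets), function(nm) {
    cat_genes <- intersect(sets[[nm]], universe)
    k <- length(intersect(genes, cat_genes))
    if (length(cat_genes) == 0) return(NULL)
    h <- hypergeom_enrichment(k, length(genes), length(cat_genes),
                              length(universe))
    data.frame(category = nm, hits = k, list_size = length(genes),
               category_size = length(cat_genes),
               universe_size = length(universe),
               enrichment_ratio = h$enrichment_ratio, p_value = h$p_value,
               stringsAsFactors = FALSE)
  })
  res <- res[!vapply(res, is.null, TRUE)]
  if (length(res) == 0) {
    return(data.frame(category = character(0), hits = integer(0),
                      list_size = integer(0), category_size = integer(0),
                      universe_size = integer(0),
                      enrichment_ratio = numeric(0), p_value = numeric(0),
                      padj = numeric(0)))
  }
  out <- do.call(rbind, res)
  out$padj <- stats::p.adjust(out$p_value, method = "BH")
  out[order(out$p_value, out$category), , drop = FALSE]
}

`%||%` <- function(a, b) if (is.null(a)) b else a
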