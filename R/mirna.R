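#' Relative abundance of each miRNA within a sample group
#'
#' Default mode pools raw counts across the group's samples and divides by the
#' group total, matching the "miRNA X represents Y% of the miRNA molecules"
#' reading; `mode = "per_sample"` instead averages per-sample fractions.
#' Percentages sum to 100.
#'
#' @param x `mirna_counts` object.
#' @param group Group label to summarize.
#' @param mode `"pooled"` (default) or `"per_sample"`.
#' @return Named numeric vector of percentages over miRNA ids.
#' @export
relative_abundance <- function(x, group, mode = c("pooled", "per_sample")) {
  mode <- match.arg(mode)
  stopifnot(inherits(x, "mirna_counts"))
  idx <- which(x$groups == group)
  if (!length(idx)) stop("no samples in group: ", group)
  sub <- x$counts[, idx, drop = FALSE]
  if (mode == "pooled") {
    total <- sum(sub)
    if (total == 0) stop("group ", group, " has zero total counts")
    100 * rowSums(sub) / total
  } else {
    libs <- colSums(sub)
    if (any(libs == 0)) stop("sample with zero total counts in group ", group)
    100 * rowMeans(sweep(sub, 2, libs, "/"))
  }
}

#' Count miRNAs expressed in at least one sample
#'
#' @param x `mirna_counts` object.
#' @param min_count Minimum raw count (default 1) a miRNA must reach in at
#'   least one sample to be called expressed.
#' @return Integer count of expressed miRNAs.
#' @export
count_expressed <- function(x, min_count = 1L) {
  stopifnot(inherits(x, "mirna_counts"), min_count >= 1)
  sum(apply(x$counts >= min_count, 1, any))
}

#' Classify differential-expression results for a volcano plot
#'
#' Partitions features by the two volcano criteria: adjusted p below
#' `p_thresh` and absolute log2 fold change above `lfc_thresh`.
#'
#' @param log2fc Numeric vector of log2 fold changes.
#' @param padj Numeric vector of adjusted p-values.
#' @param p_thresh Significance threshold (default 0.05).
#' @param lfc_thresh Fold-change threshold on |log2FC| (default 1).
#' @return Factor with levels `sig_and_large`, `large_only`, `sig_only`,
#'   `neither`.
#' @export
classify_volcano <- function(log2fc, padj, p_thresh = 0.05, lfc_thresh = 1) {
  stopifnot(length(log2fc) == length(padj),
            all(is.finite(log2fc)), all(is.finite(padj)))
  sig <- padj < p_thresh
  large <- abs(log2fc) > lfc_thresh
  cls <- ifelse(sig & large, "sig_and_large",
         ifelse(large, "large_only",
         ifelse(sig, "sig_only", "neither")))
  factor(cls, levels = c("sig_and_large", "large_only", "sig_only", "neither"))
}

#' Top significantly regulated features in one direction
#'
#' Restricts to features classified `sig_and_large` whose fold-change sign
#' matches `direction`, sorts ascending by adjusted p (ties broken by |log2FC|
#' descending, then feature id), and returns the first `n` rows — the layout
#' of a top-regulated table.
#'
#' @param table DE data.frame with columns `feature_id`, `log2fc`, `padj`.
#' @param direction `"up"` or `"down"`.
#' @param n Number of rows to return (fewer if fewer qualify).
#' @param p_thresh,lfc_thresh Volcano thresholds (defaults 0.05 and 1).
#' @return Data.frame subset in ranked order.
#' @export
top_regulated <- function(table, direction = c("up", "down"), n = 10L,
                          p_thresh = 0.05, lfc_thresh = 1) {
  direction <- match.arg(direction)
  stopifnot(n >= 1)
  if (nrow(table) == 0) return(table)
  cls <- classify_volcano(table$log2fc, table$padj, p_thresh, lfc_thresh)
  keep <- cls == "sig_and_large" &
    (if (direction == "up") table$log2fc > 0 else table$log2fc < 0)
  sub <- table[keep, , drop = FALSE]
  ord <- order(sub$padj, -abs(sub$log2fc), sub$feature_id, method = "radix")
  utils::head(sub[ord, , drop = FALSE], n)
}
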