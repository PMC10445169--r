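#' Rank genes within one expression profile
#'
#' Ranks are 1-based with rank 1 the highest expression. Ties are broken
#' deterministically: descending value, then ascending lexicographic gene
#' identifier (C collation), so a fixed profile always yields the same ranks.
#'
#' @param profile Named numeric vector of one sample's expression values.
#' @return Named integer vector of ranks, a permutation of `1:length(profile)`.
#' @export
rank_genes <- function(profile) {
  if (length(profile) == 0) stop("empty expression profile")
  if (is.null(names(profile))) stop("profile must be named by gene")
  ord <- order(-profile, names(profile), method = "radix")
  r <- integer(length(profile))
  r[ord] <- seq_along(profile)
  names(r) <- names(profile)
  r
}

#' Pathway activity score of one pathway on one ranked profile
#'
#' Computes `sum over g in P of max(K - i_g, 0) / (|P| * K)` where `i_g` is the
#' 1-based rank of gene `g` in the profile sorted by decreasing expression.
#' Only pathway members ranked within the top `K` contribute; members absent
#' from the profile stay in `|P|` but contribute 0, keeping scores comparable
#' across matrices with different gene coverage.
#'
#' @param ranks Named integer ranks from [rank_genes()].
#' @param pathway Character vector of member gene identifiers.
#' @param K Positive integer rank-truncation hyperparameter (the study default
#'   for whole-transcriptome data is 3000).
#' @return A score in `[0, 1)`.
#' @export
pas_score <- function(ranks, pathway, K) {
  if (length(pathway) == 0) stop("empty pathway")
  if (K < 1) stop("K must be >= 1")
  i <- ranks[match(pathway, names(ranks))]
  i <- i[!is.na(i)]
  if (length(i) == 0) return(0)
  sum(pmax(K - i, 0)) / (length(pathway) * K)
}

#' Pathway activity scores for every pathway and sample
#'
#' @param x Expression matrix (genes x samples); see
#'   [validate_expression_matrix()].
#' @param sets Named list of gene sets (e.g. from [read_gmt()]).
#' @param K Rank-truncation hyperparameter; default 3000.
#' @return Numeric matrix (pathways x samples) of class `pas_matrix` with
#'   attribute `K`.
#' @export
pas_matrix <- function(x, sets, K = 3000) {
  validate_expression_matrix(x)
  validate_gene_sets(sets)
  ranks <- vapply(seq_len(ncol(x)), function(j) {
    rank_genes(setNames(x[, j], rownames(x)))
  }, integer(nrow(x)))
  dimnames(ranks) <- dimnames(x)
  w <- pmax(K - ranks, 0)
  out <- matrix(0, length(sets), ncol(x),
                dimnames = list(names(sets), colnames(x)))
  for (p in names(sets)) {
    members <- intersect(sets[[p]], rownames(x))
    if (length(members)) {
      out[p, ] <- colSums(w[members, , drop = FALSE]) / (length(sets[[p]]) * K)
    }
  }
  attr(out, "K") <- K
  class(out) <- c("pas_matrix", class(out))
  out
}

#' Write a PAS matrix as TSV
#'
#' A header comment records `K` and, when given, the checksum of the exclusion
#' list applied upstream, so a score file is traceable to its configuration.
#'
#' @param pas PAS matrix from [pas_matrix()].
#' @param path Output path.
#' @param exclusion_checksum Optional checksum string recorded in the header.
#' @return Invisibly, `path`.
#' @export
write_pas_matrix <- function(pas, path, exclusion_checksum = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# K=%d", as.integer(attr(pas, "K"))), con)
  if (!is.null(exclusion_checksum)) {
    writeLines(sprintf("# exclusion_checksum=%s", exclusion_checksum), con)
  }
  df <- data.frame(pathway = rownames(pas), unclass(pas), check.names = FALSE)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a PAS matrix written by [write_pas_matrix()]
#'
#' @param path Path to the TSV file.
#' @return A `pas_matrix` with its `K` attribute restored.
#' @export
read_pas_matrix <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr <- grep("^#", lines, value = TRUE)
  K <- NA_integer_
  km <- grep("^# K=", hdr, value = TRUE)
  if (length(km)) K <- as.integer(sub("^# K=", "", km[1]))
  df <- utils::read.delim(text = lines[!grepl("^#", lines)],
                          check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  attr(m, "K") <- K
  class(m) <- c("pas_matrix", class(m))
  m
}
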