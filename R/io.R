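#' Read a GMT gene-set collection
#'
#' Parses the tab-separated GMT format used by MSigDB: one gene set per line,
#' fields are set name, description, then member gene symbols. Duplicate
#' members within a line are collapsed.
#'
#' @param path Path to a GMT file.
#' @return A named list of character vectors of gene identifiers, with a
#'   `description` attribute (named character vector) carrying the second
#'   field of each line.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("GMT file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(vapply(fields, length, 1L) < 3L)
  if (length(bad)) {
    stop("malformed GMT line ", bad[1], ": fewer than 3 tab-separated fields")
  }
  nm <- vapply(fields, `[[`, "", 1L)
  if (anyDuplicated(nm)) {
    stop("duplicate gene-set name in GMT: ", nm[duplicated(nm)][1])
  }
  sets <- lapply(fields, function(f) unique(f[-(1:2)]))
  names(sets) <- nm
  desc <- vapply(fields, `[[`, "", 2L)
  names(desc) <- nm
  attr(sets, "description") <- desc
  sets
}

#' Write a gene-set collection as GMT
#'
#' @param sets Named list of character vectors.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_gmt <- function(sets, path) {
  validate_gene_sets(sets)
  desc <- attr(sets, "description")
  if (is.null(desc)) desc <- setNames(rep("na", length(sets)), names(sets))
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, desc[[nm]], sets[[nm]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

validate_gene_sets <- function(sets) {
  if (!is.list(sets) || is.null(names(sets)) || any(!nzchar(names(sets)))) {
    stop("gene sets must be a named list")
  }
  if (anyDuplicated(names(sets))) stop("duplicate gene-set names")
  if (any(vapply(sets, length, 1L) == 0L)) stop("empty gene set")
  invisible(sets)
}

#' Validate an expression matrix
#'
#' An expression matrix is a base numeric matrix of nonnegative values with
#' unique gene identifiers as rownames and unique sample identifiers as
#' colnames; missing cells are not permitted.
#'
#' @param x Numeric matrix.
#' @return Invisibly, `x`.
#' @export
validate_expression_matrix <- function(x) {
  if (!is.matrix(x) || !is.numeric(x)) stop("expression matrix must be a numeric matrix")
  if (is.null(rownames(x)) || is.null(colnames(x))) {
    stop("expression matrix needs gene rownames and sample colnames")
  }
  if (anyDuplicated(rownames(x))) {
    stop("duplicate gene identifier: ", rownames(x)[duplicated(rownames(x))][1])
  }
  if (anyDuplicated(colnames(x))) {
    stop("duplicate sample identifier: ", colnames(x)[duplicated(colnames(x))][1])
  }
  if (anyNA(x)) stop("expression matrix contains missing values")
  if (any(x < 0)) stop("expression matrix contains negative values")
  invisible(x)
}

#' Read a genes-by-samples expression matrix from TSV
#'
#' First column holds gene identifiers, header row holds sample identifiers.
#'
#' @param path Path to a tab-separated file.
#' @return Validated numeric matrix (genes x samples).
#' @export
read_expression_matrix <- function(path) {
  if (!file.exists(path)) stop("expression file not found: ", path)
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  genes <- as.character(df[[1]])
  if (anyDuplicated(genes)) {
    stop("duplicate gene identifier: ", genes[duplicated(genes)][1])
  }
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- genes
  validate_expression_matrix(m)
  m
}

#' Write an expression matrix as TSV
#'
#' @param x Expression matrix.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_expression_matrix <- function(x, path) {
  validate_expression_matrix(x)
  df <- data.frame(gene_id = rownames(x), x, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an exclusion list (one gene identifier per line)
#'
#' Blank lines and `#` comments are ignored. Used for housekeeping and
#' immune/stromal marker genes to be removed before pathway scoring.
#'
#' @param path Path to a one-column text file.
#' @return Character vector of unique gene identifiers.
#' @export
read_exclusion_list <- function(path) {
  if (!file.exists(path)) stop("exclusion list not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  unique(lines[nzchar(lines)])
}

#' Remove excluded genes from an expression matrix
#'
#' Drops rows whose gene identifier appears in the exclusion list. Matching is
#' exact, case-sensitive string equality on HUGO symbols.
#'
#' @param x Expression matrix (genes x samples).
#' @param exclude Character vector of gene identifiers to drop.
#' @return The filtered matrix; samples unchanged.
#' @export
apply_exclusion <- function(x, exclude) {
  validate_expression_matrix(x)
  keep <- !(rownames(x) %in% exclude)
  if (!any(keep)) stop("exclusion list removes every gene in the matrix")
  x[keep, , drop = FALSE]
}

#' Read a differential-expression result table
#'
#' Expects tab-separated columns `feature_id` (or first column), a log2
#' fold-change column and an adjusted-p column. Column names matching
#' `log2FoldChange`/`log2fc` and `padj`/`p_adj` (case-insensitive) are
#' recognised.
#'
#' @param path Path to a TSV file.
#' @return A data.frame with columns `feature_id`, `log2fc`, `padj`.
#' @export
read_de_table <- function(path) {
  if (!file.exists(path)) stop("DE table not found: ", path)
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  nms <- tolower(names(df))
  fc_col <- which(nms %in% c("log2foldchange", "log2fc", "logfc"))[1]
  p_col <- which(nms %in% c("padj", "p_adj", "fdr", "adj.p.val"))[1]
  if (is.na(fc_col) || is.na(p_col)) {
    stop("DE table needs a log2 fold-change and an adjusted-p column")
  }
  out <- data.frame(
    feature_id = as.character(df[[1]]),
    log2fc = as.numeric(df[[fc_col]]),
    padj = as.numeric(df[[p_col]]),
    stringsAsFactors = FALSE
  )
  validate_de_table(out)
  out
}

validate_de_table <- function(df) {
  if (anyDuplicated(df$feature_id)) {
    stop("duplicate feature in DE table: ", df$feature_id[duplicated(df$feature_id)][1])
  }
  ok <- is.na(df$padj) | (df$padj >= 0 & df$padj <= 1)
  if (!all(ok)) stop("adjusted p-values outside [0, 1]")
  invisible(df)
}

#' Construct a mature-miRNA count container
#'
#' @param counts Nonnegative integer matrix, miRNAs x samples.
#' @param groups Group label per sample (character or factor), aligned with
#'   `colnames(counts)`.
#' @return An object of class `mirna_counts`: a list with elements `counts`
#'   and `groups` (named factor).
#' @export
mirna_counts <- function(counts, groups) {
  if (!is.matrix(counts)) stop("counts must be a matrix")
  if (anyNA(counts) || any(counts < 0)) stop("counts must be nonnegative")
  if (any(counts != round(counts))) stop("counts must be integers")
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop("counts need miRNA rownames and sample colnames")
  }
  if (length(groups) != ncol(counts)) stop("one group label per sample required")
  groups <- factor(groups)
  names(groups) <- colnames(counts)
  structure(list(counts = counts, groups = groups), class = "mirna_counts")
}

#' Read a miRNA count matrix with group labels
#'
#' The TSV layout mirrors [read_expression_matrix()]; group labels come either
#' from a two-column `sample_id<TAB>group` file or a named vector.
#'
#' @param path Count TSV (first column miRNA id, header row sample ids).
#' @param groups Either a path to a sample-annotation TSV or a vector of group
#'   labels named by sample id.
#' @return A `mirna_counts` object.
#' @export
read_mirna_counts <- function(path, groups) {
  m <- read_expression_matrix(path)
  if (any(m != round(m))) stop("miRNA counts must be integers")
  if (is.character(groups) && length(groups) == 1 && file.exists(groups)) {
    ann <- utils::read.delim(groups, stringsAsFactors = FALSE)
    groups <- setNames(as.character(ann[[2]]), as.character(ann[[1]]))
  }
  if (is.null(names(groups))) stop("group labels must be named by sample id")
  missing <- setdiff(colnames(m), names(groups))
  if (length(missing)) stop("no group label for sample: ", missing[1])
  mirna_counts(m, groups[colnames(m)])
}

#' Validate a 2x2 contingency table
#'
#' @param x 2x2 matrix of nonnegative integer counts.
#' @return Invisibly, `x`.
#' @export
validate_contingency_2x2 <- function(x) {
  if (!is.matrix(x) || !all(dim(x) == c(2L, 2L))) stop("need a 2x2 matrix")
  if (anyNA(x) || any(x < 0)) stop("contingency counts must be nonnegative")
  if (any(x != round(x))) stop("contingency counts must be integers")
  if (sum(x) == 0) stop("contingency table total must be positive")
  invisible(x)
}
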