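#' Select cancer-type-predictive pathways by L1-penalized multinomial regression
#'
#' Fits a multinomial (softmax) logistic regression of sample class on
#' standardized PAS features with an L1 penalty, and reports the pathways
#' carrying at least one coefficient of magnitude above tolerance. With
#' `penalty = "auto"` the penalty is chosen by stratified k-fold
#' cross-validated multinomial deviance.
#'
#' PAS features are standardized to zero mean / unit variance before fitting
#' because the L1 penalty is scale-sensitive and PAS ranges vary with pathway
#' size; constant features are dropped (they can never be selected).
#'
#' @param pas PAS matrix (pathways x samples) from [pas_matrix()].
#' @param labels Class label per sample (character or factor), aligned with
#'   `colnames(pas)` or named by sample id.
#' @param penalty Nonnegative numeric lambda, or `"auto"` for cross-validation.
#' @param seed Integer seed fixing fold assignment; selection is deterministic
#'   given data, penalty and seed.
#' @param nfolds Folds for cross-validation (default 5).
#' @param rule Which cross-validated lambda to use: `"lambda.min"` (default)
#'   or `"lambda.1se"`.
#' @param tol Coefficient-magnitude tolerance for "nonzero" (default 1e-8).
#' @return An object of class `pathway_selection`: list with `selected`
#'   (character vector, PAS row order), `coefficients` (pathway x class
#'   matrix), `penalty`, `classes`, `seed`, and the fitted `cv` object when
#'   `penalty = "auto"`.
#' @export
select_pathways <- function(pas, labels, penalty = "auto", seed = 1L,
                            nfolds = 5L, rule = c("lambda.min", "lambda.1se"),
                            tol = 1e-8) {
  rule <- match.arg(rule)
  labels <- align_labels(labels, colnames(pas))
  y <- factor(labels)
  if (nlevels(y) < 2) stop("need at least 2 distinct class labels")
  x <- t(unclass(pas))
  sds <- apply(x, 2, stats::sd)
  keep <- !is.na(sds) & sds > 0
  empty <- structure(list(selected = character(0),
                          coefficients = matrix(0, 0, nlevels(y),
                                                dimnames = list(NULL, levels(y))),
                          penalty = if (identical(penalty, "auto")) NA_real_ else penalty,
                          classes = levels(y), seed = seed, cv = NULL),
                     class = "pathway_selection")
  if (!any(keep)) return(empty)
  x <- scale(x[, keep, drop = FALSE])

  if (identical(penalty, "auto")) {
    counts <- table(y)
    if (any(counts < 2)) stop("need >= 2 samples per class for cross-validation")
    if (nfolds > min(counts)) {
      stop("more folds (", nfolds, ") than smallest class (", min(counts),
           "); lower nfolds or supply a numeric penalty")
    }
    foldid <- stratified_folds(y, nfolds, seed)
    cv <- glmnet::cv.glmnet(x, y, family = "multinomial", alpha = 1,
                            foldid = foldid, standardize = FALSE)
    lambda <- cv[[rule]]
    fit <- cv$glmnet.fit
  } else {
    stopifnot(is.numeric(penalty), penalty >= 0)
    cv <- NULL
    lambda <- penalty
    fit <- glmnet::glmnet(x, y, family = "multinomial", alpha = 1,
                          standardize = FALSE)
  }
  co <- coef_matrix(fit, lambda)
  selected <- rownames(co)[apply(abs(co) > tol, 1, any)]
  selected <- intersect(rownames(pas), selected)  # deterministic PAS order
  structure(list(selected = selected, coefficients = co, penalty = lambda,
                 classes = levels(y), seed = seed, cv = cv),
            class = "pathway_selection")
}

#' Select approximately a fixed number of pathways
#'
#' Walks the L1 regularization path and bisects the penalty until the number
#' of selected pathways is the largest achievable value not exceeding
#' `target_count`. Because the lasso path changes support in jumps, the exact
#' target may be unreachable; the result then carries `warning_flag = TRUE`
#' and the nearest-below count.
#'
#' @inheritParams select_pathways
#' @param target_count Desired panel size, between 1 and `nrow(pas)`.
#' @param max_iter Bisection iterations (default 50).
#' @return A `pathway_selection` with extra fields `target_count`,
#'   `achieved_count` and `warning_flag`.
#' @export
select_to_count <- function(pas, labels, target_count, seed = 1L, tol = 1e-8,
                            max_iter = 50L) {
  if (target_count < 1 || target_count > nrow(pas)) {
    stop("target_count must be in [1, number of pathways]")
  }
  labels <- align_labels(labels, colnames(pas))
  y <- factor(labels)
  if (nlevels(y) < 2) stop("need at least 2 distinct class labels")
  x <- t(unclass(pas))
  sds <- apply(x, 2, stats::sd)
  keep <- !is.na(sds) & sds > 0
  x <- scale(x[, keep, drop = FALSE])
  fit <- glmnet::glmnet(x, y, family = "multinomial", alpha = 1,
                        standardize = FALSE, nlambda = 100,
                        lambda.min.ratio = 1e-4)
  n_at <- function(lam) {
    co <- coef_matrix(fit, lam)
    sum(apply(abs(co) > tol, 1, any))
  }
  counts <- vapply(fit$lambda, n_at, 1L)
  # path is ordered from large lambda (sparse) to small (dense)
  if (all(counts < target_count)) {
    lam <- fit$lambda[length(fit$lambda)]
  } else if (any(counts == target_count)) {
    lam <- fit$lambda[which(counts == target_count)[1]]
  } else {
    # bracket the jump over target_count and bisect
    hi_i <- max(which(counts < target_count))           # sparser side
    lo_i <- min(which(counts > target_count))           # denser side
    hi <- fit$lambda[hi_i]; lo <- fit$lambda[lo_i]
    lam <- hi
    for (i in seq_len(max_iter)) {
      mid <- sqrt(hi * lo)
      nm <- n_at(mid)
      if (nm == target_count) { lam <- mid; break }
      if (nm < target_count) { hi <- mid; lam <- mid } else lo <- mid
    }
  }
  co <- coef_matrix(fit, lam)
  selected <- rownames(co)[apply(abs(co) > tol, 1, any)]
  selected <- intersect(rownames(pas), selected)
  achieved <- length(selected)
  structure(list(selected = selected, coefficients = co, penalty = lam,
                 classes = levels(y), seed = seed, cv = NULL,
                 target_count = target_count, achieved_count = achieved,
                 warning_flag = achieved != target_count),
            class = "pathway_selection")
}

#' Write a selection result as TSV
#'
#' One row per pathway with per-class coefficients and a selected flag; the
#' penalty and seed are recorded in a header comment.
#'
#' @param sel `pathway_selection` object.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_selection <- function(sel, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# penalty=%.8g seed=%d", sel$penalty, sel$seed), con)
  df <- data.frame(pathway = rownames(sel$coefficients), sel$coefficients,
                   selected = rownames(sel$coefficients) %in% sel$selected,
                   check.names = FALSE)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @export
print.pathway_selection <- function(x, ...) {
  cat("pathway selection:", length(x$selected), "pathways at penalty",
      format(x$penalty, digits = 4), "over classes",
      paste(x$classes, collapse = ", "), "\n")
  invisible(x)
}

# per-class glmnet coefficients (intercept dropped) as pathway x class matrix
coef_matrix <- function(fit, lambda) {
  co <- glmnet::coef.glmnet(fit, s = lambda, exact = FALSE)
  m <- do.call(cbind, lapply(co, function(s) as.numeric(s)[-1]))
  rownames(m) <- rownames(co[[1]])[-1]
  colnames(m) <- names(co)
  m
}

stratified_folds <- function(y, nfolds, seed) {
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  foldid <- integer(length(y))
  for (cl in levels(y)) {
    idx <- which(y == cl)
    foldid[idx] <- sample(rep_len(seq_len(nfolds), length(idx)))
  }
  foldid
}

align_labels <- function(labels, sample_ids) {
  if (!is.null(names(labels))) {
    missing <- setdiff(sample_ids, names(labels))
    if (length(missing)) stop("no class label for sample: ", missing[1])
    labels <- labels[sample_ids]
  } else if (length(labels) != length(sample_ids)) {
    stop("one class label per sample required")
  }
  as.character(labels)
}
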