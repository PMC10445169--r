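#' Simulate an expression matrix with class-specific active pathways
#'
#' Generates the data structure the PAS pipeline assumes: a log-normal
#' baseline expression per gene (gene-specific means drawn once per
#' simulation), a collection of disjoint pathways, and for each sample class a
#' designated set of "active" pathways whose member genes are coherently
#' shifted up on the log2 scale before per-gene noise is added. Every pathway
#' additionally receives an independent per-sample activity fluctuation
#' (`activity_sd`), emulating inter-sample pathway heterogeneity; this also
#' means each planted pathway carries its own information about the class
#' rather than being a copy of its neighbours. All randomness is fixed by
#' `seed`; there is no dependence on global random state.
#'
#' @param n_genes Number of genes (default 4000).
#' @param n_per_class Samples per class (default 30).
#' @param classes Class labels (default 3 classes).
#' @param n_sets Number of pathways in the collection (default 200).
#' @param set_size Inclusive range of pathway sizes (default `c(8, 15)`);
#'   pathways are disjoint, so the sizes must sum to at most `n_genes`.
#' @param n_planted Active pathways per class (default 10); the first
#'   `n_planted * length(classes)` pathways are planted, disjointly by class.
#' @param planted Optional explicit map `class -> pathway names`, overriding
#'   `n_planted`. Names must exist in the generated collection.
#' @param effect Log2-scale mean shift applied to active-pathway member genes
#'   in their class (default 2, i.e. 4-fold).
#' @param activity_sd SD of the per-pathway, per-sample activity fluctuation
#'   on the log2 scale (default 0.7).
#' @param noise_sd SD of per-gene log2 noise (default 0.2).
#' @param baseline_mean,baseline_sd Mean and SD of the per-gene baseline log2
#'   expression (defaults 6 and 2).
#' @param seed Integer seed (required).
#' @return List with `expression` (genes x samples matrix), `sets` (named
#'   list), `annotation` (data.frame: sample_id, class_label, origin), and
#'   `planted` (list class -> active pathway names).
#' @export
simulate_expression <- function(n_genes = 4000L, n_per_class = 30L,
                                classes = c("classA", "classB", "classC"),
                                n_sets = 200L, set_size = c(8L, 15L),
                                n_planted = 10L, planted = NULL,
                                effect = 2, activity_sd = 0.7, noise_sd = 0.2,
                                baseline_mean = 6, baseline_sd = 2,
                                seed) {
  stopifnot(effect >= 0, activity_sd >= 0, noise_sd >= 0, n_genes >= 1)
  if (missing(seed)) stop("an explicit integer seed is required")
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)

  genes <- sprintf("G%05d", seq_len(n_genes))
  sizes <- sample(seq(set_size[1], set_size[2]), n_sets, replace = TRUE)
  if (sum(sizes) > n_genes) {
    stop("pathway sizes exceed n_genes; raise n_genes or shrink the collection")
  }
  pool <- sample(genes)
  sets <- vector("list", n_sets)
  names(sets) <- sprintf("PW%03d", seq_len(n_sets))
  off <- 0L
  for (i in seq_len(n_sets)) {
    sets[[i]] <- pool[(off + 1L):(off + sizes[i])]
    off <- off + sizes[i]
  }

  if (is.null(planted)) {
    if (n_planted * length(classes) > n_sets) stop("too many planted pathways")
    planted <- split(names(sets)[seq_len(n_planted * length(classes))],
                     rep(classes, each = n_planted))
    planted <- planted[classes]
  } else {
    missing_pw <- setdiff(unlist(planted), names(sets))
    if (length(missing_pw)) stop("planted pathway absent: ", missing_pw[1])
  }

  labels <- rep(classes, each = n_per_class)
  samples <- sprintf("S%03d", seq_along(labels))
  mu <- stats::rnorm(n_genes, baseline_mean, baseline_sd)
  names(mu) <- genes

  x <- matrix(0, n_genes, length(samples), dimnames = list(genes, samples))
  for (j in seq_along(samples)) {
    z <- mu
    active <- planted[[labels[j]]]
    for (p in names(sets)) {
      a <- effect * (p %in% active) + stats::rnorm(1, 0, activity_sd)
      z[sets[[p]]] <- z[sets[[p]]] + a
    }
    x[, j] <- 2^(z + stats::rnorm(n_genes, 0, noise_sd))
  }
  validate_expression_matrix(x)
  annotation <- data.frame(sample_id = samples, class_label = labels,
                           origin = "tissue", stringsAsFactors = FALSE)
  list(expression = x, sets = sets, annotation = annotation, planted = planted)
}

#' Simulate mature-miRNA counts with a designed group composition
#'
#' Each group has a Dirichlet concentration vector over miRNA ids; every
#' sample draws its composition from that Dirichlet and its counts from a
#' multinomial at the sample's library size. A dominant species (e.g. one
#' miRNA carrying 21.5% of the concentration mass) therefore reappears at
#' about that pooled fraction.
#'
#' @param concentrations Named list `group -> named positive concentration
#'   vector over miRNA ids`. The miRNA universe is the union of all names.
#' @param n_per_group Samples per group (scalar or named per group).
#' @param library_size Reads per sample (scalar or named per group;
#'   default 1e6).
#' @param seed Integer seed (required).
#' @return A `mirna_counts` object.
#' @export
simulate_mirna_counts <- function(concentrations, n_per_group,
                                  library_size = 1e6, seed) {
  if (missing(seed)) stop("an explicit integer seed is required")
  stopifnot(is.list(concentrations), length(concentrations) >= 1)
  if (any(unlist(concentrations) <= 0)) stop("concentrations must be positive")
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)

  groups <- names(concentrations)
  mirnas <- sort(unique(unlist(lapply(concentrations, names))))
  n_per_group <- expand_per_group(n_per_group, groups)
  library_size <- expand_per_group(library_size, groups)

  cols <- list(); labels <- character(0)
  for (g in groups) {
    alpha <- setNames(rep(0, length(mirnas)), mirnas)
    alpha[names(concentrations[[g]])] <- concentrations[[g]]
    present <- alpha > 0
    for (i in seq_len(n_per_group[[g]])) {
      p <- rep(0, length(mirnas))
      gam <- stats::rgamma(sum(present), shape = alpha[present], rate = 1)
      p[present] <- gam / sum(gam)
      cols[[length(cols) + 1L]] <-
        as.integer(stats::rmultinom(1, size = library_size[[g]], prob = p))
      labels <- c(labels, g)
    }
  }
  counts <- do.call(cbind, cols)
  rownames(counts) <- mirnas
  colnames(counts) <- sprintf("%s_%02d", labels, stats::ave(seq_along(labels),
                                                            labels,
                                                            FUN = seq_along))
  mirna_counts(counts, labels)
}

expand_per_group <- function(x, groups) {
  if (length(x) == 1L && is.null(names(x))) {
    x <- setNames(rep(x, length(groups)), groups)
  }
  if (!all(groups %in% names(x))) stop("per-group value missing for a group")
  as.list(x[groups])
}

#' Simulate partially overlapping target-prediction lists
#'
#' Builds one prediction set per source containing the designed consensus
#' genes plus source-specific disjoint extras drawn from a gene pool, so the
#' intersection over sources (within any superset list) is the consensus by
#' construction.
#'
#' @param consensus Character vector of genes present in every source.
#' @param extras_per_source Number of source-specific extra genes (default 3).
#' @param sources Source names (default the three common databases).
#' @param gene_pool Pool to draw extras from (must avoid `consensus`); a
#'   default pool of synthetic symbols is generated when `NULL`.
#' @param mirna miRNA id recorded on each set (default "hsa-miR-10a-5p").
#' @param seed Integer seed (required).
#' @return List of prediction sets as in [read_target_predictions()].
#' @export
simulate_target_lists <- function(consensus, extras_per_source = 3L,
                                  sources = c("TargetScan", "miRDB",
                                              "miRTarBase"),
                                  gene_pool = NULL,
                                  mirna = "hsa-miR-10a-5p", seed) {
  if (missing(seed)) stop("an explicit integer seed is required")
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  need <- extras_per_source * length(sources)
  if (is.null(gene_pool)) {
    gene_pool <- sprintf("EXTRA%04d", seq_len(max(need, 1)))
  }
  gene_pool <- setdiff(gene_pool, consensus)
  if (length(gene_pool) < need) stop("gene pool too small for requested extras")
  extras <- if (need > 0) sample(gene_pool, need) else character(0)
  lapply(seq_along(sources), function(i) {
    idx <- if (extras_per_source > 0) {
      ((i - 1) * extras_per_source + 1):(i * extras_per_source)
    } else integer(0)
    list(source = sources[i], mirna = mirna,
         genes = c(consensus, extras[idx]))
  })
}

#' Simulate a noiseless or noisy four-parameter dose-response table
#'
#' Convenience generator for IC50 recovery checks.
#'
#' @param ic50,top,bottom,hill True curve parameters.
#' @param doses Dose vector (default ten doses, 5 to 200).
#' @param replicates Replicates per dose (default 3).
#' @param noise_sd Gaussian noise SD on viability (default 0 = noiseless).
#' @param seed Integer seed (required when `noise_sd > 0`).
#' @return Data.frame with columns `dose`, `viability`.
#' @export
simulate_dose_response <- function(ic50, top = 1, bottom = 0, hill = 1,
                                   doses = c(5, 10, 20, 30, 50, 75, 100,
                                             130, 160, 200),
                                   replicates = 3L, noise_sd = 0, seed = NULL) {
  dose <- rep(doses, each = replicates)
  v <- bottom + (top - bottom) / (1 + (dose / ic50)^hill)
  if (noise_sd > 0) {
    if (is.null(seed)) stop("seed required for noisy simulation")
    old <- get0(".Random.seed", envir = globalenv())
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
    set.seed(seed)
    v <- v + stats::rnorm(length(v), 0, noise_sd)
  }
  data.frame(dose = dose, viability = v)
}
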