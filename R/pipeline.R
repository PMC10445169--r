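#' Validate a pipeline run configuration
#'
#' A configuration is a named list (or a YAML file of one) with input paths
#' and parameters. Required: `expression`, `gmt`, `annotation` (sample_id /
#' class_label TSV), `outdir`. Optional: `exclusion`, `de_table`,
#' `mirna_counts` + `mirna_groups`, `targets` (named list source -> path),
#' `target_mirna`. Parameters with defaults: `K` (3000), `penalty`
#' (`"auto"`), `target_count` (unset), `p_thresh` (0.05), `lfc_thresh` (1),
#' `linkage` (`"average"`), `seed` (1).
#'
#' @param config Named list or path to a YAML file.
#' @return The validated, default-filled configuration list.
#' @export
validate_config <- function(config) {
  if (is.character(config) && length(config) == 1) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  defaults <- list(K = 3000L, penalty = "auto", p_thresh = 0.05,
                   lfc_thresh = 1, linkage = "average", seed = 1L)
  for (nm in names(defaults)) {
    if (is.null(config[[nm]])) config[[nm]] <- defaults[[nm]]
  }
  for (nm in c("expression", "gmt", "annotation", "outdir")) {
    if (is.null(config[[nm]])) stop("config missing required field: ", nm)
  }
  paths <- c(config$expression, config$gmt, config$annotation,
             config$exclusion, config$de_table, config$mirna_counts,
             config$mirna_groups, unlist(config$targets))
  missing <- paths[!file.exists(paths)]
  if (length(missing)) stop("config references missing file: ", missing[1])
  if (config$K < 1) stop("K must be >= 1")
  if (config$p_thresh <= 0 || config$lfc_thresh <= 0) {
    stop("thresholds must be positive")
  }
  config
}

#' Run the full analysis pipeline from a configuration
#'
#' Executes exclusion filtering, PAS computation, pathway selection,
#' similarity and clustering, and — when miRNA inputs are present — miRNA
#' composition profiling, volcano/top tables, target consensus and
#' over-representation. Every stage writes its output under
#' `config$outdir`, and a JSON manifest records the configuration, seed and
#' an MD5 checksum per output file, so a rerun with an identical
#' configuration reproduces identical checksums.
#'
#' @param config Named list or YAML path; see [validate_config()].
#' @return The manifest (list), invisibly written to `manifest.json`.
#' @export
run_pipeline <- function(config) {
  config <- validate_config(config)
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  outputs <- character(0)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  out <- function(file) file.path(config$outdir, file)

  x <- stage("read_expression", read_expression_matrix(config$expression))
  sets <- stage("read_gmt", read_gmt(config$gmt))
  ann <- utils::read.delim(config$annotation, stringsAsFactors = FALSE)
  labels <- setNames(as.character(ann$class_label), ann$sample_id)

  excl_checksum <- NULL
  if (!is.null(config$exclusion)) {
    excl <- stage("read_exclusion", read_exclusion_list(config$exclusion))
    x <- stage("apply_exclusion", apply_exclusion(x, excl))
    excl_checksum <- unname(tools::md5sum(config$exclusion))
  }

  pas <- stage("pas", pas_matrix(x, sets, K = config$K))
  write_pas_matrix(pas, out("pas_matrix.tsv"), excl_checksum)
  outputs <- c(outputs, "pas_matrix.tsv")

  sel <- stage("selection", {
    if (!is.null(config$target_count)) {
      select_to_count(pas, labels, config$target_count, seed = config$seed)
    } else {
      select_pathways(pas, labels, penalty = config$penalty,
                      seed = config$seed)
    }
  })
  write_selection(sel, out("selection.tsv"))
  outputs <- c(outputs, "selection.tsv")

  use_pw <- if (length(sel$selected) >= 3) sel$selected else rownames(pas)
  sim <- stage("similarity", similarity_matrix(pas, use_pw))
  cl <- stage("clustering", cluster_samples(sim, linkage = config$linkage))
  write_similarity(sim, out("similarity.tsv"), order = cl$order)
  writeLines(cl$newick, out("dendrogram.nwk"))
  outputs <- c(outputs, "similarity.tsv", "dendrogram.nwk")

  if (!is.null(config$mirna_counts)) {
    mc <- stage("read_mirna",
                read_mirna_counts(config$mirna_counts, config$mirna_groups))
    ab <- lapply(levels(mc$groups), function(g) {
      data.frame(group = g, mirna = rownames(mc$counts),
                 percent = relative_abundance(mc, g))
    })
    utils::write.table(do.call(rbind, ab), out("mirna_abundance.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    outputs <- c(outputs, "mirna_abundance.tsv")
  }

  if (!is.null(config$de_table)) {
    de <- stage("read_de", read_de_table(config$de_table))
    de$volcano_class <- classify_volcano(de$log2fc, de$padj,
                                         config$p_thresh, config$lfc_thresh)
    utils::write.table(de, out("de_classified.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(top_regulated(de, "up", 10, config$p_thresh,
                                     config$lfc_thresh),
                       out("top_up.tsv"), sep = "\t", quote = FALSE,
                       row.names = FALSE)
    utils::write.table(top_regulated(de, "down", 10, config$p_thresh,
                                     config$lfc_thresh),
                       out("top_down.tsv"), sep = "\t", quote = FALSE,
                       row.names = FALSE)
    outputs <- c(outputs, "de_classified.tsv", "top_up.tsv", "top_down.tsv")

    if (!is.null(config$targets)) {
      preds <- stage("read_targets", lapply(names(config$targets), function(s) {
        read_target_predictions(config$targets[[s]], s,
                                mirna = config$target_mirna)
      }))
      down <- downregulated_genes(de, config$p_thresh, config$lfc_thresh)
      cons <- stage("consensus", consensus_targets(down, preds))
      writeLines(jsonlite::toJSON(
        list(per_source = cons$per_source, consensus = cons$consensus,
             union = cons$union, counts = as.list(cons$counts)),
        auto_unbox = TRUE, pretty = TRUE), out("target_consensus.json"))
      outputs <- c(outputs, "target_consensus.json")

      enr <- stage("enrichment",
                   category_enrichment(cons$union, sets, de$feature_id))
      utils::write.table(enr, out("target_enrichment.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      outputs <- c(outputs, "target_enrichment.tsv")
    }
  }

  checksums <- as.list(tools::md5sum(file.path(config$outdir, outputs)))
  names(checksums) <- outputs
  manifest <- list(
    config = config[setdiff(names(config), "outdir")],
    seed = config$seed,
    n_selected = length(sel$selected),
    stages = outputs,
    checksums = checksums,
    status = "ok")
  writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, pretty = TRUE),
             out("manifest.json"))
  invisible(manifest)
}
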