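#!/usr/bin/env Rscript
# Three-source miRNA target consensus over a downregulated gene list, with
# hypergeometric over-representation of functional categories in the union.

library(pasmatch)

sources <- c("TargetScan", "miRDB", "miRTarBase")
preds <- lapply(sources, function(s) {
  read_target_predictions(sprintf("results/data/targets_%s.tsv", s), s,
                          mirna = "hsa-miR-10a-5p")
})

# downregulated universe: every predicted gene is "downregulated" here, plus a
# margin of unrelated genes, so the consensus operates inside a DE context
down <- unique(unlist(lapply(preds, `[[`, "genes")))
universe <- c(down, sprintf("BG%04d", 1:3000))

cons <- consensus_targets(down, preds)
print(cons)
cat("consensus genes:", paste(cons$consensus, collapse = ", "), "\n")
writeLines(jsonlite::toJSON(list(consensus = cons$consensus,
                                 counts = as.list(cons$counts)),
                            auto_unbox = TRUE, pretty = TRUE),
           "results/target_consensus.json")

# over-representation of a category built around the consensus
sets <- list(
  consensus_family = c(cons$consensus, sprintf("BG%04d", 1:6)),
  random_block = sprintf("BG%04d", 101:160))
enr <- category_enrichment(cons$union, sets, universe)
print(enr[, c("category", "hits", "enrichment_ratio", "p_value", "padj")])
write.table(enr, "results/target_enrichment.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
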