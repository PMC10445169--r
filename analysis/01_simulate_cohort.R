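#!/usr/bin/env Rscript
# Simulate the study-shaped inputs for the downstream analyses: a 3-class
# expression cohort with 10 active pathways planted per class, group-structured
# mature-miRNA counts with a dominant species, and three partially overlapping
# target-prediction lists. All files go under results/data/.

library(pasmatch)

seed <- 7L
dir.create("results/data", recursive = TRUE, showWarnings = FALSE)

sim <- simulate_expression(seed = seed)
write_expression_matrix(sim$expression, "results/data/expression.tsv")
write_gmt(sim$sets, "results/data/pathways.gmt")
write.table(sim$annotation, "results/data/annotation.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
writeLines(unlist(sim$planted), "results/data/planted_pathways.txt")
cat(sprintf("expression: %d genes x %d samples; %d pathways (%d planted)\n",
            nrow(sim$expression), ncol(sim$expression), length(sim$sets),
            length(unlist(sim$planted))))

# miRNA counts: tumor group dominated by one species carrying 21.5% of the
# concentration mass, benign group by a different species at 14.5%
conc <- list(
  tumor = c("hsa-miR-10a-5p" = 430, "hsa-miR-30a-5p" = 122,
            "hsa-miR-141-3p" = 27, "other-pool" = 1421),
  benign = c("hsa-miR-143-3p" = 290, "hsa-miR-146b-5p" = 89,
             "other-pool" = 1621))
mirna <- simulate_mirna_counts(conc, n_per_group = 4, library_size = 5e6,
                               seed = seed)
write_expression_matrix(mirna$counts + 0, "results/data/mirna_counts.tsv")
write.table(data.frame(sample_id = colnames(mirna$counts),
                       group = as.character(mirna$groups)),
            "results/data/mirna_groups.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat(sprintf("miRNA counts: %d species x %d samples\n",
            nrow(mirna$counts), ncol(mirna$counts)))

# three target-prediction sources sharing a designed consensus
consensus <- c("BDNF", "RORA", "CSRNP3", "CHL1", "LIX1L", "RAP2A")
lists <- simulate_target_lists(consensus, extras_per_source = 55, seed = seed,
                               gene_pool = sprintf("TG%04d", 1:400))
for (p in lists) {
  write.table(data.frame(mirna = p$mirna, gene = p$genes),
              sprintf("results/data/targets_%s.tsv", p$source),
              sep = "\t", quote = FALSE, row.names = FALSE)
}
cat(sprintf("target lists: %s, %d designed consensus genes\n",
            paste(vapply(lists, `[[`, "", "source"), collapse = "/"),
            length(consensus)))
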