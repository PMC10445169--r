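#!/usr/bin/env Rscript
# Mature-miRNA composition of each group, expressed-species counting, volcano
# classification and top regulated tables. The DE table is the example set of
# mature-miRNA results shipped with the package; the count matrix is the
# simulated cohort from step 01.

library(pasmatch)

mc <- read_mirna_counts("results/data/mirna_counts.tsv",
                        "results/data/mirna_groups.tsv")

cat(sprintf("%d of %d miRNA species expressed in at least one sample\n",
            count_expressed(mc, min_count = 1), nrow(mc$counts)))

for (g in levels(mc$groups)) {
  ab <- sort(relative_abundance(mc, g), decreasing = TRUE)
  cat(sprintf("%s: most abundant %s at %.1f%% (pooled)\n",
              g, names(ab)[1], ab[1]))
}
ab_all <- do.call(rbind, lapply(levels(mc$groups), function(g) {
  data.frame(group = g, mirna = rownames(mc$counts),
             percent = relative_abundance(mc, g))
}))
write.table(ab_all, "results/mirna_abundance.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

de <- read_de_table(system.file("extdata", "mirna_de_example.tsv",
                                package = "pasmatch"))
de$volcano_class <- classify_volcano(de$log2fc, de$padj,
                                     p_thresh = 0.05, lfc_thresh = 1)
print(table(de$volcano_class))
write.table(de, "results/mirna_de_classified.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

top_up <- top_regulated(de, "up", 10)
top_down <- top_regulated(de, "down", 10)
cat(sprintf("top upregulated: %s (log2FC %.2f, padj %.2g)\n",
            top_up$feature_id[1], top_up$log2fc[1], top_up$padj[1]))
cat(sprintf("top downregulated: %s (log2FC %.2f, padj %.2g)\n",
            top_down$feature_id[1], top_down$log2fc[1], top_down$padj[1]))
write.table(top_up, "results/mirna_top_up.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
write.table(top_down, "results/mirna_top_down.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
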