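#!/usr/bin/env Rscript
# Mapped-gene filtering (RPKM >= 0.5 in any sample) and the per-pair DEG
# screen (fold change > 1.5 and RPKM difference > 10 in every pair).

suppressPackageStartupMessages(library(degnet))

expr <- read_expression("results/inputs/discovery_rpkm.tsv", unit = "rpkm")
mapped <- filter_mapped(expr, min_rpkm = 0.5)
degs <- screen_paired(mapped, fc_threshold = 1.5, diff_threshold = 10)
dir.create("results", showWarnings = FALSE)
write.table(degs, "results/deg_table.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

truth <- read.delim("results/inputs/truth_degs.tsv")
i <- match(truth$gene_id, degs$gene_id)
sens <- mean(!is.na(i) & degs$direction[i] == truth$direction)
cat(sprintf("mapped genes: %d of %d\n", nrow(mapped$values), nrow(expr$values)),
    sprintf("DEGs: %d up, %d down\n", sum(degs$direction == "up"),
            sum(degs$direction == "down")),
    sprintf("planted-DEG sensitivity: %.1f%%, false positives: %d\n",
            100 * sens, sum(!degs$gene_id %in% truth$gene_id)))
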