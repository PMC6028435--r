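#!/usr/bin/env Rscript
# Term over-representation of the up- and down-regulated DEG lists against
# the mapped-gene universe (raw p < 0.05, the pathway-stage convention;
# rerun with adjust = "bh" for the GO-style criterion).

suppressPackageStartupMessages(library(degnet))

expr <- read_expression("results/inputs/discovery_rpkm.tsv", unit = "rpkm")
mapped <- filter_mapped(expr)
universe <- rownames(mapped$values)
degs <- read.delim("results/deg_table.tsv")

set.seed(101)
coll <- simulate_gene_sets(universe, degs$gene_id)

for (dir in c("up", "down")) {
  res <- enrich(degs$gene_id[degs$direction == dir], coll, universe,
                alpha = 0.05, adjust = "none")
  write.table(res, sprintf("results/enrichment_%s.tsv", dir), sep = "\t",
              quote = FALSE, row.names = FALSE)
  cat(sprintf("%s-regulated: %d/%d terms significant (raw p < 0.05); top: %s (p = %.3g)\n",
              dir, sum(res$significant), nrow(res), res$term_id[1],
              res$p_raw[1]))
}
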