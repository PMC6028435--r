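#!/usr/bin/env Rscript
# PPI subnetwork around the validated hub genes and chromosome co-location
# of the directly interacting pairs (the cis/trans classification).

suppressPackageStartupMessages(library(degnet))

ppi <- read_ppi("results/inputs/ppi_background.tsv")
loc <- read_gene_locations("results/inputs/gene_locations.bed")
val <- read.delim("results/validation.tsv")
seeds <- val$gene_id[val$concordant %in% TRUE]

sub <- extract_subnetwork(ppi, seeds)
write.table(sub$edges, "results/ppi_edges.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
pairs <- classify_pairs(sub$edges[sub$edges$kind == "seed-seed",
                                  c("a", "b")], loc)
write.table(pairs, "results/ppi_pairs.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
links <- circos_links(sub$edges[sub$edges$kind == "seed-seed", c("a", "b")],
                      loc)
write.table(links, "results/circos_links.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE, col.names = FALSE)

cat(sprintf("subnetwork: %d seed-seed and %d seed-neighbor edges\n",
            sum(sub$edges$kind == "seed-seed"),
            sum(sub$edges$kind == "seed-neighbor")))
print(pairs)
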