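#!/usr/bin/env Rscript
# Validation-cohort differential expression (p < 0.05 and fold change > 1.5
# or < 2/3) and direction concordance of the hub genes with discovery.

suppressPackageStartupMessages(library(degnet))

counts <- as.matrix(read.delim("results/inputs/validation_counts.tsv",
                               row.names = 1, check.names = FALSE))
groups <- read.delim("results/inputs/validation_groups.tsv")$group
de <- cohort_de(counts, groups, p_threshold = 0.05, fc_up = 1.5,
                fc_down = 2 / 3)
write.table(de, "results/validation_de.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

hubs <- read.delim("results/hub_genes.tsv")
res <- concordance(hubs, de)
write.table(res, "results/validation.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
s <- attr(res, "summary")
cat(sprintf("cohort DEGs: %d of %d genes\n", sum(de$direction != "ns"),
            nrow(de)),
    sprintf("hub genes tested: %d; cohort-concordant: %d\n",
            s$n_tested, s$n_cohort_consistent))
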