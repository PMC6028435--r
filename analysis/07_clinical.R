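#!/usr/bin/env Rscript
# Spearman association of hub-gene expression with the clinical phenotypes
# (tumor size, node, metastasis, stage) plus the metastasis t-test, and the
# discovery-cohort summary statistics.

suppressPackageStartupMessages(library(degnet))

expr <- as.matrix(read.delim("results/inputs/clinical_expression.tsv",
                             row.names = 1, check.names = FALSE))
clinical <- read_clinical("results/inputs/clinical_table.tsv")
res <- associate(expr, clinical, tumor_size = "cm")
write.table(res, "results/clinical_assoc.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
print(res[res$method != "untested", ])

s <- summarize_cohort(ptc_cohort())
cat(sprintf("\ndiscovery cohort: n = %d, age %.1f +/- %.1f years\n",
            s$n_patients, s$mean_age_display, s$sd_age_display))
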