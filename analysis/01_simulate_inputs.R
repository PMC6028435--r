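#!/usr/bin/env Rscript
# Generate the synthetic study inputs: paired discovery counts/RPKM,
# validation-cohort counts, pathway XML bundle, PPI background with
# locations, and clinical phenotypes. Everything downstream reads from
# results/inputs/.

suppressPackageStartupMessages(library(degnet))

seed <- 1L
out <- "results/inputs"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

cfg <- sim_config(seed = seed)
disc <- simulate_paired_discovery(cfg)
write_expression(disc$rpkm, file.path(out, "discovery_rpkm.tsv"))
write.table(data.frame(gene_id = names(disc$lengths_kb),
                       length_kb = disc$lengths_kb),
            file.path(out, "gene_lengths.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(disc$truth, file.path(out, "truth_degs.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

val <- simulate_validation_cohort(cfg, disc$truth)
write.table(data.frame(gene_id = rownames(val$counts), val$counts,
                       check.names = FALSE),
            file.path(out, "validation_counts.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(data.frame(sample = colnames(val$counts), group = val$groups),
            file.path(out, "validation_groups.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

pw <- simulate_pathways(cfg, disc$truth, file.path(out, "pathways"))
write.table(data.frame(gene_id = pw$hub_genes),
            file.path(out, "truth_hubs.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

ppi <- simulate_ppi_and_locations(cfg, pw$hub_genes)
write.table(ppi$ppi, file.path(out, "ppi_background.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE, col.names = FALSE)
write.table(ppi$locations[, c("chromosome", "start", "end", "gene_id")],
            file.path(out, "gene_locations.bed"), sep = "\t",
            quote = FALSE, row.names = FALSE, col.names = FALSE)

clin <- simulate_clinical(cfg, target_gene = pw$hub_genes[1])
write.table(data.frame(gene_id = rownames(clin$expr), clin$expr,
                       check.names = FALSE),
            file.path(out, "clinical_expression.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(clin$clinical, file.path(out, "clinical_table.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

cat(sprintf("simulated %d genes x %d paired samples (%d planted DEGs),\n",
            nrow(disc$counts), ncol(disc$counts), nrow(disc$truth)),
    sprintf("validation cohort %d tumor / %d normal, %d pathway files,\n",
            cfg$n_tumor, cfg$n_normal, length(pw$files)),
    sprintf("PPI background %d edges, clinical cohort n = %d\n",
            nrow(ppi$ppi), nrow(clin$clinical)))
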