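#!/usr/bin/env Rscript
# Integrate the pathway bundle into one regulatory network, mark DEG nodes,
# and select the DEG-containing nodes in the top degree decile.

suppressPackageStartupMessages(library(degnet))

files <- list.files("results/inputs/pathways", full.names = TRUE)
net <- integrate_pathways(lapply(files, parse_pathway))
degs <- read.delim("results/deg_table.tsv")
net <- mark_degs(net, degs$gene_id)
sel <- select_hub_degs(net, top_fraction = 0.10, deg_directions = degs)

write_network_tables(net, "results/network_nodes.tsv",
                     "results/network_edges.tsv")
write.table(data.frame(gene_id = sel$hub_genes,
                       direction = ifelse(sel$hub_genes %in% sel$up_genes,
                                          "up", "down")),
            "results/hub_genes.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

truth_hubs <- read.delim("results/inputs/truth_hubs.tsv")$gene_id
cat(sprintf("integrated network: %d nodes, %d edges\n",
            nrow(net$nodes), nrow(net$edges)),
    sprintf("top-decile cutoff degree: %d; hub DEG nodes: %d\n",
            sel$cutoff_degree, nrow(sel$hub_nodes)),
    sprintf("hub genes (%d up, %d down): %s\n", length(sel$up_genes),
            length(sel$down_genes), paste(sel$hub_genes, collapse = ", ")),
    sprintf("planted hubs recovered exactly: %s\n",
            setequal(sel$hub_genes, truth_hubs)))
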