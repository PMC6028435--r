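# End-to-end pipeline driver: simulate (or read) inputs, screen DEGs,
# run enrichment, build the integrated pathway network and pick hub genes,
# validate against the cohort, extract the PPI subnetwork, and test
# clinical associations. Every stage writes a TSV under the output
# directory and logs its thresholds and seed.

#' Default pipeline configuration
#'
#' Threshold defaults are the screen's canonical values: mapped-gene RPKM
#' 0.5 (any-sample scope), per-pair fold change 1.5, RPKM difference 10,
#' enrichment alpha 0.05 (raw p for pathways, BH for GO-style runs), hub
#' top fraction 0.10, validation p 0.05 with fold bounds 1.5 and 2/3.
#'
#' @param seed Master seed for the simulated bundle.
#' @param ... Overrides for any config entry (`min_rpkm`, `filter_scope`,
#'   `fc_threshold`, `diff_threshold`, `screen_mode`, `alpha`,
#'   `enrich_adjust`, `top_fraction`, `p_threshold`, `fc_up`, `fc_down`,
#'   `allow_partial`, or any [sim_config()] field under `sim`).
#' @return Named list of class `degnet_config`.
#' @export
pipeline_config <- function(seed = 1L, ...) {
  cfg <- list(seed = as.integer(seed),
              min_rpkm = 0.5, filter_scope = "any",
              fc_threshold = 1.5, diff_threshold = 10,
              screen_mode = "all_pairs",
              alpha = 0.05, enrich_adjust = "none",
              top_fraction = 0.10,
              p_threshold = 0.05, fc_up = 1.5, fc_down = 2 / 3,
              tumor_size = "cm",
              allow_partial = FALSE,
              sim = list())
  dots <- list(...)
  for (nm in names(dots)) cfg[[nm]] <- dots[[nm]]
  structure(cfg, class = "degnet_config")
}

#' Read a pipeline configuration from YAML
#'
#' Any key present in the file overrides the [pipeline_config()] default;
#' `sim:` entries override [sim_config()] fields.
#'
#' @param path YAML file path.
#' @return A `degnet_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(pipeline_config, c(list(seed = y$seed %||% 1L),
                             y[setdiff(names(y), "seed")]))
}

#' Run the full discovery-to-validation pipeline
#'
#' Executes, in order: synthetic input generation, mapped-gene filtering and
#' the paired DEG screen, term enrichment of the up- and down-regulated
#' lists (tested separately), pathway-network integration with top-decile
#' hub selection, validation-cohort concordance for the hub genes, PPI
#' subnetwork extraction with chromosome co-location, and clinical
#' association of the first hub gene. All randomness derives from
#' `config$seed`, and outputs are byte-stable for a fixed seed.
#'
#' @param config A `degnet_config` (or YAML path for one).
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list of the in-memory stage results; files are
#'   written under `out_dir` (`deg_table.tsv`, `enrichment_up.tsv`,
#'   `enrichment_down.tsv`, `network_nodes.tsv`, `network_edges.tsv`,
#'   `hub_genes.tsv`, `validation.tsv`, `ppi_edges.tsv`, `ppi_pairs.tsv`,
#'   `clinical_assoc.tsv`, `run_log.txt`).
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir) {
  if (is.character(config)) config <- read_pipeline_config(config)
  .check(inherits(config, "degnet_config"), "config must be a degnet_config")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- c(sprintf("seed\t%d", config$seed),
                 sprintf("min_rpkm\t%g", config$min_rpkm),
                 sprintf("fc_threshold\t%g", config$fc_threshold),
                 sprintf("diff_threshold\t%g", config$diff_threshold),
                 sprintf("alpha\t%g", config$alpha),
                 sprintf("top_fraction\t%g", config$top_fraction),
                 sprintf("p_threshold\t%g", config$p_threshold))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }

  # -- inputs ---------------------------------------------------------------
  scfg <- stage("simulate",
                do.call(sim_config, c(list(seed = config$seed), config$sim)))
  disc <- stage("simulate", simulate_paired_discovery(scfg))
  cohort_sim <- stage("simulate", simulate_validation_cohort(scfg, disc$truth))
  paths <- stage("simulate",
                 simulate_pathways(scfg, disc$truth,
                                   file.path(out_dir, "inputs", "pathways")))

  # -- DEG screen -----------------------------------------------------------
  degs <- stage("screen", {
    mapped <- filter_mapped(disc$rpkm, config$min_rpkm, config$filter_scope)
    screen_paired(mapped, config$fc_threshold, config$diff_threshold,
                  config$screen_mode)
  })
  .write_tsv(degs, file.path(out_dir, "deg_table.tsv"))
  log_lines <- c(log_lines,
                 sprintf("degs_up\t%d", sum(degs$direction == "up")),
                 sprintf("degs_down\t%d", sum(degs$direction == "down")))

  # -- enrichment -----------------------------------------------------------
  universe <- rownames(disc$rpkm$values)
  enr <- stage("enrich", {
    set.seed(.child_seed(config$seed, 91L))
    coll <- simulate_gene_sets(universe, degs$gene_id)
    up <- enrich(degs$gene_id[degs$direction == "up"], coll, universe,
                 alpha = config$alpha, adjust = config$enrich_adjust)
    down <- enrich(degs$gene_id[degs$direction == "down"], coll, universe,
                   alpha = config$alpha, adjust = config$enrich_adjust)
    list(up = up, down = down)
  })
  .write_tsv(enr$up, file.path(out_dir, "enrichment_up.tsv"))
  .write_tsv(enr$down, file.path(out_dir, "enrichment_down.tsv"))

  # -- pathway network ------------------------------------------------------
  hubs <- NULL
  if (length(paths$files) > 0) {
    net <- stage("network", {
      graphs <- lapply(paths$files, parse_pathway)
      g <- integrate_pathways(graphs)
      mark_degs(g, degs$gene_id)
    })
    hubs <- stage("network",
                  select_hub_degs(net, config$top_fraction,
                                  deg_directions = degs))
    write_network_tables(net, file.path(out_dir, "network_nodes.tsv"),
                         file.path(out_dir, "network_edges.tsv"))
    .write_tsv(data.frame(gene_id = hubs$hub_genes,
                          direction = ifelse(hubs$hub_genes %in% hubs$up_genes,
                                             "up", "down"),
                          stringsAsFactors = FALSE),
               file.path(out_dir, "hub_genes.tsv"))
    log_lines <- c(log_lines,
                   sprintf("network_nodes\t%d", nrow(net$nodes)),
                   sprintf("network_edges\t%d", nrow(net$edges)),
                   sprintf("hub_genes\t%d", length(hubs$hub_genes)))
  } else if (config$allow_partial) {
    warning("no pathway files; network stage skipped", call. = FALSE)
  } else {
    stop("pipeline stage 'network' failed: no pathway files", call. = FALSE)
  }

  # -- validation -----------------------------------------------------------
  val <- stage("validate", {
    de <- cohort_de(cohort_sim$counts, cohort_sim$groups,
                    p_threshold = config$p_threshold,
                    fc_up = config$fc_up, fc_down = config$fc_down)
    sel <- degs[degs$gene_id %in% (hubs$hub_genes %||% degs$gene_id),
                c("gene_id", "direction")]
    concordance(sel, de)
  })
  .write_tsv(val, file.path(out_dir, "validation.tsv"))

  # -- PPI + chromosomes ----------------------------------------------------
  ppi_res <- stage("ppi", {
    validated <- val$gene_id[which(val$concordant)]
    sim_ppi <- simulate_ppi_and_locations(scfg, union(validated,
                                                      paths$hub_genes))
    sub <- extract_subnetwork(sim_ppi$ppi, union(validated, paths$hub_genes))
    pairs <- classify_pairs(sub$edges[sub$edges$kind == "seed-seed",
                                      c("a", "b"), drop = FALSE],
                            sim_ppi$locations)
    list(sub = sub, pairs = pairs)
  })
  .write_tsv(ppi_res$sub$edges, file.path(out_dir, "ppi_edges.tsv"))
  .write_tsv(ppi_res$pairs, file.path(out_dir, "ppi_pairs.tsv"))

  # -- clinical -------------------------------------------------------------
  clin <- stage("clinical", {
    target <- (paths$hub_genes %||% degs$gene_id)[1]
    sim_cl <- simulate_clinical(scfg, target_gene = target)
    associate(sim_cl$expr, sim_cl$clinical,
              alpha = config$alpha, tumor_size = config$tumor_size)
  })
  .write_tsv(clin, file.path(out_dir, "clinical_assoc.tsv"))

  writeLines(log_lines, file.path(out_dir, "run_log.txt"))
  invisible(list(truth = disc$truth, planted_hubs = paths$hub_genes,
                 degs = degs, enrichment = enr,
                 hubs = hubs, validation = val, ppi = ppi_res,
                 clinical = clin, config = config))
}
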