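# Seeded generators for every pipeline input: paired discovery counts,
# a two-group validation cohort, KGML pathway bundles with planted hubs,
# a PPI background with planted interacting pairs, gene-set collections,
# and clinical phenotypes with planted Spearman correlations.
#
# Count model: gamma-Poisson. For the paired discovery data the Gamma draw
# is the per-patient, per-gene baseline shared between the tumor and the
# adjacent sample of a pair (the "per-patient baseline heterogeneity"), so
# marginal counts are negative binomial with the configured dispersion while
# the within-pair comparison sees only Poisson-level noise — the power
# rationale of a paired design. Validation-cohort samples are unpaired and
# each receives an independent Gamma draw, so the full NB dispersion acts
# between groups there.

#' Simulation configuration
#'
#' Bundles every generator parameter with its default study conditions:
#' 3 discovery pairs with planted up/down DEGs at fold 4 on a 30-RPKM
#' baseline over NB dispersion 0.1; a 60 vs 10 validation cohort (the
#' 513/59 design at desk scale); pathway bundles with planted high-degree
#' hub nodes carrying DEGs; a PPI background with planted interacting
#' pairs on different chromosomes; and clinical phenotypes with planted
#' Spearman correlations.
#'
#' @param seed Integer master seed; every generator derives its stream from
#'   it deterministically.
#' @param n_genes Genes in the expression universe.
#' @param n_pairs Discovery tumor/adjacent pairs.
#' @param planted_up,planted_down Numbers of planted up-/down-regulated
#'   genes (2:1, mirroring the skew of paired tumor screens).
#' @param effect_fold Planted fold change (tumor over adjacent for up genes).
#' @param baseline_rpkm Baseline RPKM of planted genes.
#' @param nb_dispersion NB dispersion phi (variance = mu + phi mu^2).
#' @param library_millions Mean mapped library size, millions of reads.
#' @param n_tumor,n_normal Validation-cohort group sizes.
#' @param n_pathways,pathway_size Pathway bundle shape.
#' @param planted_hub_count Planted high-degree DEG hub nodes.
#' @param hub_degree Degree wired into each planted hub.
#' @param ppi_background_genes,ppi_background_edges PPI background size.
#' @param n_clinical_samples Patients in the clinical association cohort.
#' @param planted_rho Named vector of planted Spearman correlations per
#'   phenotype (`tumor_size`, `node`, `metastasis`, `stage`).
#' @return Validated list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_genes = 2000L,
                       n_pairs = 3L,
                       planted_up = 40L,
                       planted_down = 20L,
                       effect_fold = 4,
                       baseline_rpkm = 30,
                       nb_dispersion = 0.1,
                       library_millions = 10,
                       n_tumor = 60L,
                       n_normal = 10L,
                       n_pathways = 4L,
                       pathway_size = 30L,
                       planted_hub_count = 3L,
                       hub_degree = 12L,
                       ppi_background_genes = 200L,
                       ppi_background_edges = 400L,
                       n_clinical_samples = 500L,
                       planted_rho = c(tumor_size = 0.5, node = 0.3,
                                       metastasis = 0, stage = 0.3)) {
  cfg <- list(seed = as.integer(seed), n_genes = as.integer(n_genes),
              n_pairs = as.integer(n_pairs),
              planted_up = as.integer(planted_up),
              planted_down = as.integer(planted_down),
              effect_fold = effect_fold, baseline_rpkm = baseline_rpkm,
              nb_dispersion = nb_dispersion,
              library_millions = library_millions,
              n_tumor = as.integer(n_tumor), n_normal = as.integer(n_normal),
              n_pathways = as.integer(n_pathways),
              pathway_size = as.integer(pathway_size),
              planted_hub_count = as.integer(planted_hub_count),
              hub_degree = as.integer(hub_degree),
              ppi_background_genes = as.integer(ppi_background_genes),
              ppi_background_edges = as.integer(ppi_background_edges),
              n_clinical_samples = as.integer(n_clinical_samples),
              planted_rho = planted_rho)
  with(cfg, {
    .check(all(c(n_genes, n_pairs, n_tumor, n_normal, n_pathways,
                 pathway_size, planted_hub_count, hub_degree,
                 ppi_background_genes, ppi_background_edges,
                 n_clinical_samples) > 0), "all counts must be positive")
    .check(planted_up >= 0 && planted_down >= 0 &&
             planted_up + planted_down <= n_genes,
           "planted gene counts must fit inside n_genes")
    .check(effect_fold > 0 && baseline_rpkm > 0 && nb_dispersion >= 0 &&
             library_millions > 0, "effect/baseline/dispersion invalid")
    .check(all(abs(planted_rho) < 1), "planted_rho must lie in (-1, 1)")
  })
  structure(cfg, class = "sim_config")
}

.gene_ids <- function(n) sprintf("g%04d", seq_len(n))

# gamma multiplier with mean 1 and variance phi (Gamma(1/phi, 1/phi));
# degenerate at 1 when phi == 0
.gamma_het <- function(n, phi) {
  if (phi <= 0) rep(1, n) else stats::rgamma(n, shape = 1 / phi, rate = 1 / phi)
}

#' Simulate the paired discovery experiment
#'
#' Counts for `n_genes` genes in `n_pairs` tumor/adjacent pairs. Per gene
#' and patient a shared Gamma baseline (mean = the gene's baseline RPKM,
#' CV^2 = `nb_dispersion`) scales both samples of the pair; planted genes
#' are shifted by `effect_fold` in the tumor sample of every pair. Counts
#' are Poisson around baseline x fold x length_kb x library_millions, and
#' RPKM is recomputed from the counts via [rpkm_matrix()]. Background
#' baselines are log-normal and straddle the 0.5-RPKM mapped-gene filter.
#'
#' @param config A [sim_config()].
#' @return List with `rpkm` (a `paired_expression_set`), `counts` (matrix),
#'   `lengths_kb`, `library_millions` (per sample), `truth` (data frame
#'   `gene_id`, `direction` of planted DEGs).
#' @export
simulate_paired_discovery <- function(config) {
  .check(inherits(config, "sim_config"), "config must be a sim_config")
  set.seed(.child_seed(config$seed, 11L))
  n <- config$n_genes
  ids <- .gene_ids(n)
  lengths_kb <- exp(stats::rnorm(n, log(2), 0.35))

  n_planted <- config$planted_up + config$planted_down
  planted <- seq_len(n_planted)
  direction <- rep(c("up", "down"), c(config$planted_up, config$planted_down))
  baseline <- exp(stats::rnorm(n, log(3), 1.6)) # background spans the 0.5 filter
  baseline[planted] <- config$baseline_rpkm

  samples <- as.vector(rbind(paste0(seq_len(config$n_pairs), "ca"),
                             paste0(seq_len(config$n_pairs), "adj")))
  lib <- config$library_millions * exp(stats::rnorm(length(samples), 0, 0.05))
  counts <- matrix(0, n, length(samples), dimnames = list(ids, samples))
  fold_up <- config$effect_fold
  for (p in seq_len(config$n_pairs)) {
    het <- baseline * .gamma_het(n, config$nb_dispersion)
    mu_t <- mu_a <- het
    mu_t[planted][direction == "up"] <- het[planted][direction == "up"] * fold_up
    mu_a[planted][direction == "down"] <- het[planted][direction == "down"] * fold_up
    ca <- paste0(p, "ca"); adj <- paste0(p, "adj")
    counts[, ca] <- stats::rpois(n, mu_t * lengths_kb * lib[match(ca, samples)])
    counts[, adj] <- stats::rpois(n, mu_a * lengths_kb * lib[match(adj, samples)])
  }
  rpkm_vals <- rpkm_matrix(counts, lib, lengths_kb)
  truth <- data.frame(gene_id = ids[planted], direction = direction,
                      stringsAsFactors = FALSE)
  list(rpkm = paired_expression_set(rpkm_vals, unit = "rpkm"),
       counts = counts, lengths_kb = stats::setNames(lengths_kb, ids),
       library_millions = stats::setNames(lib, samples), truth = truth)
}

#' Simulate the two-group validation cohort
#'
#' Unpaired NB counts (`n_tumor` + `n_normal` samples) over the same gene
#' ids; planted genes carry the truth-table direction at `effect_fold`.
#' Each sample gets an independent Gamma draw, so the full NB dispersion
#' separates the groups.
#'
#' @param config A [sim_config()].
#' @param truth Truth table from [simulate_paired_discovery()].
#' @return List with `counts` (gene x sample matrix) and `groups`
#'   (`"tumor"`/`"normal"` per column).
#' @export
simulate_validation_cohort <- function(config, truth) {
  .check(inherits(config, "sim_config"), "config must be a sim_config")
  set.seed(.child_seed(config$seed, 23L))
  n <- config$n_genes
  ids <- .gene_ids(n)
  lengths_kb <- exp(stats::rnorm(n, log(2), 0.35))
  baseline <- exp(stats::rnorm(n, log(3), 1.6))
  pl <- match(truth$gene_id, ids)
  baseline[pl] <- config$baseline_rpkm

  n_s <- config$n_tumor + config$n_normal
  groups <- rep(c("tumor", "normal"), c(config$n_tumor, config$n_normal))
  samples <- paste0(ifelse(groups == "tumor", "t", "n"),
                    unlist(lapply(rle(groups)$lengths, seq_len)))
  lib <- config$library_millions * exp(stats::rnorm(n_s, 0, 0.05))
  fold <- matrix(1, n, n_s)
  fold[pl[truth$direction == "up"], groups == "tumor"] <- config$effect_fold
  fold[pl[truth$direction == "down"], groups == "normal"] <- config$effect_fold
  mu <- (baseline * lengths_kb) %o% lib * fold
  het <- matrix(.gamma_het(n * n_s, config$nb_dispersion), n, n_s)
  counts <- matrix(stats::rpois(n * n_s, mu * het), n, n_s,
                   dimnames = list(ids, samples))
  list(counts = counts, groups = groups)
}

#' Simulate a KGML pathway bundle with planted hubs
#'
#' Writes `n_pathways` KGML-dialect files. Each of the first
#' `planted_hub_count` pathways contains one hub node — a planted DEG gene
#' wired to `hub_degree` partner nodes — while the remaining nodes form a
#' sparse ring (degree 2) with a few additional planted DEG genes attached
#' as degree-1 leaves. Planted hubs are therefore the only DEG-containing
#' nodes in the top degree decile of the integrated network.
#'
#' @param config A [sim_config()].
#' @param truth Truth table from [simulate_paired_discovery()].
#' @param dir Output directory for the XML files.
#' @return List with `files`, `hub_genes` (the planted hub DEGs),
#'   `leaf_deg_genes` (planted DEGs wired as low-degree leaves), and
#'   per-pathway `node_counts` / `edge_counts`.
#' @export
simulate_pathways <- function(config, truth, dir) {
  .check(inherits(config, "sim_config"), "config must be a sim_config")
  .check(config$planted_hub_count <= nrow(truth),
         "need at least planted_hub_count planted DEGs")
  .check(config$pathway_size > config$hub_degree + 2,
         "pathway_size must exceed hub_degree + 2")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(.child_seed(config$seed, 37L))

  # hub genes skew up-regulated with one down-regulated hub when available,
  # mirroring the direction imbalance typical of tumor hub sets
  up_ids <- truth$gene_id[truth$direction == "up"]
  down_ids <- truth$gene_id[truth$direction == "down"]
  n_hub <- config$planted_hub_count
  n_up <- min(length(up_ids), n_hub - min(1L, length(down_ids)))
  hub_genes <- c(utils::head(up_ids, n_up),
                 utils::head(down_ids, n_hub - n_up))
  .check(length(hub_genes) == n_hub, "not enough planted DEGs for hubs")
  leaf_pool <- setdiff(truth$gene_id, hub_genes)
  files <- character(config$n_pathways)
  node_counts <- edge_counts <- integer(config$n_pathways)
  leaf_used <- character()

  for (pw in seq_len(config$n_pathways)) {
    pid <- sprintf("sim%02d", pw)
    size <- config$pathway_size
    # background genes unique to this pathway
    bg <- sprintf("%s_b%03d", pid, seq_len(size))
    genes <- bg
    has_hub <- pw <= config$planted_hub_count
    if (has_hub) genes[1] <- hub_genes[pw]
    # two planted DEG leaves per pathway where available
    n_leaf <- min(2L, length(leaf_pool))
    leaves <- leaf_pool[seq_len(n_leaf)]
    leaf_pool <- setdiff(leaf_pool, leaves)
    leaf_used <- c(leaf_used, leaves)

    entries <- c(genes, leaves)
    eid <- seq_along(entries)
    rel <- list()
    if (has_hub) {
      spokes <- 1L + seq_len(config$hub_degree)
      for (s in spokes) rel[[length(rel) + 1L]] <- c(1L, s)
      ring <- setdiff(seq_along(genes), c(1L, spokes))
    } else {
      ring <- seq_along(genes)
    }
    if (length(ring) >= 3) {
      for (i in seq_along(ring)) {
        rel[[length(rel) + 1L]] <- c(ring[i], ring[(i %% length(ring)) + 1L])
      }
    }
    # attach DEG leaves to ring nodes
    for (j in seq_along(leaves)) {
      rel[[length(rel) + 1L]] <- c(ring[j], length(genes) + j)
    }
    xml <- c(sprintf('<pathway name="path:%s" title="simulated pathway %d">',
                     pid, pw),
             sprintf('  <entry id="%d" type="gene" name="%s"/>', eid, entries),
             unlist(lapply(rel, function(e) {
               sprintf(paste0('  <relation entry1="%d" entry2="%d" ',
                              'type="PPrel"><subtype name="activation"/>',
                              '</relation>'), e[1], e[2])
             })),
             "</pathway>")
    files[pw] <- file.path(dir, paste0(pid, ".xml"))
    writeLines(xml, files[pw])
    node_counts[pw] <- length(entries)
    edge_counts[pw] <- length(rel)
  }
  list(files = files, hub_genes = hub_genes, leaf_deg_genes = leaf_used,
       node_counts = node_counts, edge_counts = edge_counts)
}

#' Simulate a gene-set collection with one planted enriched term
#'
#' Random terms drawn from the universe plus one term constructed to
#' overlap the query far above chance.
#'
#' @param universe Character vector of background gene ids.
#' @param query Character vector the planted term should be enriched in.
#' @param n_terms Total number of terms.
#' @param term_size Members per term.
#' @param enriched_overlap Query members planted into the enriched term
#'   (capped at `min(term_size, length(query))`).
#' @return A [gene_set_collection()]; the planted term is `term_enriched`.
#' @export
simulate_gene_sets <- function(universe, query, n_terms = 20L,
                               term_size = 50L, enriched_overlap = 25L) {
  .check(length(universe) >= term_size, "universe smaller than term_size")
  k <- min(enriched_overlap, term_size, length(query))
  planted <- c(sample(intersect(query, universe), k),
               sample(setdiff(universe, query), term_size - k))
  ids <- c("term_enriched", sprintf("term_%03d", seq_len(n_terms - 1L)))
  members <- c(list(sort(planted)),
               lapply(seq_len(n_terms - 1L),
                      function(i) sort(sample(universe, term_size))))
  gene_set_collection(ids, c("planted enriched term",
                             sprintf("random term %d", seq_len(n_terms - 1L))),
                      members)
}

#' Simulate a PPI background with planted interacting pairs
#'
#' Random background edges among `ppi_background_genes` bystander genes plus
#' planted seed-seed edges pairing up the given seed genes; locations place
#' the two members of every planted pair on different chromosomes.
#'
#' @param config A [sim_config()].
#' @param seeds Character vector of validated DEG gene ids (>= 2).
#' @return List with `ppi` (edge data frame `a`, `b`), `locations`
#'   (BED-like data frame), and `planted_pairs` (data frame `a`, `b`).
#' @export
simulate_ppi_and_locations <- function(config, seeds) {
  .check(inherits(config, "sim_config"), "config must be a sim_config")
  seeds <- unique(as.character(seeds))
  .check(length(seeds) >= 2, "need at least 2 seed genes")
  set.seed(.child_seed(config$seed, 53L))
  bg_genes <- sprintf("ppi_bg%04d", seq_len(config$ppi_background_genes))

  # planted seed-seed pairs: consecutive disjoint pairs
  n_pair <- length(seeds) %/% 2
  planted <- data.frame(a = seeds[2 * seq_len(n_pair) - 1],
                        b = seeds[2 * seq_len(n_pair)],
                        stringsAsFactors = FALSE)

  pool <- c(bg_genes, seeds)
  a <- sample(pool, config$ppi_background_edges, replace = TRUE)
  b <- sample(bg_genes, config$ppi_background_edges, replace = TRUE)
  keep <- a != b
  edges <- rbind(planted, data.frame(a = a[keep], b = b[keep],
                                     stringsAsFactors = FALSE))
  lo <- pmin(edges$a, edges$b); hi <- pmax(edges$a, edges$b)
  keep <- !duplicated(paste(lo, hi, sep = "\r"))
  ppi <- data.frame(a = lo[keep], b = hi[keep], stringsAsFactors = FALSE)

  genes <- c(seeds, bg_genes)
  chroms <- paste0("chr", c(1:22, "X"))
  chrom <- sample(chroms, length(genes), replace = TRUE)
  names(chrom) <- genes
  # force each planted pair onto different chromosomes
  for (i in seq_len(nrow(planted))) {
    if (chrom[planted$a[i]] == chrom[planted$b[i]]) {
      chrom[planted$b[i]] <- sample(setdiff(chroms, chrom[planted$a[i]]), 1)
    }
  }
  start <- sample.int(2e8, length(genes))
  locations <- data.frame(gene_id = genes, chromosome = unname(chrom),
                          start = start, end = start + sample.int(2e5, length(genes)),
                          stringsAsFactors = FALSE)
  list(ppi = ppi, locations = locations, planted_pairs = planted)
}

#' Simulate clinical phenotypes with planted Spearman correlations
#'
#' For a designated target gene, per-patient expression is generated
#' log-normally and each phenotype is derived from a Gaussian copula of the
#' expression's normal scores: the latent correlation is calibrated as
#' `2*sin(pi*rho_s/6)` so the population Spearman correlation of the
#' *continuous* latent pair equals the planted value; ordinal phenotypes
#' are then obtained by thresholding the latent variable, which attenuates
#' the realised correlation slightly (more for the binary node/metastasis
#' codes than for the 4-level sizes and stages).
#'
#' @param config A [sim_config()]; `planted_rho` gives the per-phenotype
#'   targets.
#' @param target_gene Gene id the correlations are planted on.
#' @param other_genes Optional further gene ids simulated as null
#'   (uncorrelated) expression.
#' @return List with `expr` (gene x patient matrix), `clinical` (a
#'   `clinical_table` with `tumor_cm`, `t`, `n`, `m`, `stage`), and
#'   `planted_rho`.
#' @export
simulate_clinical <- function(config, target_gene = "g0001",
                              other_genes = character()) {
  .check(inherits(config, "sim_config"), "config must be a sim_config")
  set.seed(.child_seed(config$seed, 71L))
  n <- config$n_clinical_samples
  patients <- sprintf("p%04d", seq_len(n))
  x <- exp(stats::rnorm(n, log(30), 0.8))
  u <- stats::qnorm((rank(x) - 0.5) / n)

  latent <- function(rho_s) {
    rho_l <- 2 * sin(pi * rho_s / 6)
    rho_l * u + sqrt(1 - rho_l^2) * stats::rnorm(n)
  }
  cutq <- function(z, probs) {
    # threshold a latent normal into ordinal codes with given mass per level
    cuts <- stats::quantile(z, cumsum(probs)[-length(probs)])
    findInterval(z, cuts) + 1L
  }
  rho <- config$planted_rho
  z_size <- latent(rho[["tumor_size"]] %||% 0)
  t_cat <- cutq(z_size, c(0.7, 0.15, 0.1, 0.05))
  tumor_cm <- round(stats::qlnorm(stats::pnorm(z_size), log(1.3), 0.4), 2)
  n_cat <- cutq(latent(rho[["node"]] %||% 0), c(0.55, 0.45)) - 1L
  m_cat <- cutq(latent(rho[["metastasis"]] %||% 0), c(0.93, 0.07)) - 1L
  stage_cat <- cutq(latent(rho[["stage"]] %||% 0), c(0.6, 0.2, 0.12, 0.08))

  clinical <- data.frame(patient_id = patients, age = round(stats::rnorm(n, 47, 12)),
                         tumor_cm = tumor_cm, t = t_cat, n = n_cat,
                         m = m_cat, stage = stage_cat,
                         stringsAsFactors = FALSE)
  class(clinical) <- c("clinical_table", "data.frame")

  expr <- matrix(x, 1, n, dimnames = list(target_gene, patients))
  if (length(other_genes) > 0) {
    null_expr <- matrix(exp(stats::rnorm(length(other_genes) * n, log(30), 0.8)),
                        length(other_genes), n,
                        dimnames = list(other_genes, patients))
    expr <- rbind(expr, null_expr)
  }
  list(expr = expr, clinical = clinical, planted_rho = rho)
}
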