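# PPI subnetwork extraction around validated DEGs and cis/trans chromosome
# co-location classification of interacting pairs.

#' Extract the PPI subnetwork around seed genes
#'
#' Returns the direct (seed-seed) interaction edges and, when
#' `include_neighbors`, the seed-neighbor edges with first-neighbor roles
#' marked. Neighbor-neighbor edges are never included.
#'
#' @param background PPI edge list: data frame with columns `a`, `b`
#'   (as from [read_ppi()]).
#' @param seeds Character vector of seed (validated DEG) gene ids.
#' @param include_neighbors Include first-neighbor edges (default `TRUE`).
#' @return List with `edges` (columns `a`, `b`, `kind` =
#'   `"seed-seed"`/`"seed-neighbor"`) and `roles` (columns `gene_id`, `role`
#'   = `"seed"`/`"neighbor"`). Empty with a warning when no seed occurs in
#'   the background.
#' @export
extract_subnetwork <- function(background, seeds, include_neighbors = TRUE) {
  .check(is.data.frame(background) && all(c("a", "b") %in% names(background)),
         "background must be an edge-list data frame with columns a, b")
  .check(nrow(background) > 0, "background network is empty")
  seeds <- unique(as.character(seeds))
  in_a <- background$a %in% seeds
  in_b <- background$b %in% seeds
  if (!any(in_a | in_b)) {
    warning("no seed gene found in the PPI background", call. = FALSE)
    return(list(edges = data.frame(a = character(), b = character(),
                                   kind = character(),
                                   stringsAsFactors = FALSE),
                roles = data.frame(gene_id = character(), role = character(),
                                   stringsAsFactors = FALSE)))
  }
  ss <- background[in_a & in_b, c("a", "b"), drop = FALSE]
  ss$kind <- rep("seed-seed", nrow(ss))
  edges <- ss
  if (include_neighbors) {
    sn <- background[xor(in_a, in_b), c("a", "b"), drop = FALSE]
    if (nrow(sn) > 0) {
      sn$kind <- "seed-neighbor"
      edges <- rbind(edges, sn)
    }
  }
  edges <- edges[order(edges$a, edges$b), , drop = FALSE]
  rownames(edges) <- NULL
  members <- unique(c(edges$a, edges$b))
  roles <- data.frame(gene_id = sort(members),
                      stringsAsFactors = FALSE)
  roles$role <- ifelse(roles$gene_id %in% seeds, "seed", "neighbor")
  list(edges = edges, roles = roles)
}

#' Classify interacting gene pairs by chromosome co-location
#'
#' Each (unordered) pair is labelled `same_chromosome` or
#' `different_chromosomes` by chromosome-label equality, or `unknown` when
#' either gene lacks a location record — the substrate of the cis/trans
#' co-regulation argument.
#'
#' @param pairs Data frame with columns `a`, `b` (e.g. the seed-seed edges
#'   of [extract_subnetwork()]).
#' @param locations Gene-location table from [read_gene_locations()].
#' @return Data frame `gene_a`, `gene_b`, `chrom_a`, `chrom_b`, `colocation`.
#' @export
classify_pairs <- function(pairs, locations) {
  .check(all(c("a", "b") %in% names(pairs)), "pairs needs columns a, b")
  ca <- locations$chromosome[match(pairs$a, locations$gene_id)]
  cb <- locations$chromosome[match(pairs$b, locations$gene_id)]
  coloc <- ifelse(is.na(ca) | is.na(cb), "unknown",
                  ifelse(ca == cb, "same_chromosome", "different_chromosomes"))
  data.frame(gene_a = pairs$a, gene_b = pairs$b,
             chrom_a = ca, chrom_b = cb, colocation = coloc,
             stringsAsFactors = FALSE)
}

#' Circos-compatible link records for interacting pairs
#'
#' One row per pair with located endpoints:
#' `chrom_a start_a end_a chrom_b start_b end_b`. Pairs with a missing
#' location are dropped with a message.
#'
#' @param pairs Data frame with columns `a`, `b`.
#' @param locations Gene-location table from [read_gene_locations()].
#' @return Data frame of link records.
#' @export
circos_links <- function(pairs, locations) {
  ia <- match(pairs$a, locations$gene_id)
  ib <- match(pairs$b, locations$gene_id)
  drop <- is.na(ia) | is.na(ib)
  if (any(drop)) {
    message(sprintf("circos_links: dropped %d pair(s) without locations",
                    sum(drop)))
  }
  ia <- ia[!drop]; ib <- ib[!drop]
  data.frame(chrom_a = locations$chromosome[ia],
             start_a = locations$start[ia],
             end_a = locations$end[ia],
             chrom_b = locations$chromosome[ib],
             start_b = locations$start[ib],
             end_b = locations$end[ib],
             stringsAsFactors = FALSE)
}
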