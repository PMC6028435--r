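# KGML-dialect pathway parsing, multi-pathway integration, degree
# computation, and top-decile hub-gene selection.
#
# A node is a pathway "data object": the product of one or more genes. Nodes
# are merged across pathways by their exact (sorted) gene-id set; edges are
# undirected for degree purposes, with relation types and pathway provenance
# kept as metadata.

.node_key <- function(genes) paste(sort(unique(genes)), collapse = "|")

.new_pathway_graph <- function(nodes, edges) {
  structure(list(nodes = nodes, edges = edges), class = "pathway_graph")
}

#' @export
print.pathway_graph <- function(x, ...) {
  cat(sprintf("pathway_graph: %d nodes, %d edges, %d pathway(s)\n",
              nrow(x$nodes), nrow(x$edges),
              length(unique(unlist(x$nodes$pathways)))))
  invisible(x)
}

#' Parse a single KGML-dialect pathway file
#'
#' Supported subset of the KEGG KGML schema: `entry` elements with `@id`,
#' `@type` and `@name` (space-separated gene ids), `group` entries whose
#' `component` children reference other entries, and `relation` elements with
#' `@entry1`, `@entry2` and `subtype/@name`. Gene-type entries become nodes
#' keyed by their sorted gene-id set. Relations touching a group are
#' replicated to each component (recursively for nested groups). Non-gene
#' entries (`compound`, `map`, ...) and `maplink` relations are dropped with
#' a message; a relation referencing an undefined entry id is an error.
#'
#' @param path KGML XML file path.
#' @param pathway_id Pathway label recorded on nodes/edges; defaults to the
#'   `<pathway name=...>` attribute, falling back to the file name.
#' @return A `pathway_graph` for this single pathway.
#' @export
parse_pathway <- function(path, pathway_id = NULL) {
  doc <- xml2::read_xml(path)
  root <- xml2::xml_find_first(doc, "/pathway")
  .check(!inherits(root, "xml_missing"), "not a pathway XML file: %s", path)
  if (is.null(pathway_id)) {
    pathway_id <- xml2::xml_attr(root, "name")
    if (is.na(pathway_id)) pathway_id <- basename(path)
  }

  entries <- xml2::xml_find_all(doc, "/pathway/entry")
  ids <- xml2::xml_attr(entries, "id")
  types <- xml2::xml_attr(entries, "type")
  names_attr <- xml2::xml_attr(entries, "name")
  .check(!anyDuplicated(ids), "duplicate entry id in %s", path)

  genes_of <- stats::setNames(
    lapply(seq_along(entries), function(i) {
      if (identical(types[i], "gene")) {
        strsplit(trimws(names_attr[i]), "\\s+")[[1]]
      } else character()
    }), ids)
  components <- stats::setNames(
    lapply(entries, function(e) {
      xml2::xml_attr(xml2::xml_find_all(e, "component"), "id")
    }), ids)

  dropped <- ids[!(types %in% c("gene", "group"))]
  if (length(dropped) > 0) {
    message(sprintf("%s: dropped %d non-gene entr%s (types: %s)",
                    pathway_id, length(dropped),
                    if (length(dropped) == 1) "y" else "ies",
                    paste(unique(types[!(types %in% c("gene", "group"))]),
                          collapse = ", ")))
  }

  # recursively expand an entry id to the gene-type entry ids it stands for
  expand <- function(id, depth = 0) {
    .check(depth < 50, "group nesting too deep at entry %s", id)
    i <- match(id, ids)
    .check(!is.na(i), "relation references missing entry id %s in %s", id, path)
    if (identical(types[i], "group")) {
      unlist(lapply(components[[id]], expand, depth = depth + 1))
    } else if (identical(types[i], "gene")) {
      id
    } else {
      character() # compound/map entries vanish, taking their relations along
    }
  }

  node_ids <- ids[types == "gene" & vapply(genes_of[ids], length, 1L) > 0]
  keys <- vapply(genes_of[node_ids], .node_key, "")
  # entries with identical gene sets collapse already within one pathway
  uniq <- !duplicated(keys)
  nodes <- data.frame(node_key = keys[uniq], stringsAsFactors = FALSE)
  nodes$genes <- I(lapply(genes_of[node_ids[uniq]], function(g) sort(unique(g))))
  nodes$pathways <- I(rep(list(pathway_id), nrow(nodes)))
  key_of_entry <- stats::setNames(keys, node_ids)

  relations <- xml2::xml_find_all(doc, "/pathway/relation")
  edge_rows <- list()
  n_dropped_rel <- 0L
  for (r in relations) {
    subtypes <- xml2::xml_attr(xml2::xml_find_all(r, "subtype"), "name")
    subtypes <- subtypes[!is.na(subtypes)]
    rel_type <- xml2::xml_attr(r, "type")
    if ("maplink" %in% subtypes ||
        (!is.na(rel_type) && identical(rel_type, "maplink"))) {
      n_dropped_rel <- n_dropped_rel + 1L
      next
    }
    e1 <- expand(xml2::xml_attr(r, "entry1"))
    e2 <- expand(xml2::xml_attr(r, "entry2"))
    if (length(e1) == 0 || length(e2) == 0) {
      n_dropped_rel <- n_dropped_rel + 1L
      next
    }
    for (a in e1) for (b in e2) {
      ka <- key_of_entry[[a]]; kb <- key_of_entry[[b]]
      if (identical(ka, kb)) next # self-loop after merge
      edge_rows[[length(edge_rows) + 1L]] <-
        list(a = min(ka, kb), b = max(ka, kb),
             relations = if (length(subtypes)) subtypes else "unspecified")
    }
  }
  if (n_dropped_rel > 0) {
    message(sprintf("%s: dropped %d relation(s) (maplink or non-gene endpoint)",
                    pathway_id, n_dropped_rel))
  }

  if (length(edge_rows) > 0) {
    a <- vapply(edge_rows, `[[`, "", "a")
    b <- vapply(edge_rows, `[[`, "", "b")
    pair <- paste(a, b, sep = "\r")
    uniq_e <- !duplicated(pair)
    rel <- lapply(split(seq_along(pair), pair)[unique(pair[uniq_e])],
                  function(ix) sort(unique(unlist(
                    lapply(edge_rows[ix], `[[`, "relations")))))
    edges <- data.frame(a = a[uniq_e], b = b[uniq_e], stringsAsFactors = FALSE)
    edges$relations <- I(unname(rel[paste(edges$a, edges$b, sep = "\r")]))
    edges$pathways <- I(rep(list(pathway_id), nrow(edges)))
  } else {
    edges <- data.frame(a = character(), b = character(),
                        stringsAsFactors = FALSE)
    edges$relations <- I(list())
    edges$pathways <- I(list())
  }
  .new_pathway_graph(nodes, edges)
}

#' Integrate parsed pathways into one network
#'
#' Nodes are merged across pathways by identical gene-id set; edges are
#' deduplicated by unordered endpoint pair. Relation types and pathway
#' provenance are unioned. Node degree (number of distinct incident edges in
#' the simple undirected graph) is computed on the integrated network.
#'
#' @param graphs List of `pathway_graph` objects from [parse_pathway()].
#' @return Integrated `pathway_graph`; `nodes` gains `degree` and an
#'   unset `is_deg` column (see [mark_degs()]).
#' @export
integrate_pathways <- function(graphs) {
  if (inherits(graphs, "pathway_graph")) graphs <- list(graphs)
  .check(length(graphs) >= 1, "need at least one parsed pathway")
  .check(all(vapply(graphs, inherits, TRUE, "pathway_graph")),
         "all inputs must be pathway_graph objects")

  all_nodes <- do.call(rbind, lapply(graphs, `[[`, "nodes"))
  key_order <- sort(unique(all_nodes$node_key))
  nodes <- data.frame(node_key = key_order, stringsAsFactors = FALSE)
  idx <- split(seq_len(nrow(all_nodes)), all_nodes$node_key)
  nodes$genes <- I(lapply(key_order, function(k)
    sort(unique(unlist(all_nodes$genes[idx[[k]]])))))
  nodes$pathways <- I(lapply(key_order, function(k)
    sort(unique(unlist(all_nodes$pathways[idx[[k]]])))))

  all_edges <- do.call(rbind, lapply(graphs, `[[`, "edges"))
  if (!is.null(all_edges) && nrow(all_edges) > 0) {
    pair <- paste(all_edges$a, all_edges$b, sep = "\r")
    pair_order <- sort(unique(pair))
    eidx <- split(seq_len(nrow(all_edges)), pair)
    edges <- data.frame(
      a = vapply(eidx[pair_order], function(ix) all_edges$a[ix[1]], ""),
      b = vapply(eidx[pair_order], function(ix) all_edges$b[ix[1]], ""),
      stringsAsFactors = FALSE)
    edges$relations <- I(lapply(eidx[pair_order], function(ix)
      sort(unique(unlist(all_edges$relations[ix])))))
    edges$pathways <- I(lapply(eidx[pair_order], function(ix)
      sort(unique(unlist(all_edges$pathways[ix])))))
    rownames(edges) <- NULL
    endpoint_missing <- setdiff(c(edges$a, edges$b), nodes$node_key)
    .check(length(endpoint_missing) == 0, "edge endpoint without node: %s",
           paste(endpoint_missing, collapse = ", "))
  } else {
    edges <- data.frame(a = character(), b = character(),
                        stringsAsFactors = FALSE)
    edges$relations <- I(list())
    edges$pathways <- I(list())
  }

  g <- igraph::graph_from_data_frame(edges[, c("a", "b")], directed = FALSE,
                                     vertices = nodes$node_key)
  deg <- igraph::degree(g, loops = FALSE)
  nodes$degree <- as.integer(deg[nodes$node_key])
  nodes$is_deg <- NA
  rownames(nodes) <- NULL
  .new_pathway_graph(nodes, edges)
}

#' Mark nodes containing differentially expressed genes
#'
#' @param graph Integrated `pathway_graph`.
#' @param degs Character vector of DEG gene ids.
#' @return The graph with `nodes$is_deg` set: `TRUE` iff the node's gene set
#'   intersects `degs`.
#' @export
mark_degs <- function(graph, degs) {
  .check(inherits(graph, "pathway_graph"), "graph must be a pathway_graph")
  degs <- as.character(degs)
  graph$nodes$is_deg <- vapply(graph$nodes$genes,
                               function(g) any(g %in% degs), TRUE)
  graph
}

#' Select hub DEG nodes in the top degree decile
#'
#' Nodes are ranked by degree (descending); the cutoff rank is
#' `k = ceiling(top_fraction * |V|)` and, with `ties = "include"` (default),
#' every node whose degree reaches the k-th ranked node's degree is in the
#' top set. Hub nodes are the top-set nodes marked as containing DEGs; the
#' hub gene list is the union of their DEG genes, split by direction when a
#' direction table is supplied.
#'
#' @param graph Integrated `pathway_graph` after [mark_degs()].
#' @param top_fraction Fraction of nodes forming the top set (default 0.10).
#' @param deg_directions Optional data frame `gene_id`, `direction`
#'   (`"up"`/`"down"`) used to restrict hub genes to DEGs and split them.
#' @param ties `"include"` (boundary ties enter the top set) or `"exclude"`
#'   (exactly `k` nodes, ties broken by node key).
#' @return List with `top_nodes` (node table of the top set), `hub_nodes`
#'   (its DEG-marked subset), `hub_genes`, `up_genes`, `down_genes`, and
#'   `cutoff_degree`.
#' @export
select_hub_degs <- function(graph, top_fraction = 0.10, deg_directions = NULL,
                            ties = c("include", "exclude")) {
  ties <- match.arg(ties)
  .check(inherits(graph, "pathway_graph"), "graph must be a pathway_graph")
  .check(nrow(graph$nodes) > 0, "empty graph")
  .check(top_fraction > 0 && top_fraction <= 1,
         "top_fraction must be in (0, 1]")
  .check(!anyNA(graph$nodes$is_deg), "run mark_degs() before hub selection")

  nodes <- graph$nodes
  ord <- order(-nodes$degree, nodes$node_key)
  nodes <- nodes[ord, , drop = FALSE]
  k <- ceiling(top_fraction * nrow(nodes))
  cutoff <- nodes$degree[k]
  top <- if (ties == "include") {
    nodes[nodes$degree >= cutoff, , drop = FALSE]
  } else {
    nodes[seq_len(k), , drop = FALSE]
  }
  hub <- top[top$is_deg, , drop = FALSE]
  genes <- sort(unique(unlist(hub$genes)))
  up <- down <- character()
  if (!is.null(deg_directions)) {
    genes <- intersect(genes, deg_directions$gene_id)
    up <- intersect(genes,
                    deg_directions$gene_id[deg_directions$direction == "up"])
    down <- intersect(genes,
                      deg_directions$gene_id[deg_directions$direction == "down"])
  }
  list(top_nodes = top, hub_nodes = hub, hub_genes = genes,
       up_genes = up, down_genes = down, cutoff_degree = cutoff)
}

#' Export a pathway graph as Cytoscape-importable node and edge tables
#'
#' Node TSV columns, in order: `node_key`, `genes` (';'-joined),
#' `degree`, `is_deg`, `pathways` (';'-joined). Edge TSV columns:
#' `a`, `b`, `relations` (';'-joined), `pathways` (';'-joined). Rows are
#' sorted by key so output is byte-stable for identical graphs.
#'
#' @param graph Integrated `pathway_graph`.
#' @param node_path,edge_path Output TSV paths.
#' @return Invisibly, `c(node_path, edge_path)`.
#' @export
write_network_tables <- function(graph, node_path, edge_path) {
  .check(inherits(graph, "pathway_graph"), "graph must be a pathway_graph")
  join <- function(lst) vapply(lst, function(v) paste(v, collapse = ";"), "")
  nd <- graph$nodes[order(graph$nodes$node_key), , drop = FALSE]
  nodes <- data.frame(node_key = nd$node_key,
                      genes = join(nd$genes),
                      degree = nd$degree,
                      is_deg = nd$is_deg,
                      pathways = join(nd$pathways),
                      stringsAsFactors = FALSE)
  ed <- graph$edges[order(graph$edges$a, graph$edges$b), , drop = FALSE]
  edges <- data.frame(a = ed$a, b = ed$b,
                      relations = join(ed$relations),
                      pathways = join(ed$pathways),
                      stringsAsFactors = FALSE)
  .write_tsv(nodes, node_path)
  .write_tsv(edges, edge_path)
  invisible(c(node_path, edge_path))
}
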