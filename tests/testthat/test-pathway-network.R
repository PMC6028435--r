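entries2 <- list(list(id = "1", type = "gene", name = "A"),
                 list(id = "2", type = "gene", name = "B"))

test_that("a minimal pathway parses to the expected nodes and edges", {
  f <- write_kgml(entries2, list(list("1", "2")))
  g <- parse_pathway(f)
  expect_equal(nrow(g$nodes), 2)
  expect_equal(nrow(g$edges), 1)
  expect_equal(sort(g$nodes$node_key), c("A", "B"))
  expect_equal(g$edges$relations[[1]], "activation")
})

test_that("group entries expand their relations to every component", {
  entries <- c(entries2,
               list(list(id = "3", type = "gene", name = "C"),
                    list(id = "4", type = "group", components = c("1", "2"))))
  f <- write_kgml(entries, list(list("4", "3")))
  g <- parse_pathway(f)
  expect_equal(nrow(g$edges), 2)
  expect_setequal(paste(g$edges$a, g$edges$b), c("A C", "B C"))
})

test_that("map/compound entries and maplink relations are dropped", {
  entries <- c(entries2, list(list(id = "9", type = "map", name = "path:x")))
  f <- write_kgml(entries, list(list("1", "9"), list("1", "2")))
  expect_message(g <- parse_pathway(f), "dropped")
  expect_equal(nrow(g$nodes), 2)
  expect_equal(nrow(g$edges), 1)

  f2 <- write_kgml(entries2, list(list("1", "2", "maplink")))
  g2 <- suppressMessages(parse_pathway(f2))
  expect_equal(nrow(g2$edges), 0)

  f3 <- write_kgml(entries2, list(list("1", "99")))
  expect_error(parse_pathway(f3), "missing entry id 99")
})

test_that("multi-gene entries merge by exact gene set, and duplicate edges union metadata", {
  entries <- list(list(id = "1", type = "gene", name = "B A"),
                  list(id = "2", type = "gene", name = "A B"),
                  list(id = "3", type = "gene", name = "C"))
  f <- write_kgml(entries, list(list("1", "3"), list("2", "3", "inhibition")))
  g <- parse_pathway(f)
  expect_equal(nrow(g$nodes), 2)  # "A|B" and "C"
  expect_equal(nrow(g$edges), 1)
  expect_setequal(g$edges$relations[[1]], c("activation", "inhibition"))
})

test_that("integration deduplicates, unions provenance and counts degree", {
  f <- write_kgml(entries2, list(list("1", "2")), name = "path:P1")
  f2 <- write_kgml(entries2, list(list("1", "2")), name = "path:P2")
  g <- integrate_pathways(list(parse_pathway(f), parse_pathway(f2)))
  expect_equal(nrow(g$nodes), 2)
  expect_equal(nrow(g$edges), 1)
  expect_setequal(g$edges$pathways[[1]], c("path:P1", "path:P2"))

  # shared node with one unique edge per pathway -> degree 2
  fa <- write_kgml(entries2, list(list("1", "2")), name = "path:A")
  fb <- write_kgml(list(list(id = "1", type = "gene", name = "A"),
                        list(id = "2", type = "gene", name = "C")),
                   list(list("1", "2")), name = "path:B")
  gab <- integrate_pathways(list(parse_pathway(fa), parse_pathway(fb)))
  expect_equal(gab$nodes$degree[gab$nodes$node_key == "A"], 2L)

  # disjoint pathways add their node/edge counts
  fc_ <- write_kgml(list(list(id = "1", type = "gene", name = "X"),
                         list(id = "2", type = "gene", name = "Y"),
                         list(id = "3", type = "gene", name = "Z")),
                    list(list("1", "2"), list("2", "3")), name = "path:C")
  g3 <- integrate_pathways(list(parse_pathway(fa), parse_pathway(fb),
                                parse_pathway(fc_)))
  expect_equal(nrow(g3$nodes), 3 + 3)
  expect_equal(nrow(g3$edges), 2 + 2)
})

test_that("integration is idempotent and input-order invariant", {
  cfg <- sim_config(seed = 5)
  disc <- suppressMessages(simulate_paired_discovery(cfg))
  pw <- simulate_pathways(cfg, disc$truth, withr::local_tempdir())
  graphs <- lapply(pw$files, parse_pathway)
  g1 <- integrate_pathways(graphs)
  g2 <- integrate_pathways(g1)           # re-integrating the integrated graph
  expect_equal(g1$nodes[, c("node_key", "degree")],
               g2$nodes[, c("node_key", "degree")])
  expect_equal(g1$edges[, c("a", "b")], g2$edges[, c("a", "b")])
  g3 <- integrate_pathways(rev(graphs))
  expect_equal(g1$nodes, g3$nodes)
  expect_equal(g1$edges, g3$edges)
})

test_that("degrees agree with brute-force incidence counts on random graphs", {
  set.seed(21)
  for (rep in 1:5) {
    n <- sample(20:200, 1)
    ids <- sprintf("n%03d", seq_len(n))
    m <- sample(n:(3 * n), 1)
    ends <- cbind(sample(ids, m, TRUE), sample(ids, m, TRUE))
    entries <- lapply(seq_len(n), function(i)
      list(id = as.character(i), type = "gene", name = ids[i]))
    rels <- lapply(seq_len(m), function(j)
      list(as.character(match(ends[j, 1], ids)),
           as.character(match(ends[j, 2], ids))))
    f <- write_kgml(entries, rels)
    g <- integrate_pathways(parse_pathway(f))
    expect_identical(g$nodes$degree,
                     unname(oracle_degrees(g)[g$nodes$node_key]))
  }
})

test_that("deg marking is by gene-set intersection", {
  entries <- list(list(id = "1", type = "gene", name = "A B"),
                  list(id = "2", type = "gene", name = "C"))
  f <- write_kgml(entries, list(list("1", "2")))
  g <- integrate_pathways(parse_pathway(f))
  m <- mark_degs(g, "B")
  expect_true(m$nodes$is_deg[m$nodes$node_key == "A|B"])
  expect_false(m$nodes$is_deg[m$nodes$node_key == "C"])
  expect_false(any(mark_degs(g, character())$nodes$is_deg))
})

test_that("hub selection applies the ceiling cutoff with boundary ties", {
  star_graph <- function(degrees) {
    # build a graph with prescribed approximate degree sequence via stars
    entries <- list(); rels <- list(); id <- 0
    for (i in seq_along(degrees)) {
      id <- id + 1; hub_id <- id
      entries[[hub_id]] <- list(id = as.character(hub_id), type = "gene",
                                name = sprintf("hub%02d", i))
      for (j in seq_len(degrees[i])) {
        id <- id + 1
        entries[[id]] <- list(id = as.character(id), type = "gene",
                              name = sprintf("leaf%02d_%02d", i, j))
        rels[[length(rels) + 1]] <- list(as.character(hub_id),
                                         as.character(id))
      }
    }
    integrate_pathways(parse_pathway(write_kgml(entries, rels)))
  }
  # unique maximum: only the degree-9 hub is in the top set (k = 1 at 10%)
  g <- star_graph(c(9))                        # 10 nodes: hub + 9 leaves
  g <- mark_degs(g, character())
  sel <- select_hub_degs(g, 0.10)
  expect_equal(sel$top_nodes$node_key, "hub01")
  expect_equal(sel$cutoff_degree, 9L)

  # boundary ties: four degree-5 hubs all enter at k = ceiling(0.1 * 24) = 3
  g4 <- mark_degs(star_graph(c(5, 5, 5, 5)), c("hub01", "leaf01_01"))
  sel4 <- select_hub_degs(g4, 0.10)
  expect_setequal(sel4$top_nodes$node_key,
                  c("hub01", "hub02", "hub03", "hub04"))
  # only the DEG-marked top node contributes hub genes; the DEG leaf is
  # below the cutoff and excluded
  expect_equal(sel4$hub_nodes$node_key, "hub01")
  expect_equal(sel4$hub_genes, "hub01")

  # ties can be excluded to return exactly k nodes
  sel_ex <- select_hub_degs(g4, 0.10, ties = "exclude")
  expect_equal(nrow(sel_ex$top_nodes), 3)
})

test_that("top_fraction = 1 returns exactly the DEG-marked nodes as hubs", {
  cfg <- sim_config(seed = 6)
  disc <- suppressMessages(simulate_paired_discovery(cfg))
  pw <- simulate_pathways(cfg, disc$truth, withr::local_tempdir())
  g <- mark_degs(integrate_pathways(lapply(pw$files, parse_pathway)),
                 disc$truth$gene_id)
  sel <- select_hub_degs(g, 1)
  expect_setequal(sel$hub_nodes$node_key,
                  g$nodes$node_key[g$nodes$is_deg])
})

test_that("network export writes importable, byte-stable tables", {
  f <- write_kgml(entries2, list(list("1", "2")))
  g <- mark_degs(integrate_pathways(parse_pathway(f)), "A")
  d <- withr::local_tempdir()
  write_network_tables(g, file.path(d, "n.tsv"), file.path(d, "e.tsv"))
  nd <- read.delim(file.path(d, "n.tsv"))
  expect_equal(names(nd), c("node_key", "genes", "degree", "is_deg", "pathways"))
  expect_equal(nd$degree, c(1L, 1L))
  ed <- read.delim(file.path(d, "e.tsv"))
  expect_equal(names(ed), c("a", "b", "relations", "pathways"))
})
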