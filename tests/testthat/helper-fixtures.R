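# Shared fixtures and independent brute-force oracles.

# tiny paired RPKM set from explicit tumor/adjacent matrices
make_pes <- function(tumor, adjacent, genes = NULL) {
  n_pairs <- ncol(tumor)
  if (is.null(genes)) genes <- sprintf("gene%02d", seq_len(nrow(tumor)))
  values <- matrix(0, nrow(tumor), 2 * n_pairs)
  samples <- as.vector(rbind(paste0(seq_len(n_pairs), "ca"),
                             paste0(seq_len(n_pairs), "adj")))
  colnames(values) <- samples
  rownames(values) <- genes
  for (p in seq_len(n_pairs)) {
    values[, paste0(p, "ca")] <- tumor[, p]
    values[, paste0(p, "adj")] <- adjacent[, p]
  }
  paired_expression_set(values, unit = "rpkm")
}

# brute-force re-evaluation of the per-pair screen rule, gene by gene
oracle_screen <- function(tumor, adjacent, fc = 1.5, diff = 10) {
  dir <- character(nrow(tumor))
  for (g in seq_len(nrow(tumor))) {
    up <- down <- TRUE
    for (p in seq_len(ncol(tumor))) {
      ca <- tumor[g, p]; adj <- adjacent[g, p]
      fc_up <- if (adj == 0) ca > 0 else ca / adj > fc
      fc_dn <- if (ca == 0) adj > 0 else adj / ca > fc
      up <- up && fc_up && (ca - adj > diff)
      down <- down && fc_dn && (adj - ca > diff)
    }
    dir[g] <- if (up) "up" else if (down) "down" else "ns"
  }
  dir
}

# exhaustive hypergeometric upper tail: sum the pmf over j = k..min(K, n)
oracle_hyper_tail <- function(N, K, n, k) {
  j <- k:min(K, n)
  if (k > min(K, n)) return(0)
  sum(choose(K, j) * choose(N - K, n - j)) / choose(N, n)
}

# hand step-up BH: p * m / rank, cumulative min from the largest rank
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  pmin(1, cummin(p[o] * m / (m:1)))[ro]
}

# rank-then-Pearson Spearman oracle with explicit mid-ranks
oracle_spearman <- function(x, y) {
  midrank <- function(v) {
    r <- numeric(length(v))
    for (i in seq_along(v)) r[i] <- mean(which(sort(v) == v[i]))
    r
  }
  rx <- midrank(x); ry <- midrank(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# degree by brute-force incidence count over the edge table
oracle_degrees <- function(graph) {
  vapply(graph$nodes$node_key, function(k)
    sum(graph$edges$a == k | graph$edges$b == k), 1L)
}

# minimal KGML document from entry/relation specs
kgml_string <- function(entries, relations, name = "path:test") {
  ent <- vapply(entries, function(e) {
    if (identical(e$type, "group")) {
      sprintf('<entry id="%s" type="group" name="undefined">%s</entry>',
              e$id, paste(sprintf('<component id="%s"/>', e$components),
                          collapse = ""))
    } else {
      sprintf('<entry id="%s" type="%s" name="%s"/>', e$id, e$type, e$name)
    }
  }, "")
  rel <- vapply(relations, function(r) {
    sprintf('<relation entry1="%s" entry2="%s" type="%s"><subtype name="%s"/></relation>',
            r[[1]], r[[2]], if (length(r) >= 4) r[[4]] else "PPrel",
            if (length(r) >= 3) r[[3]] else "activation")
  }, "")
  paste0(sprintf('<pathway name="%s" title="t">', name),
         paste(ent, collapse = ""), paste(rel, collapse = ""), "</pathway>")
}

write_kgml <- function(entries, relations, name = "path:test") {
  f <- withr::local_tempfile(fileext = ".xml",
                             .local_envir = parent.frame())
  writeLines(kgml_string(entries, relations, name), f)
  f
}
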