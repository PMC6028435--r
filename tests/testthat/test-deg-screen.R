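test_that("rpkm follows the normalization formula", {
  expect_equal(rpkm(1000, 10, 2), 50)
  expect_equal(rpkm(0, 10, 2), 0)
  expect_equal(rpkm(123, 7.5, 1.3), 123 / (7.5 * 1.3))
  expect_error(rpkm(10, 0, 2), "positive")
  expect_error(rpkm(10, 10, -1), "positive")
  expect_error(rpkm(-5, 10, 2), "non-negative")

  counts <- matrix(c(1000, 200, 500, 100), 2,
                   dimnames = list(c("a", "b"), c("s1", "s2")))
  r <- rpkm_matrix(counts, c(10, 5), c(2, 0.5))
  expect_equal(r["a", "s1"], 50)
  expect_equal(r["b", "s2"], 100 / (5 * 0.5))
})

test_that("mapped-gene filter keeps the 0.5 boundary inclusive", {
  tum <- rbind(c(0.5, 0.2), c(0.49, 0.49), c(2, 3))
  adj <- rbind(c(0.1, 0.3), c(0.4, 0.2), c(1, 1))
  x <- make_pes(tum, adj)
  kept <- suppressMessages(filter_mapped(x))
  expect_setequal(rownames(kept$values), c("gene01", "gene03"))

  # all-samples scope drops the gene whose minimum falls below 0.5
  kept_all <- suppressMessages(filter_mapped(x, scope = "all"))
  expect_setequal(rownames(kept_all$values), "gene03")

  # identity when everything clears the threshold
  y <- make_pes(tum + 1, adj + 1)
  expect_identical(suppressMessages(filter_mapped(y))$values, y$values)
})

test_that("screen applies the per-pair fold-change and difference rule", {
  tum <- rbind(c(20, 30, 25), c(20, 30, 25), c(12, 13, 14))
  adj <- rbind(c(5, 8, 10), c(5, 8, 18), c(2, 3, 4))
  x <- make_pes(tum, adj)
  out <- screen_paired(x)
  # gene01: FC 4/3.75/2.5 all > 1.5, diff 15/22/15 all > 10 -> up
  expect_equal(out$gene_id, "gene01")
  expect_equal(out$direction, "up")
  expect_equal(unlist(out[1, c("fc_1", "fc_2", "fc_3")], use.names = FALSE),
               c(4, 3.75, 2.5))
  expect_equal(out$mean_fc, (4 * 3.75 * 2.5)^(1 / 3))
  # gene02 fails pair 3 (FC 25/18 < 1.5); gene03 fails the strict diff
  # rule (diff exactly 10 in pairs 1 and 3)
})

test_that("zero-denominator and both-zero pairs follow the stated rule", {
  tum <- rbind(c(20, 20, 20), c(0, 0, 0))
  adj <- rbind(c(0, 5, 5), c(0, 0, 0))
  out <- screen_paired(make_pes(tum, adj))
  expect_equal(out$gene_id, "gene01")  # Inf ratio passes; 0/0 gene fails
  expect_equal(out$direction, "up")
})

test_that("screen agrees exactly with the brute-force oracle", {
  set.seed(101)
  for (rep in 1:5) {
    n <- 50
    tum <- matrix(round(rexp(n * 3, 1 / 20), 2), n, 3)
    adj <- matrix(round(rexp(n * 3, 1 / 20), 2), n, 3)
    # salt in exact-boundary and zero cases
    tum[1, ] <- adj[1, ] * 1.5          # FC exactly at threshold: not a DEG
    tum[2, ] <- adj[2, ] + 10           # diff exactly at threshold
    adj[3, ] <- 0; tum[3, ] <- c(50, 60, 70)
    tum[4, ] <- 0; adj[4, ] <- 0
    x <- make_pes(tum, adj)
    got <- screen_paired(x)
    want <- oracle_screen(tum, adj)
    genes <- rownames(x$values)
    got_dir <- rep("ns", n)
    got_dir[match(got$gene_id, genes)] <- got$direction
    expect_identical(got_dir, want)
  }
})

test_that("label swap maps up to down exactly", {
  set.seed(7)
  tum <- matrix(rexp(150, 1 / 25), 50, 3)
  adj <- matrix(rexp(150, 1 / 25), 50, 3)
  fwd <- screen_paired(make_pes(tum, adj))
  rev <- screen_paired(make_pes(adj, tum))
  expect_setequal(fwd$gene_id[fwd$direction == "up"],
                  rev$gene_id[rev$direction == "down"])
  expect_setequal(fwd$gene_id[fwd$direction == "down"],
                  rev$gene_id[rev$direction == "up"])
})

test_that("raising either threshold never adds a DEG", {
  set.seed(8)
  tum <- matrix(rexp(150, 1 / 25), 50, 3)
  adj <- matrix(rexp(150, 1 / 25), 50, 3)
  x <- make_pes(tum, adj)
  base <- screen_paired(x)$gene_id
  for (fc in c(1.6, 2, 3)) {
    expect_true(all(screen_paired(x, fc_threshold = fc)$gene_id %in% base))
  }
  for (d in c(12, 20, 40)) {
    expect_true(all(screen_paired(x, diff_threshold = d)$gene_id %in% base))
  }
})

test_that("scaling one pair leaves its fold-change condition unchanged", {
  set.seed(9)
  tum <- matrix(rexp(90, 1 / 30) + 15, 30, 3)
  adj <- matrix(rexp(90, 1 / 30) + 15, 30, 3)
  x1 <- make_pes(tum, adj)
  tum2 <- tum; adj2 <- adj
  tum2[, 2] <- tum[, 2] * 3; adj2[, 2] <- adj[, 2] * 3
  x2 <- make_pes(tum2, adj2)
  # compare only the fold-change half of the rule with the diff disabled
  s1 <- screen_paired(x1, diff_threshold = 1e-9)
  s2 <- screen_paired(x2, diff_threshold = 1e-9)
  expect_identical(s1$gene_id, s2$gene_id)
  expect_identical(s1$direction, s2$direction)
})

test_that("degenerate screens error out", {
  x <- make_pes(cbind(c(1, 2)), cbind(c(1, 2)))
  x$pairs <- x$pairs[0, ]
  expect_error(screen_paired(x), "pair")
  y <- make_pes(cbind(c(1, 2)), cbind(c(0.5, 1)))
  expect_error(screen_paired(y, fc_threshold = -1), "positive")
})
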