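test_that("ddct reproduces worked examples and shift behaviour", {
  expect_equal(ddct(20, 15, 22, 15), 4)
  expect_equal(ddct(18, 12, 20, 14), 1)   # equal delta-Ct -> 1
  expect_equal(ddct(21, 15, 20, 15), 0.5)

  # adding c to the case target Ct scales the result by 2^-c
  set.seed(31)
  for (i in 1:20) {
    ct <- runif(4, 10, 30)
    c_shift <- runif(1, -3, 3)
    expect_equal(ddct(ct[1] + c_shift, ct[2], ct[3], ct[4]),
                 ddct(ct[1], ct[2], ct[3], ct[4]) * 2^-c_shift)
  }
  expect_error(ddct(NA, 1, 2, 3), "finite")
})

test_that("cohort_de applies the strict decision rule", {
  set.seed(32)
  counts <- matrix(rpois(4 * 8, 100), 4, 8,
                   dimnames = list(paste0("g", 1:4),
                                   paste0("s", 1:8)))
  groups <- rep(c("tumor", "normal"), each = 4)
  # identical group means -> ns
  counts[1, ] <- 100
  de <- cohort_de(counts, groups)
  expect_equal(de$direction[1], "ns")
  expect_equal(de$fc[1], 1, tolerance = 0.05)

  expect_error(cohort_de(counts, rep(c("tumor", "normal"), c(7, 1))),
               "at least 2")

  # external p-value hook overrides the built-in test
  p_ext <- setNames(rep(1, 4), rownames(counts))
  de_ext <- cohort_de(counts, groups, p_values = p_ext)
  expect_true(all(de_ext$direction == "ns"))
})

test_that("fold change at exactly 1.5 with tiny p stays non-significant", {
  # two clearly separated groups engineered to a CPM ratio of exactly 1.5
  counts <- rbind(g1 = c(rep(300, 4), rep(200, 4)),
                  g2 = rep(1000, 8))
  # equalize library sizes so CPM ratio = count ratio
  counts <- rbind(counts, filler = 5000 - colSums(counts))
  groups <- rep(c("tumor", "normal"), each = 4)
  de <- cohort_de(counts, groups, pseudocount = 0)
  expect_equal(de$fc[de$gene_id == "g1"], 1.5, tolerance = 1e-12)
  expect_equal(de$direction[de$gene_id == "g1"], "ns")
})

test_that("direction flips exactly under group-label swap", {
  set.seed(33)
  cfg <- sim_config(seed = 33, n_genes = 300, planted_up = 10,
                    planted_down = 5)
  disc <- suppressMessages(simulate_paired_discovery(cfg))
  sim <- simulate_validation_cohort(cfg, disc$truth)
  de1 <- cohort_de(sim$counts, sim$groups)
  swapped <- ifelse(sim$groups == "tumor", "normal", "tumor")
  de2 <- cohort_de(sim$counts, swapped)
  expect_equal(de2$fc, 1 / de1$fc, tolerance = 1e-12)
  expect_identical(de2$direction == "up", de1$direction == "down")
  expect_identical(de2$direction == "down", de1$direction == "up")
})

test_that("null cohort p-values are calibrated near 5%", {
  cfg <- sim_config(seed = 34, n_genes = 2000, planted_up = 0,
                    planted_down = 0, nb_dispersion = 0.1)
  disc <- suppressMessages(simulate_paired_discovery(cfg))
  sim <- simulate_validation_cohort(cfg, disc$truth[0, ])
  de <- cohort_de(sim$counts, sim$groups)
  expect_equal(mean(de$p < 0.05), 0.05, tolerance = 0.5) # within [0.025, 0.075]
})

test_that("paired qPCR test matches a hand-computed t statistic", {
  ct <- data.frame(
    patient_id = rep(c("p1", "p2", "p3"), each = 2),
    gene_id = "COMP",
    tissue = rep(c("tumor", "adjacent"), 3),
    ct_target = c(20, 24, 21, 24.5, 19.5, 23),
    ct_reference = rep(15, 6))
  res <- pcr_validate(ct)
  ddct_i <- c(20 - 24, 21 - 24.5, 19.5 - 23)
  t_hand <- mean(ddct_i) / (sd(ddct_i) / sqrt(3))
  p_hand <- 2 * pt(-abs(t_hand), 2)
  expect_equal(res$p, p_hand, tolerance = 1e-12)
  expect_equal(res$rel_expr, exp(mean(log(2^-ddct_i))), tolerance = 1e-12)
  expect_equal(res$direction, "up")
})

test_that("concordance joins discovery, cohort and qPCR directions", {
  discovery <- data.frame(gene_id = c("a", "b", "c", "d"),
                          direction = c("up", "up", "down", "up"))
  cohort <- data.frame(gene_id = c("a", "b", "c"),
                       fc = c(3, 1, 2), t = c(5, 0, 4),
                       p = c(0.001, 0.9, 0.001),
                       direction = c("up", "ns", "up"))
  expect_warning(res <- concordance(discovery, cohort), "absent")
  expect_equal(res$concordant[res$gene_id == "a"], TRUE)
  expect_equal(res$concordant[res$gene_id == "b"], FALSE)   # cohort ns
  expect_equal(res$concordant[res$gene_id == "c"], FALSE)   # reversed
  expect_equal(res$note[res$gene_id == "c"], "reversed")
  expect_equal(res$note[res$gene_id == "d"], "untested")

  pcr <- data.frame(gene_id = "a", n_patients = 3, rel_expr = 0.3,
                    p = 0.01, direction = "down")
  res2 <- suppressWarnings(concordance(discovery, cohort, pcr))
  expect_equal(res2$concordant[res2$gene_id == "a"], FALSE) # qPCR disagrees
  s <- attr(res2, "summary")
  expect_equal(s$n_tested, 3)
  expect_equal(s$n_cohort_consistent, 1)
})

test_that("planted validation effects are recovered concordantly", {
  hits <- 0L; total <- 0L
  for (s in 1:5) {
    cfg <- sim_config(seed = 340 + s, n_genes = 500, planted_up = 20,
                      planted_down = 10)
    disc <- suppressMessages(simulate_paired_discovery(cfg))
    sim <- simulate_validation_cohort(cfg, disc$truth)
    de <- cohort_de(sim$counts, sim$groups)
    res <- concordance(disc$truth, de)
    hits <- hits + sum(res$concordant)
    total <- total + nrow(res)
  }
  expect_gte(hits / total, 0.95)
})
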