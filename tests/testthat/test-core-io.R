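test_that("pairing is inferred from the ca/adj naming convention", {
  p <- infer_pairs(c("1ca", "1adj", "2ca", "2adj"))
  expect_equal(nrow(p), 2)
  expect_equal(p$tumor, c("1ca", "2ca"))
  expect_equal(p$adjacent, c("1adj", "2adj"))

  expect_error(infer_pairs(c("1ca", "2ca", "2adj")), "unpaired sample.*1ca")
  expect_error(infer_pairs(c("1ca", "1adj", "weird")), "suffix")
})

test_that("expression reader validates and round-trips", {
  m <- matrix(c(1.25, 0, 3.5, 10.125, 2, 7), nrow = 3,
              dimnames = list(c("a", "b", "c"), c("1ca", "1adj")))
  x <- paired_expression_set(m, unit = "rpkm")
  f <- withr::local_tempfile(fileext = ".tsv")
  write_expression(x, f)
  y <- read_expression(f, unit = "rpkm")
  expect_identical(y$values, x$values)
  expect_equal(y$pairs, x$pairs)

  m2 <- m; m2[1, 1] <- -1
  expect_error(paired_expression_set(m2, unit = "rpkm"), "negative")
  expect_error(paired_expression_set(rbind(m, a = c(1, 2)), unit = "rpkm"),
               "duplicated gene_id")
})

test_that("GMT reader parses, deduplicates and rejects short lines", {
  f <- withr::local_tempfile(fileext = ".gmt")
  writeLines(c("t1\tfirst term\tA\tB\tC",
               "t2\tsecond term\tB\tB\tD"), f)
  expect_message(g <- read_gmt(f), "duplicate")
  expect_equal(length(g), 2)
  expect_equal(g$members[[1]], c("A", "B", "C"))
  expect_equal(g$members[[2]], c("B", "D"))

  writeLines("t1\tonly-two-fields", f)
  expect_error(read_gmt(f), "line 1")

  writeLines(character(), f)
  expect_warning(empty <- read_gmt(f), "empty")
  expect_equal(length(empty), 0)

  g2 <- gene_set_collection(c("t1", "t2"), c("a", "b"),
                            list(c("A", "B"), "C"))
  f2 <- withr::local_tempfile(fileext = ".gmt")
  write_gmt(g2, f2)
  expect_equal(read_gmt(f2)$members, g2$members)
})

test_that("PPI reader collapses reversed duplicates and drops self-loops", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("A\tB", "B\tA", "C\tC", "B\tC", "D\tE"), f)
  expect_message(e <- read_ppi(f), "self-loop")
  expect_equal(nrow(e), 3)
  expect_true(all(e$a <= e$b))
  expect_setequal(paste(e$a, e$b), c("A B", "B C", "D E"))

  writeLines(c("A\tB", "justone"), f)
  expect_error(read_ppi(f), "line 2")
})

test_that("gene location reader enforces coordinates and uniqueness", {
  f <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("chr2\t1000\t2000\tFN1", "chr19\t500\t900\tCOMP"), f)
  loc <- read_gene_locations(f)
  expect_equal(loc$chromosome[loc$gene_id == "FN1"], "chr2")

  writeLines("chr2\t2000\t1000\tFN1", f)
  expect_error(read_gene_locations(f), "start > end")
  writeLines(c("chr2\t1\t2\tFN1", "chr3\t1\t2\tFN1"), f)
  expect_error(read_gene_locations(f), "duplicate")
})

test_that("cohort summary reproduces the published age statistics", {
  cohort <- ptc_cohort()
  s <- summarize_cohort(cohort)
  expect_equal(s$n_patients, 16)
  expect_equal(s$mean_age_display, 42.8)
  expect_equal(s$sd_age_display, 9.3)
  # category tallies: one T4 patient, 7 node-positive, no metastasis
  expect_equal(as.integer(s$tnm_counts$t[["4"]]), 1)
  expect_equal(as.integer(s$tnm_counts$n[["1"]]), 7)
  expect_equal(names(s$tnm_counts$m), "0")
})

test_that("cohort summary matches hand arithmetic and a brute-force oracle", {
  dummy <- data.frame(patient_id = c("a", "b"))
  s <- summarize_cohort(dummy, ages = c(20, 40))
  expect_equal(s$mean_age, 30)
  expect_equal(s$sd_age, sqrt(200))

  s0 <- summarize_cohort(data.frame(patient_id = 1:3), ages = c(40, 40, 40))
  expect_equal(s0$sd_age, 0)
  expect_error(summarize_cohort(data.frame(patient_id = 1), ages = 41),
               "n < 2")

  set.seed(42)
  for (i in 1:20) {
    ages <- sample(20:80, sample(2:30, 1), replace = TRUE)
    s <- summarize_cohort(data.frame(patient_id = seq_along(ages)),
                          ages = ages)
    expect_equal(s$mean_age, sum(ages) / length(ages))
    expect_equal(s$sd_age,
                 sqrt(sum((ages - mean(ages))^2) / (length(ages) - 1)))
  }
})

test_that("display rounding is half-up at the printed precision", {
  expect_equal(round_half_up(42.8125, 1), 42.8)
  expect_equal(round_half_up(0.25, 1), 0.3)
  expect_equal(round_half_up(-0.25, 1), -0.3)
  expect_equal(round_half_up(9.325369, 1), 9.3)
})

test_that("clinical reader decodes TNM labels to ordinal codes", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("patient_id\tage\tt\tn\tm\tstage",
               "p1\t41\tT1\tN1\tM0\tI",
               "p2\t39\t4\t0\t1\tIV"), f)
  cl <- read_clinical(f)
  expect_equal(cl$t, c(1L, 4L))
  expect_equal(cl$n, c(1L, 0L))
  expect_equal(cl$m, c(0L, 1L))
  expect_equal(cl$stage, c(1L, 4L))

  writeLines(c("patient_id\tt", "p1\tT9"), f)
  expect_error(read_clinical(f), "outside")
  writeLines(c("patient_id\tage", "p1\t40", "p1\t41"), f)
  expect_error(read_clinical(f), "duplicated patient_id")
})
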