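# Spearman correlation of gene expression with ordinal clinical phenotypes
# and the two-group t-test used for distant metastasis.

# all permutations of 1..n as an (n! x n) matrix
.permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- .permutations(n - 1)
  do.call(rbind, lapply(seq_len(n), function(i) {
    rest <- seq_len(n)[-i]
    cbind(i, matrix(rest[sub], nrow(sub)))
  }))
}

#' Spearman rank correlation with tie handling
#'
#' `rho` is the Pearson correlation of mid-ranks (average ranks for ties).
#' The two-sided p-value uses the t approximation
#' `t = rho * sqrt((n - 2) / (1 - rho^2))` with `n - 2` degrees of freedom;
#' `exact = TRUE` (n <= 9) enumerates all permutations of one argument
#' instead and reports `P(|rho_perm| >= |rho_obs|)`.
#'
#' @param x,y Equal-length numeric vectors, `n >= 3`, neither constant.
#' @param exact Exact permutation p-value (only for `n <= 9`).
#' @return List with `rho`, `p`, `n`.
#' @export
spearman_cor <- function(x, y, exact = FALSE) {
  .check(length(x) == length(y), "x and y must have equal length")
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  .check(n >= 3, "need at least 3 complete observations")
  .check(stats::sd(x) > 0 && stats::sd(y) > 0,
         "undefined correlation: constant vector")
  rx <- rank(x); ry <- rank(y)
  rho <- stats::cor(rx, ry)
  if (exact) {
    .check(n <= 9, "exact permutation p only supported for n <= 9")
    perms <- .permutations(n)
    ry_s <- sort(ry)
    rho_perm <- as.vector(stats::cor(rx, t(matrix(ry_s[perms], nrow(perms)))))
    p <- mean(abs(rho_perm) >= abs(rho) - 1e-12)
  } else if (abs(rho) >= 1 - 1e-15) {
    p <- 0
  } else {
    t <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(-abs(t), n - 2)
  }
  list(rho = rho, p = p, n = n)
}

#' Two-group t-test
#'
#' Thin wrapper over [stats::t.test()]: Welch by default (Satterthwaite
#' degrees of freedom, robust to the unequal group sizes typical of
#' metastasis yes/no splits) or Student with `variant = "student"`.
#'
#' @param values Numeric vector.
#' @param group Binary labels (factor/character/logical), one per value.
#' @param variant `"welch"` (default) or `"student"`.
#' @return List with `t`, `df`, `p`, `n1`, `n2`.
#' @export
ttest_groups <- function(values, group, variant = c("welch", "student")) {
  variant <- match.arg(variant)
  group <- as.factor(group)
  .check(nlevels(droplevels(group)) == 2, "group must have exactly 2 levels")
  g <- droplevels(group)
  n1 <- sum(g == levels(g)[1]); n2 <- sum(g == levels(g)[2])
  .check(n1 >= 2 && n2 >= 2, "each group needs at least 2 members")
  ht <- stats::t.test(values ~ g, var.equal = (variant == "student"))
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value, n1 = n1, n2 = n2)
}

#' Associate gene expression with clinical phenotypes
#'
#' For each requested gene, Spearman correlation of per-sample expression
#' with the ordinal phenotypes tumor size (`t` category 1-4, or continuous
#' `tumor_cm` when `tumor_size = "cm"`), lymph node (`n`, 0/1), distant
#' metastasis (`m`, 0/1) and TNM `stage` (1-4), plus a two-group Welch
#' t-test of expression split by metastasis. Samples are matched to
#' patients by column name / `patient_id` intersection (logged). Constant
#' phenotypes are skipped with a warning; genes absent from the matrix are
#' recorded untested. Stars follow the usual convention: `*` p < 0.05,
#' `**` p < 0.01.
#'
#' @param expr Gene x sample expression matrix.
#' @param clinical A `clinical_table`.
#' @param genes Genes to test (default: all matrix rows).
#' @param alpha Significance threshold used for the `significant` flag.
#' @param tumor_size `"ordinal"` (T category) or `"cm"` (continuous).
#' @return Data frame `gene_id`, `phenotype`, `method`, `estimate`
#'   (rho or t), `p`, `n`, `stars`, `significant`.
#' @export
associate <- function(expr, clinical, genes = rownames(expr), alpha = 0.05,
                      tumor_size = c("ordinal", "cm")) {
  tumor_size <- match.arg(tumor_size)
  samples <- intersect(colnames(expr), clinical$patient_id)
  .check(length(samples) >= 3, "fewer than 3 samples align with the clinical table")
  message(sprintf("associate: using %d aligned samples", length(samples)))
  cl <- clinical[match(samples, clinical$patient_id), , drop = FALSE]

  phen <- list()
  size_col <- if (tumor_size == "cm") "tumor_cm" else "t"
  if (size_col %in% names(cl)) phen$tumor_size <- as.numeric(cl[[size_col]])
  if ("n" %in% names(cl)) phen$node <- as.numeric(cl$n)
  if ("m" %in% names(cl)) phen$metastasis <- as.numeric(cl$m)
  if ("stage" %in% names(cl)) phen$stage <- as.numeric(cl$stage)
  .check(length(phen) > 0, "no recognised phenotype columns")

  stars_of <- function(p) {
    if (is.na(p)) "" else if (p < 0.01) "**" else if (p < 0.05) "*" else ""
  }
  rows <- list()
  add <- function(gene, phenotype, method, estimate, p, n) {
    rows[[length(rows) + 1L]] <<- data.frame(
      gene_id = gene, phenotype = phenotype, method = method,
      estimate = estimate, p = p, n = n, stars = stars_of(p),
      significant = !is.na(p) && p < alpha, stringsAsFactors = FALSE)
  }

  for (gene in genes) {
    if (!gene %in% rownames(expr)) {
      add(gene, NA_character_, "untested", NA_real_, NA_real_, 0L)
      next
    }
    x <- as.numeric(expr[gene, samples])
    for (ph in names(phen)) {
      y <- phen[[ph]]
      if (stats::sd(y, na.rm = TRUE) == 0) {
        warning(sprintf("phenotype %s is constant; skipped", ph),
                call. = FALSE)
        next
      }
      sp <- spearman_cor(x, y)
      add(gene, ph, "spearman", sp$rho, sp$p, sp$n)
    }
    if (!is.null(phen$metastasis) && stats::sd(phen$metastasis) > 0 &&
        min(table(phen$metastasis)) >= 2) {
      tt <- ttest_groups(x, phen$metastasis)
      add(gene, "metastasis", "ttest", tt$t, tt$p, tt$n1 + tt$n2)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
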