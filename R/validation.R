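# Validation-cohort differential expression, qPCR 2^-ddCt quantification,
# and discovery/validation direction concordance.

# Vectorised per-gene Welch (or Student) t-test across the rows of a matrix.
.row_ttest <- function(x, g1, g2, variant = c("welch", "student")) {
  variant <- match.arg(variant)
  m1 <- rowMeans(x[, g1, drop = FALSE])
  m2 <- rowMeans(x[, g2, drop = FALSE])
  n1 <- length(g1); n2 <- length(g2)
  v1 <- apply(x[, g1, drop = FALSE], 1, stats::var)
  v2 <- apply(x[, g2, drop = FALSE], 1, stats::var)
  if (variant == "welch") {
    se2 <- v1 / n1 + v2 / n2
    t <- (m1 - m2) / sqrt(se2)
    df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  } else {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    t <- (m1 - m2) / sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- rep(n1 + n2 - 2, length(t))
  }
  p <- 2 * stats::pt(-abs(t), df)
  p[is.nan(t)] <- 1       # zero variance and zero difference
  p[is.infinite(t)] <- 0  # zero variance, non-zero difference
  list(t = t, df = df, p = p)
}

#' Two-group validation-cohort differential expression
#'
#' Counts are normalized to counts-per-million with a pseudocount; the fold
#' change is the ratio of tumor to normal group means of CPM, and the
#' p-value comes from a two-sided Welch t-test on log2 CPM (a documented
#' two-group stand-in; externally computed p-values can be supplied through
#' `p_values` to plug in any DE engine). The decision rule is:
#' `up` if `p < p_threshold` and `fc > fc_up`; `down` if `p < p_threshold`
#' and `fc < fc_down`; otherwise `ns`. All comparisons are strict.
#'
#' @param counts Gene x sample count matrix (rownames = gene ids).
#' @param groups Vector of `"tumor"`/`"normal"` labels, one per column.
#' @param p_threshold Significance threshold, default 0.05.
#' @param fc_up Upper fold-change bound for `up`, default 1.5.
#' @param fc_down Lower bound for `down`, default 2/3.
#' @param pseudocount Added to counts before CPM, default 0.5.
#' @param p_values Optional named numeric vector of per-gene p-values that
#'   overrides the built-in test.
#' @param variant `"welch"` (default) or `"student"`.
#' @return Data frame `gene_id`, `fc`, `t`, `p`, `direction`.
#' @export
cohort_de <- function(counts, groups, p_threshold = 0.05,
                      fc_up = 1.5, fc_down = 2 / 3, pseudocount = 0.5,
                      p_values = NULL, variant = c("welch", "student")) {
  variant <- match.arg(variant)
  .check(is.matrix(counts) && !is.null(rownames(counts)),
         "counts must be a matrix with gene rownames")
  groups <- as.character(groups)
  .check(length(groups) == ncol(counts), "one group label per sample required")
  .check(all(groups %in% c("tumor", "normal")),
         "group labels must be 'tumor' or 'normal'")
  tum <- which(groups == "tumor"); nor <- which(groups == "normal")
  .check(length(tum) >= 2 && length(nor) >= 2,
         "each group needs at least 2 samples")

  lib <- colSums(counts) / 1e6
  .check(all(lib > 0), "zero library size")
  cpm <- sweep(counts + pseudocount, 2, lib, "/")
  fc <- rowMeans(cpm[, tum, drop = FALSE]) / rowMeans(cpm[, nor, drop = FALSE])

  if (is.null(p_values)) {
    tt <- .row_ttest(log2(cpm), tum, nor, variant = variant)
    tstat <- tt$t; p <- tt$p
  } else {
    .check(!is.null(names(p_values)), "p_values must be named by gene_id")
    p <- unname(p_values[rownames(counts)])
    tstat <- rep(NA_real_, nrow(counts))
  }
  direction <- rep("ns", nrow(counts))
  sig <- !is.na(p) & p < p_threshold
  direction[sig & fc > fc_up] <- "up"
  direction[sig & fc < fc_down] <- "down"
  data.frame(gene_id = rownames(counts), fc = unname(fc), t = unname(tstat),
             p = unname(p), direction = direction, stringsAsFactors = FALSE)
}

#' Relative expression by the 2^-ddCt method
#'
#' `2^-((ct_target_case - ct_ref_case) - (ct_target_ctrl - ct_ref_ctrl))`:
#' target-gene Ct normalized to a reference gene within the case sample,
#' relative to the same quantity in the control sample. Values > 1 mean
#' higher target expression in the case.
#'
#' @param ct_target_case,ct_ref_case Target and reference Ct in the case
#'   (e.g. tumor) sample.
#' @param ct_target_ctrl,ct_ref_ctrl Same in the control (e.g. adjacent)
#'   sample. All vectorized.
#' @return Relative expression value(s).
#' @export
#' @examples
#' ddct(20, 15, 22, 15) # 4
ddct <- function(ct_target_case, ct_ref_case, ct_target_ctrl, ct_ref_ctrl) {
  .check(all(is.finite(c(ct_target_case, ct_ref_case,
                         ct_target_ctrl, ct_ref_ctrl))),
         "Ct values must be finite")
  2^-((ct_target_case - ct_ref_case) - (ct_target_ctrl - ct_ref_ctrl))
}

#' Per-gene qPCR validation from a long Ct table
#'
#' Expects columns `patient_id`, `gene_id`, `tissue` (`"tumor"`/`"adjacent"`),
#' `ct_target`, `ct_reference`. For each gene, per-patient delta-Ct
#' (target - reference) is formed in both tissues, relative expression is
#' `2^-ddCt`, and significance comes from a paired two-sided t-test on the
#' delta-Ct values (`method = "wilcoxon"` switches to the signed-rank test).
#' Direction is `up` when the geometric-mean relative expression exceeds 1
#' and `p < p_threshold`, `down` when it is below 1 with `p < p_threshold`,
#' else `ns`.
#'
#' @param ct_table Long-format data frame as above.
#' @param p_threshold Significance threshold, default 0.05.
#' @param method `"ttest"` (paired t on delta-Ct) or `"wilcoxon"`.
#' @return Data frame `gene_id`, `n_patients`, `rel_expr` (geometric mean of
#'   per-patient 2^-ddCt), `p`, `direction`.
#' @export
pcr_validate <- function(ct_table, p_threshold = 0.05,
                         method = c("ttest", "wilcoxon")) {
  method <- match.arg(method)
  need <- c("patient_id", "gene_id", "tissue", "ct_target", "ct_reference")
  .check(all(need %in% names(ct_table)),
         "ct_table needs columns: %s", paste(need, collapse = ", "))
  .check(all(ct_table$tissue %in% c("tumor", "adjacent")),
         "tissue must be 'tumor' or 'adjacent'")
  out <- lapply(split(ct_table, ct_table$gene_id), function(d) {
    dct <- d$ct_target - d$ct_reference
    tum <- d[d$tissue == "tumor", ]
    adj <- d[d$tissue == "adjacent", ]
    common <- intersect(tum$patient_id, adj$patient_id)
    .check(length(common) >= 2,
           "gene %s: need >=2 patients with both tissues", d$gene_id[1])
    dct_t <- (tum$ct_target - tum$ct_reference)[match(common, tum$patient_id)]
    dct_a <- (adj$ct_target - adj$ct_reference)[match(common, adj$patient_id)]
    ddct_i <- dct_t - dct_a
    rel <- 2^-ddct_i
    p <- if (method == "ttest") {
      stats::t.test(dct_t, dct_a, paired = TRUE)$p.value
    } else {
      stats::wilcox.test(dct_t, dct_a, paired = TRUE, exact = FALSE)$p.value
    }
    gm <- exp(mean(log(rel)))
    dir <- if (p < p_threshold && gm > 1) "up"
           else if (p < p_threshold && gm < 1) "down" else "ns"
    data.frame(gene_id = d$gene_id[1], n_patients = length(common),
               rel_expr = gm, p = p, direction = dir,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Discovery vs validation direction concordance
#'
#' Joins discovery DEG calls with validation-cohort calls (and optionally
#' qPCR calls) gene by gene. A gene is concordant when the cohort direction
#' equals the discovery direction and — when qPCR results are present for
#' it — the qPCR direction matches too. A cohort call in the opposite
#' direction is flagged `reversed`. Genes absent from the cohort results are
#' recorded as untested with a warning.
#'
#' @param discovery Data frame with `gene_id`, `direction` (the screen's
#'   output suffices).
#' @param cohort Output of [cohort_de()].
#' @param pcr Optional output of [pcr_validate()].
#' @return Data frame `gene_id`, `discovery_direction`, `cohort_direction`,
#'   `cohort_p`, `cohort_fc`, `pcr_direction`, `concordant`, `note`; the
#'   summary counts are attached as attribute `"summary"`.
#' @export
concordance <- function(discovery, cohort, pcr = NULL) {
  .check(all(c("gene_id", "direction") %in% names(discovery)),
         "discovery needs gene_id and direction")
  i <- match(discovery$gene_id, cohort$gene_id)
  untested <- is.na(i)
  if (any(untested)) {
    warning(sprintf("%d gene(s) absent from the cohort matrix: %s",
                    sum(untested),
                    paste(discovery$gene_id[untested], collapse = ", ")),
            call. = FALSE)
  }
  out <- data.frame(gene_id = discovery$gene_id,
                    discovery_direction = discovery$direction,
                    cohort_direction = ifelse(untested, NA, cohort$direction[i]),
                    cohort_p = ifelse(untested, NA, cohort$p[i]),
                    cohort_fc = ifelse(untested, NA, cohort$fc[i]),
                    stringsAsFactors = FALSE)
  if (!is.null(pcr)) {
    j <- match(out$gene_id, pcr$gene_id)
    out$pcr_direction <- pcr$direction[j]
  } else {
    out$pcr_direction <- NA_character_
  }
  cohort_ok <- !is.na(out$cohort_direction) &
    out$cohort_direction == out$discovery_direction
  pcr_ok <- is.na(out$pcr_direction) |
    out$pcr_direction == out$discovery_direction
  out$concordant <- ifelse(untested, NA, cohort_ok & pcr_ok)
  reversed <- !is.na(out$cohort_direction) & out$cohort_direction != "ns" &
    out$cohort_direction != out$discovery_direction
  out$note <- ifelse(untested, "untested",
                     ifelse(reversed, "reversed", ""))
  attr(out, "summary") <- list(
    n_tested = sum(!untested),
    n_cohort_consistent = sum(cohort_ok),
    n_pcr_consistent = sum(!is.na(out$pcr_direction) &
                             out$pcr_direction == out$discovery_direction),
    n_concordant = sum(out$concordant, na.rm = TRUE))
  out
}
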