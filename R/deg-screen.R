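# RPKM normalization, mapped-gene filtering, and the paired-consistency
# DEG screen.
#
# The screen is deliberately not a statistical test: a gene is called
# differentially expressed only when the fold-change and expression-difference
# thresholds hold in every tumor/adjacent pair, mirroring the per-pair
# bracket rule of the discovery design (3 pairs by default).

#' Reads per kilobase of exon per million mapped reads
#'
#' `RPKM = exon_reads / (mapped_reads_millions * exon_length_kb)`.
#'
#' @param exon_reads Non-negative read count(s) for the gene's exons.
#' @param mapped_reads_millions Total mapped reads of the library, in
#'   millions; strictly positive.
#' @param exon_length_kb Exon length in kilobases; strictly positive.
#' @return RPKM value(s); vectorized over all arguments.
#' @export
#' @examples
#' rpkm(1000, 10, 2) # 50
rpkm <- function(exon_reads, mapped_reads_millions, exon_length_kb) {
  .check(all(exon_reads >= 0), "exon_reads must be non-negative")
  .check(all(mapped_reads_millions > 0),
         "mapped_reads_millions must be strictly positive")
  .check(all(exon_length_kb > 0), "exon_length_kb must be strictly positive")
  exon_reads / (mapped_reads_millions * exon_length_kb)
}

#' RPKM-normalize a count matrix
#'
#' @param counts Gene x sample count matrix (rownames = gene ids).
#' @param mapped_reads_millions Per-sample mapped library sizes in millions
#'   (length = ncol(counts)).
#' @param lengths_kb Per-gene exon lengths in kb (length = nrow(counts)).
#' @return RPKM matrix of the same shape.
#' @export
rpkm_matrix <- function(counts, mapped_reads_millions, lengths_kb) {
  .check(length(mapped_reads_millions) == ncol(counts),
         "one library size per sample required")
  .check(length(lengths_kb) == nrow(counts), "one length per gene required")
  .check(all(mapped_reads_millions > 0), "library sizes must be positive")
  .check(all(lengths_kb > 0), "gene lengths must be positive")
  sweep(counts / lengths_kb, 2, mapped_reads_millions, "/")
}

#' Filter to mapped genes by minimum RPKM
#'
#' A gene counts as "mapped" (expressed) when its RPKM reaches `min_rpkm`
#' (inclusive) in at least one sample (`scope = "any"`, the default) or in
#' every sample (`scope = "all"`).
#'
#' @param x A `paired_expression_set` holding RPKM values.
#' @param min_rpkm Inclusive threshold, default 0.5.
#' @param scope `"any"` or `"all"` sample semantics.
#' @return Filtered `paired_expression_set`; the number of removed genes is
#'   reported with a message.
#' @export
filter_mapped <- function(x, min_rpkm = 0.5, scope = c("any", "all")) {
  scope <- match.arg(scope)
  .check(inherits(x, "paired_expression_set"), "x must be a paired_expression_set")
  .check(identical(x$unit, "rpkm"), "filter_mapped expects RPKM values")
  hit <- x$values >= min_rpkm
  keep <- if (scope == "any") rowSums(hit) > 0 else rowSums(hit) == ncol(hit)
  message(sprintf("filter_mapped: removed %d / %d genes below RPKM %g (%s)",
                  sum(!keep), length(keep), min_rpkm, scope))
  y <- x
  y$values <- x$values[keep, , drop = FALSE]
  y
}

#' Paired-consistency DEG screen
#'
#' A gene is UP-regulated iff in *every* pair `i` the tumor/adjacent
#' fold change exceeds `fc_threshold` and the tumor-minus-adjacent RPKM
#' difference exceeds `diff_threshold` (both strict). DOWN is symmetric with
#' the roles of tumor and adjacent swapped. With `mode = "mean"` the
#' geometric-mean fold change and mean difference are tested instead.
#'
#' A zero adjacent value with positive tumor value passes the fold-change
#' condition (ratio treated as +Inf); a gene at zero in both tissues of a
#' pair fails. No pseudocounts are added.
#'
#' @param x A filtered `paired_expression_set` in RPKM.
#' @param fc_threshold Strict fold-change threshold, default 1.5.
#' @param diff_threshold Strict RPKM-difference threshold, default 10.
#' @param mode `"all_pairs"` (default, per-pair rule) or `"mean"`.
#' @return Data frame with one row per DEG: `gene_id`, `direction`
#'   (`"up"`/`"down"`), `mean_fc` (geometric mean of oriented per-pair fold
#'   changes), and oriented per-pair columns `fc_<patient>` /
#'   `diff_<patient>`. Sorted by direction then gene_id.
#' @export
screen_paired <- function(x, fc_threshold = 1.5, diff_threshold = 10,
                          mode = c("all_pairs", "mean")) {
  mode <- match.arg(mode)
  .check(inherits(x, "paired_expression_set"), "x must be a paired_expression_set")
  .check(identical(x$unit, "rpkm"), "screen_paired expects RPKM values")
  .check(nrow(x$pairs) >= 1, "at least one tumor/adjacent pair required")
  .check(fc_threshold > 0 && diff_threshold > 0, "thresholds must be positive")

  tum <- x$values[, x$pairs$tumor, drop = FALSE]
  adj <- x$values[, x$pairs$adjacent, drop = FALSE]

  pass <- function(num, den) {
    # strict per-pair conditions; num/den = Inf when den==0 & num>0 (passes),
    # NaN when both zero (fails)
    fc_ok <- num / den > fc_threshold
    fc_ok[is.na(fc_ok)] <- FALSE
    diff_ok <- (num - den) > diff_threshold
    if (mode == "all_pairs") {
      rowSums(fc_ok) == ncol(fc_ok) & rowSums(diff_ok) == ncol(diff_ok)
    } else {
      ratio <- num / den
      gm <- exp(rowMeans(log(ratio)))
      gm_ok <- gm > fc_threshold
      gm_ok[is.na(gm_ok)] <- FALSE
      gm_ok & rowMeans(num - den) > diff_threshold
    }
  }

  up <- pass(tum, adj)
  down <- pass(adj, tum)

  build <- function(idx, direction) {
    if (!any(idx)) return(NULL)
    num <- if (direction == "up") tum[idx, , drop = FALSE] else adj[idx, , drop = FALSE]
    den <- if (direction == "up") adj[idx, , drop = FALSE] else tum[idx, , drop = FALSE]
    fc <- num / den
    df <- data.frame(gene_id = rownames(x$values)[idx],
                     direction = direction,
                     mean_fc = exp(rowMeans(log(fc))),
                     stringsAsFactors = FALSE)
    fcd <- as.data.frame(fc)
    names(fcd) <- paste0("fc_", x$pairs$patient_id)
    dfd <- as.data.frame(num - den)
    names(dfd) <- paste0("diff_", x$pairs$patient_id)
    rownames(df) <- NULL
    cbind(df, fcd, dfd)
  }

  out <- rbind(build(up, "up"), build(down, "down"))
  if (is.null(out)) {
    out <- data.frame(gene_id = character(), direction = character(),
                      mean_fc = numeric(), stringsAsFactors = FALSE)
    for (p in x$pairs$patient_id) out[[paste0("fc_", p)]] <- numeric()
    for (p in x$pairs$patient_id) out[[paste0("diff_", p)]] <- numeric()
  }
  out <- out[order(out$direction, out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
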