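# Term over-representation testing: hypergeometric upper tail (with the
# conservative EASE variant), Benjamini-Hochberg adjustment, and the
# per-collection enrichment driver.

#' Hypergeometric upper-tail p-value for set overlap
#'
#' Probability of observing `k` or more query genes inside a term of size
#' `K`, for a query of size `n` drawn from a universe of size `N`:
#' `P(X >= k)` with `X ~ Hypergeometric(N, K, n)`. The EASE variant (the
#' conservative score used by the DAVID annotation tool) computes the same
#' tail with `k` replaced by `max(k - 1, 0)`.
#'
#' @param N Universe size.
#' @param K Term members in the universe.
#' @param n Query size in the universe.
#' @param k Overlap; all four vectorized.
#' @param ease Use the EASE variant (default `FALSE`).
#' @return Upper-tail p-value(s) in `[0, 1]`.
#' @export
#' @examples
#' hypergeom_tail(20, 5, 6, 4) # 540/38760
hypergeom_tail <- function(N, K, n, k, ease = FALSE) {
  .check(all(N >= 0) && all(K >= 0) && all(n >= 0) && all(k >= 0),
         "counts must be non-negative")
  .check(all(K <= N) && all(n <= N), "K and n cannot exceed N")
  .check(all(k <= pmin(K, n)), "k cannot exceed min(K, n)")
  if (ease) k <- pmax(k - 1, 0)
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Standard BH adjusted p-values (`p * m / rank` with running minimum from
#' the largest rank), returned in the input order. Adjusted values never
#' fall below the raw values.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values, same length and order as `p`.
#' @export
#' @examples
#' bh_adjust(c(0.005, 0.01, 0.03, 0.04)) # 0.02 0.02 0.04 0.04
bh_adjust <- function(p) {
  .check(is.numeric(p), "p must be numeric")
  .check(all(is.finite(p)) && all(p >= 0) && all(p <= 1),
         "p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Term over-representation analysis of a query gene set
#'
#' One hypergeometric upper-tail test per term against a fixed universe.
#' Query genes outside the universe are dropped with a warning; terms with no
#' member in the universe are skipped. Significance is flagged on the raw
#' p-value when `adjust = "none"` (the pathway-stage convention here) and on
#' the BH-adjusted p-value when `adjust = "bh"` (the GO-stage convention).
#'
#' @param query Character vector of query gene ids.
#' @param collection A [gene_set_collection()].
#' @param universe Character vector of background gene ids (non-empty).
#' @param alpha Significance threshold, default 0.05.
#' @param adjust `"none"` or `"bh"`.
#' @param ease Use the EASE tail variant (default `FALSE`).
#' @return Data frame sorted by `p_raw` ascending with columns `term_id`,
#'   `term_name`, `N`, `K`, `n`, `k`, `p_raw`, `p_adjusted`, `significant`,
#'   `overlap` (comma-separated gene ids).
#' @export
enrich <- function(query, collection, universe, alpha = 0.05,
                   adjust = c("none", "bh"), ease = FALSE) {
  adjust <- match.arg(adjust)
  .check(inherits(collection, "gene_set_collection"),
         "collection must be a gene_set_collection")
  universe <- unique(as.character(universe))
  .check(length(universe) > 0, "universe must be non-empty")
  query <- unique(as.character(query))
  outside <- setdiff(query, universe)
  if (length(outside) > 0) {
    warning(sprintf("dropped %d query gene(s) outside the universe",
                    length(outside)), call. = FALSE)
    query <- intersect(query, universe)
  }
  N <- length(universe)
  n <- length(query)
  rows <- lapply(seq_along(collection$term_id), function(i) {
    members <- intersect(collection$members[[i]], universe)
    K <- length(members)
    if (K == 0) return(NULL)
    hits <- intersect(query, members)
    k <- length(hits)
    data.frame(term_id = collection$term_id[i],
               term_name = collection$term_name[i],
               N = N, K = K, n = n, k = k,
               p_raw = hypergeom_tail(N, K, n, k, ease = ease),
               overlap = paste(sort(hits), collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(term_id = character(), term_name = character(),
                      N = integer(), K = integer(), n = integer(),
                      k = integer(), p_raw = numeric(), overlap = character(),
                      stringsAsFactors = FALSE)
  }
  out$p_adjusted <- if (nrow(out)) bh_adjust(out$p_raw) else numeric()
  out$significant <- if (adjust == "bh") out$p_adjusted < alpha else out$p_raw < alpha
  out <- out[order(out$p_raw, out$term_id), , drop = FALSE]
  out <- out[, c("term_id", "term_name", "N", "K", "n", "k",
                 "p_raw", "p_adjusted", "significant", "overlap")]
  rownames(out) <- NULL
  out
}
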