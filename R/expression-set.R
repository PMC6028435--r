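# Paired expression container and its TSV reader/writer.
#
# Samples follow the "<patient>ca" / "<patient>adj" naming convention used in
# paired tumor / adjacent-normal designs (e.g. 1ca, 1adj, 2ca, 2adj); an
# explicit pairing table overrides the convention.

#' Construct a paired expression set
#'
#' Container for a gene x sample expression matrix (counts or RPKM) together
#' with the tumor/adjacent pairing of its samples.
#'
#' @param values Non-negative numeric matrix, rownames = gene ids,
#'   colnames = sample labels.
#' @param pairs Data frame with columns `patient_id`, `tumor`, `adjacent`
#'   naming the two samples of each patient. If `NULL`, pairing is inferred
#'   from the `ca`/`adj` suffix convention.
#' @param unit Either `"rpkm"` or `"counts"` — states what `values` holds.
#' @return An object of class `paired_expression_set`: a list with elements
#'   `values`, `pairs`, `unit`.
#' @export
paired_expression_set <- function(values, pairs = NULL,
                                  unit = c("rpkm", "counts")) {
  unit <- match.arg(unit)
  .check(is.matrix(values) && is.numeric(values),
         "`values` must be a numeric matrix")
  .check(!is.null(rownames(values)) && !is.null(colnames(values)),
         "`values` must have gene rownames and sample colnames")
  .check(!anyDuplicated(rownames(values)),
         "duplicated gene_id in expression matrix: %s",
         paste(unique(rownames(values)[duplicated(rownames(values))]),
               collapse = ", "))
  .check(!anyDuplicated(colnames(values)), "duplicated sample labels")
  .check(all(is.finite(values)), "non-finite expression values")
  .check(all(values >= 0), "negative expression values are not allowed")

  if (is.null(pairs)) pairs <- infer_pairs(colnames(values))
  .check(is.data.frame(pairs) &&
           all(c("patient_id", "tumor", "adjacent") %in% names(pairs)),
         "`pairs` needs columns patient_id, tumor, adjacent")
  pairs$patient_id <- as.character(pairs$patient_id)
  pairs$tumor <- as.character(pairs$tumor)
  pairs$adjacent <- as.character(pairs$adjacent)
  missing <- setdiff(c(pairs$tumor, pairs$adjacent), colnames(values))
  .check(length(missing) == 0,
         "pairing references unknown sample(s): %s",
         paste(missing, collapse = ", "))
  .check(all(pairs$tumor != pairs$adjacent),
         "a pair must reference two distinct samples")
  .check(!anyDuplicated(pairs$patient_id), "duplicated patient_id in pairs")

  structure(list(values = values, pairs = pairs, unit = unit),
            class = "paired_expression_set")
}

#' Infer tumor/adjacent pairing from sample names
#'
#' Sample labels are expected to share a patient prefix with suffix `ca`
#' (cancer) or `adj` (matched adjacent normal), e.g. `1ca`/`1adj`.
#'
#' @param samples Character vector of sample labels.
#' @return Data frame with columns `patient_id`, `tumor`, `adjacent`.
#' @export
infer_pairs <- function(samples) {
  is_ca <- grepl("ca$", samples)
  is_adj <- grepl("adj$", samples)
  bad <- samples[!(is_ca | is_adj)]
  .check(length(bad) == 0,
         "cannot infer pairing: sample(s) %s lack a 'ca'/'adj' suffix",
         paste(bad, collapse = ", "))
  patient <- ifelse(is_ca, sub("ca$", "", samples), sub("adj$", "", samples))
  tumors <- stats::setNames(samples[is_ca], patient[is_ca])
  adjs <- stats::setNames(samples[is_adj], patient[is_adj])
  orphan <- c(setdiff(names(tumors), names(adjs)),
              setdiff(names(adjs), names(tumors)))
  if (length(orphan) > 0) {
    orphan_samples <- samples[patient %in% orphan]
    stop("unpaired sample(s): ", paste(orphan_samples, collapse = ", "),
         call. = FALSE)
  }
  ids <- names(tumors)[order(names(tumors))]
  data.frame(patient_id = ids, tumor = unname(tumors[ids]),
             adjacent = unname(adjs[ids]), stringsAsFactors = FALSE)
}

#' @export
print.paired_expression_set <- function(x, ...) {
  cat(sprintf("paired_expression_set: %d genes x %d samples (%s), %d pairs\n",
              nrow(x$values), ncol(x$values), x$unit, nrow(x$pairs)))
  invisible(x)
}

#' Read a paired expression matrix from TSV
#'
#' First column must be `gene_id`; remaining columns are samples. Pairing is
#' read from `pairs_path` (TSV with columns patient_id, tumor, adjacent) when
#' given, otherwise inferred from the `ca`/`adj` sample-name convention.
#'
#' @param path Expression TSV path.
#' @param unit `"rpkm"` or `"counts"`.
#' @param pairs_path Optional pairing TSV path.
#' @return A [paired_expression_set()].
#' @export
read_expression <- function(path, unit = c("rpkm", "counts"),
                            pairs_path = NULL) {
  unit <- match.arg(unit)
  tab <- .read_tsv(path)
  .check(ncol(tab) >= 3, "expression file needs gene_id plus >=2 samples")
  genes <- as.character(tab[[1]])
  values <- as.matrix(tab[, -1, drop = FALSE])
  storage.mode(values) <- "double"
  rownames(values) <- genes
  pairs <- if (!is.null(pairs_path)) .read_tsv(pairs_path) else NULL
  paired_expression_set(values, pairs = pairs, unit = unit)
}

#' Write a paired expression set to TSV
#'
#' Inverse of [read_expression()]; `write_expression()` then
#' [read_expression()] round-trips the matrix exactly (values are written in
#' full precision).
#'
#' @param x A `paired_expression_set`.
#' @param path Output TSV path.
#' @param pairs_path Optional path for the explicit pairing table.
#' @return `path`, invisibly.
#' @export
write_expression <- function(x, path, pairs_path = NULL) {
  df <- data.frame(gene_id = rownames(x$values),
                   format(x$values, digits = 17, trim = TRUE,
                          scientific = FALSE),
                   check.names = FALSE, stringsAsFactors = FALSE)
  .write_tsv(df, path)
  if (!is.null(pairs_path)) .write_tsv(x$pairs, pairs_path)
  invisible(path)
}
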