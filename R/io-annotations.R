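# Readers for gene-set (GMT), PPI edge-list and gene-location files.

#' Construct a gene-set collection
#'
#' @param term_id Character vector of unique term identifiers.
#' @param term_name Character vector of human-readable term names.
#' @param members List of character vectors of member gene ids (unique within
#'   a term).
#' @return Object of class `gene_set_collection`.
#' @export
gene_set_collection <- function(term_id, term_name, members) {
  .check(!anyDuplicated(term_id), "duplicated term_id")
  .check(length(term_id) == length(term_name) &&
           length(term_id) == length(members),
         "term_id, term_name and members must have equal length")
  members <- lapply(members, as.character)
  structure(list(term_id = as.character(term_id),
                 term_name = as.character(term_name),
                 members = members),
            class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat(sprintf("gene_set_collection: %d terms, median size %s\n",
              length(x$term_id),
              if (length(x$members)) stats::median(lengths(x$members)) else NA))
  invisible(x)
}

#' @export
length.gene_set_collection <- function(x) length(x$term_id)

#' Read a GMT gene-set file
#'
#' Standard GMT: one term per line, tab-separated `term_id`, description,
#' then member gene ids. Duplicate members within a term are dropped with a
#' message.
#'
#' @param path GMT file path.
#' @return A [gene_set_collection()].
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) {
    warning("empty GMT file: ", path, call. = FALSE)
    return(gene_set_collection(character(), character(), list()))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 3)
  .check(length(short) == 0,
         "GMT line %d has fewer than 3 fields", short[1])
  members <- lapply(seq_along(fields), function(i) {
    m <- fields[[i]][-(1:2)]
    m <- m[nzchar(m)]
    if (anyDuplicated(m)) {
      message(sprintf("GMT line %d: dropped %d duplicate member(s)",
                      i, sum(duplicated(m))))
      m <- unique(m)
    }
    m
  })
  gene_set_collection(vapply(fields, `[[`, "", 1L),
                      vapply(fields, `[[`, "", 2L),
                      members)
}

#' Write a gene-set collection as GMT
#'
#' @param x A `gene_set_collection`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(x, path) {
  lines <- vapply(seq_along(x$term_id), function(i) {
    paste(c(x$term_id[i], x$term_name[i], x$members[[i]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Read a protein-protein interaction edge list
#'
#' Two-column TSV of interacting gene pairs. The network is treated as
#' undirected: self-loops are removed (with a message) and duplicate edges —
#' including reversed duplicates — are collapsed.
#'
#' @param path Edge-list TSV path (no header required; a `gene_a`/`gene_b`
#'   header line is tolerated).
#' @return Data frame with columns `a`, `b` (sorted within row), one row per
#'   undirected edge.
#' @export
read_ppi <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (length(fields) > 0 && identical(tolower(fields[[1]][1]), "gene_a")) {
    fields <- fields[-1]
  }
  bad <- which(lengths(fields) != 2)
  .check(length(bad) == 0, "PPI line %d is not a 2-column record", bad[1])
  a <- vapply(fields, `[[`, "", 1L)
  b <- vapply(fields, `[[`, "", 2L)
  loops <- a == b
  if (any(loops)) {
    message(sprintf("dropped %d self-loop(s) from PPI background", sum(loops)))
    a <- a[!loops]; b <- b[!loops]
  }
  lo <- pmin(a, b); hi <- pmax(a, b)
  keep <- !duplicated(paste(lo, hi, sep = "\r"))
  data.frame(a = lo[keep], b = hi[keep], stringsAsFactors = FALSE)
}

#' Read gene chromosome locations (BED-like)
#'
#' Four-column TSV: chromosome, start, end, gene_id, with 0-based half-open
#' coordinates. Only the chromosome label is used downstream (cis/trans
#' co-location); coordinates are kept for link-file export.
#'
#' @param path BED-like TSV path.
#' @return Data frame with columns `gene_id`, `chromosome`, `start`, `end`,
#'   one row per gene.
#' @export
read_gene_locations <- function(path) {
  tab <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  .check(ncol(tab) >= 4, "locations file needs 4 columns (chrom,start,end,gene)")
  out <- data.frame(gene_id = as.character(tab[[4]]),
                    chromosome = as.character(tab[[1]]),
                    start = as.integer(tab[[2]]),
                    end = as.integer(tab[[3]]),
                    stringsAsFactors = FALSE)
  bad <- which(out$start > out$end)
  .check(length(bad) == 0,
         "location row %d: start > end for gene %s", bad[1], out$gene_id[bad[1]])
  dup <- out$gene_id[duplicated(out$gene_id)]
  .check(length(dup) == 0,
         "duplicate location record(s) for gene(s): %s",
         paste(unique(dup), collapse = ", "))
  out
}
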