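# Internal helpers shared across modules.

#' Round half away from zero
#'
#' Display rounding used for reported summaries (mean age "42.8", SD "9.3").
#' Base [round()] rounds half to even; printed clinical summaries
#' conventionally round half up, so exact .5 cases go away from zero here.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @return Rounded numeric vector.
#' @export
#' @examples
#' round_half_up(42.8125, 1) # 42.8
#' round_half_up(0.25, 1)    # 0.3 (round() would give 0.2)
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# stopifnot() with a formatted message
.check <- function(ok, ...) {
  if (!isTRUE(ok)) stop(sprintf(...), call. = FALSE)
  invisible(TRUE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Deterministic child seed derivation; keeps results < 2^31 for set.seed().
.child_seed <- function(seed, offset) {
  as.integer((as.double(seed) * 1009 + offset) %% 2147483647L)
}

# Write a data.frame as TSV with fixed, documented column order.
.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

.read_tsv <- function(path, ...) {
  utils::read.delim(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE, check.names = FALSE, ...)
}
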