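# Clinical table parsing and cohort summarization.

# category label -> ordinal code; accepts "T1".."T4", "N0"/"N1", "M0"/"M1",
# Roman stage "I".."IV", or bare numbers.
.ordinal_code <- function(x, prefix, range) {
  x <- as.character(x)
  x <- sub(paste0("^", prefix), "", x, ignore.case = TRUE)
  roman <- match(toupper(x), c("I", "II", "III", "IV"))
  out <- ifelse(is.na(roman), suppressWarnings(as.numeric(x)), roman)
  .check(!anyNA(out), "unparseable %s category value(s)", prefix)
  .check(all(out >= range[1] & out <= range[2]),
         "%s category outside %d..%d", prefix, range[1], range[2])
  as.integer(out)
}

#' Read a per-patient clinical table
#'
#' TSV with one row per patient. Recognised columns: `patient_id` (required,
#' unique), `age` (years), `tumor_cm` (continuous tumor diameter),
#' `t` (T category, `T1`-`T4` or 1-4), `n` (node, `N0`/`N1` or 0/1),
#' `m` (metastasis, `M0`/`M1` or 0/1), `stage` (`I`-`IV` or 1-4). Extra
#' columns (e.g. `gender`) are carried through untouched.
#'
#' @param path Clinical TSV path.
#' @return Data frame of class `clinical_table` with ordinal columns decoded
#'   to integers `t` (1-4), `n` (0/1), `m` (0/1), `stage` (1-4).
#' @export
read_clinical <- function(path) {
  tab <- .read_tsv(path)
  names(tab) <- tolower(names(tab))
  .check("patient_id" %in% names(tab), "clinical table needs a patient_id column")
  tab$patient_id <- as.character(tab$patient_id)
  .check(!anyDuplicated(tab$patient_id), "duplicated patient_id")
  if ("t" %in% names(tab)) tab$t <- .ordinal_code(tab$t, "T", c(1, 4))
  if ("n" %in% names(tab)) tab$n <- .ordinal_code(tab$n, "N", c(0, 1))
  if ("m" %in% names(tab)) tab$m <- .ordinal_code(tab$m, "M", c(0, 1))
  if ("stage" %in% names(tab)) {
    tab$stage <- .ordinal_code(tab$stage, "Stage ?", c(1, 4))
  }
  class(tab) <- c("clinical_table", "data.frame")
  tab
}

#' The packaged stage I PTC discovery cohort
#'
#' Transcription of the published clinical table for the 16 stage I papillary
#' thyroid carcinoma patients (all female): age, tumor diameter (cm) and TNM
#' staging. Shipped as plain text under `extdata`.
#'
#' @return A `clinical_table` data frame with 16 rows.
#' @export
#' @examples
#' summarize_cohort(ptc_cohort())
ptc_cohort <- function() {
  read_clinical(system.file("extdata", "ptc_cohort_table1.tsv",
                            package = "degnet", mustWork = TRUE))
}

#' Summarize a cohort's age and TNM composition
#'
#' Mean and sample standard deviation (n-1 denominator) of patient age, with
#' display values rounded half-up to one decimal, plus tallies of the T/N/M
#' and stage categories.
#'
#' @param clinical A `clinical_table` (or data frame with the same columns).
#' @param ages Numeric vector of ages; defaults to `clinical$age`.
#' @return Object of class `cohort_summary`: list with `n_patients`,
#'   `mean_age`, `sd_age` (full precision), `mean_age_display`,
#'   `sd_age_display` (1 decimal, half-up), and `tnm_counts`.
#' @export
summarize_cohort <- function(clinical, ages = clinical$age) {
  .check(!is.null(ages), "no ages available")
  ages <- as.numeric(ages)
  .check(all(is.finite(ages)), "non-finite age")
  n <- length(ages)
  .check(n >= 2, "sample SD undefined for n < 2 patients")
  .check(n == nrow(clinical), "ages must match the clinical table rows")
  tnm <- list()
  for (col in c("t", "n", "m", "stage")) {
    if (col %in% names(clinical)) {
      tnm[[col]] <- table(clinical[[col]])
    }
  }
  m <- mean(ages)
  s <- stats::sd(ages)
  structure(list(n_patients = n,
                 mean_age = m, sd_age = s,
                 mean_age_display = round_half_up(m, 1),
                 sd_age_display = round_half_up(s, 1),
                 tnm_counts = tnm),
            class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat(sprintf("cohort: %d patients, age %.1f +/- %.1f years\n",
              x$n_patients, x$mean_age_display, x$sd_age_display))
  for (nm in names(x$tnm_counts)) {
    tab <- x$tnm_counts[[nm]]
    cat(sprintf("  %s: %s\n", nm,
                paste(sprintf("%s=%d", names(tab), as.integer(tab)),
                      collapse = " ")))
  }
  invisible(x)
}
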