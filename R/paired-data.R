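#' Assemble a paired method-comparison dataset
#'
#' Builds the canonical tibble used throughout the package: one row per
#' patient sample, holding the reference-method concentration (e.g.
#' LC-MS/MS) and the test-method concentration (e.g. an immunoassay) in the
#' same unit. All downstream functions accept this tibble as their first
#' argument.
#'
#' @param reference Numeric vector of reference-method concentrations
#'   (strictly positive).
#' @param test Numeric vector of test-method concentrations (strictly
#'   positive, same length and unit as `reference`).
#' @param analyte Analyte label (single string), e.g. `"cortisol"`.
#' @param unit Concentration unit (single string), e.g. `"nmol/L"`.
#' @param sample_id Optional sample labels; defaults to `"S1"`, `"S2"`, ...
#'
#' @return A tibble with columns `sample_id`, `analyte`, `unit`,
#'   `reference`, `test`.
#' @examples
#' paired_dataset(c(1, 2, 3), c(1.2, 2.1, 3.3), analyte = "cortisol",
#'                unit = "umol/L")
#' @export
paired_dataset <- function(reference, test, analyte = "analyte",
                           unit = "unit", sample_id = NULL) {
  if (is.null(sample_id)) sample_id <- paste0("S", seq_along(reference))
  out <- tibble::tibble(
    sample_id = as.character(sample_id),
    analyte = as.character(analyte),
    unit = as.character(unit),
    reference = as.numeric(reference),
    test = as.numeric(test)
  )
  validate_paired_data(out)
  out
}

#' Validate a paired dataset
#'
#' Checks the invariants every analysis step relies on: equal-length,
#' complete, strictly positive concentration vectors with at least `min_n`
#' rows. Called internally by every fitting function; exported so ingestion
#' code can fail fast.
#'
#' @param data A data frame with numeric `reference` and `test` columns.
#' @param min_n Minimum number of rows required (default 3, the minimum for
#'   any regression fit).
#' @return `data`, invisibly, if valid; otherwise an error.
#' @export
validate_paired_data <- function(data, min_n = 3) {
  if (!is.data.frame(data)) {
    ab_abort("`data` must be a data frame.", "assaybias_schema_error")
  }
  for (col in c("reference", "test")) {
    if (!col %in% names(data)) {
      ab_abort(paste0("`data` is missing required column `", col, "`."),
               "assaybias_schema_error")
    }
  }
  x <- data$reference
  y <- data$test
  if (length(x) != length(y)) {
    ab_abort("`reference` and `test` must have equal length.",
             "assaybias_schema_error")
  }
  if (length(x) < min_n) {
    ab_abort(
      paste0("At least ", min_n, " paired samples are required; got ",
             length(x), "."),
      "assaybias_insufficient_data"
    )
  }
  if (anyNA(x) || anyNA(y) || !all(is.finite(x)) || !all(is.finite(y))) {
    ab_abort("Concentrations must be finite and non-missing.",
             "assaybias_schema_error")
  }
  if (any(x <= 0) || any(y <= 0)) {
    bad <- which(x <= 0 | y <= 0)
    ab_abort(
      paste0("Concentrations must be strictly positive (relative bias and ",
             "constant-CV weights are undefined otherwise); offending row(s): ",
             paste(head(bad, 5), collapse = ", "), "."),
      "assaybias_positivity_error"
    )
  }
  invisible(data)
}

# internal: pull x/y vectors from a data frame given tidyselect-style columns
extract_xy <- function(data, reference, test) {
  ref_quo <- enquo(reference)
  test_quo <- enquo(test)
  x <- if (quo_is_null(ref_quo)) data$reference else
    rlang::eval_tidy(ref_quo, data)
  y <- if (quo_is_null(test_quo)) data$test else
    rlang::eval_tidy(test_quo, data)
  if (is.null(x) || is.null(y)) {
    ab_abort("Could not find reference/test columns in `data`.",
             "assaybias_schema_error")
  }
  list(x = as.numeric(x), y = as.numeric(y))
}
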