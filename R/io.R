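#' Read paired method-comparison data from a delimited text file
#'
#' Expects a header row and (by default) columns `sample_id`, `analyte`,
#' `unit`, `reference`, `test`; other layouts are handled through
#' `col_map`. Rows with missing or non-positive concentrations are dropped
#' with a warning naming how many were removed (mirroring the exclusion
#' bookkeeping of a comparison study); an analyte reported in more than
#' one unit is an error.
#'
#' @param path Path to a CSV (or other delimited) file, UTF-8, decimal
#'   point. Set `decimal_comma = TRUE` for European-locale files using
#'   `;` as separator and `,` as decimal mark.
#' @param col_map Named character vector mapping the required roles to the
#'   file's column names, e.g.
#'   `c(sample_id = "id", analyte = "hormone", unit = "unit",
#'   reference = "lcms", test = "ia")`. Roles `reference` and `test` are
#'   mandatory; missing `sample_id`/`analyte`/`unit` roles are filled with
#'   defaults.
#' @param decimal_comma Logical; read `;`-separated, decimal-comma files.
#' @return A validated paired-measurement tibble (possibly multi-analyte).
#' @export
read_paired_csv <- function(path, col_map = NULL, decimal_comma = FALSE) {
  if (!file.exists(path)) {
    ab_abort(paste0("File not found: ", path), "assaybias_schema_error")
  }
  raw <- if (decimal_comma) {
    readr::read_csv2(path, show_col_types = FALSE, progress = FALSE)
  } else {
    readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  }
  if (is.null(col_map)) {
    col_map <- c(sample_id = "sample_id", analyte = "analyte",
                 unit = "unit", reference = "reference", test = "test")
  }
  for (role in c("reference", "test")) {
    if (!role %in% names(col_map) || !col_map[[role]] %in% names(raw)) {
      ab_abort(
        paste0("Required column for role `", role, "` not found in ", path,
               " (looked for `",
               if (role %in% names(col_map)) col_map[[role]] else role, "`)."),
        "assaybias_schema_error"
      )
    }
  }
  get_col <- function(role, default) {
    if (role %in% names(col_map) && col_map[[role]] %in% names(raw)) {
      raw[[col_map[[role]]]]
    } else {
      default
    }
  }
  out <- tibble::tibble(
    sample_id = as.character(get_col("sample_id", paste0("S", seq_len(nrow(raw))))),
    analyte = as.character(get_col("analyte", "analyte")),
    unit = as.character(get_col("unit", "unit")),
    reference = as.numeric(get_col("reference", NULL)),
    test = as.numeric(get_col("test", NULL))
  )
  units_per_analyte <- dplyr::summarise(
    dplyr::group_by(out, .data$analyte),
    n_units = dplyr::n_distinct(.data$unit), .groups = "drop"
  )
  if (any(units_per_analyte$n_units > 1)) {
    bad <- units_per_analyte$analyte[units_per_analyte$n_units > 1]
    ab_abort(paste0("Mixed units within analyte(s): ",
                    paste(bad, collapse = ", "), "."),
             "assaybias_unit_error")
  }
  keep <- is.finite(out$reference) & is.finite(out$test) &
    out$reference > 0 & out$test > 0
  if (any(!keep)) {
    dropped <- out$sample_id[!keep]
    warn(paste0("Dropped ", sum(!keep),
                " row(s) with missing or non-positive concentrations: ",
                paste(head(dropped, 10), collapse = ", "), "."))
    out <- out[keep, ]
  }
  validate_paired_data(out)
  out
}

#' Write paired data to CSV
#'
#' Writes the canonical column layout read back by [read_paired_csv()];
#' the round trip preserves values to full double precision.
#'
#' @param data A paired-measurement tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_paired_csv <- function(data, path) {
  validate_paired_data(data)
  cols <- intersect(c("sample_id", "analyte", "unit", "reference", "test"),
                    names(data))
  out <- data[cols]
  # 17 significant digits: lossless round trip for doubles
  for (col in c("reference", "test")) {
    out[[col]] <- formatC(out[[col]], digits = 17, format = "g")
  }
  readr::write_csv(out, path)
  invisible(path)
}

#' Default analysis configuration
#'
#' Bundles the tunable thresholds of the pipeline. All analysis functions
#' accept these values individually; `run_comparison()` takes the bundle.
#'
#' @param alpha Significance level for diagnostics (default 0.05).
#' @param rb_tolerance_pct Mean relative-bias acceptance band, percent
#'   (default 20).
#' @param lambda Deming error-variance ratio (default 1).
#' @param weighted Use the weighted (constant-CV) Deming fit (default TRUE).
#' @param jackknife_min_n Minimum n for jack-knife intervals (default 10).
#' @param pb_grid_size Points in the proportional-bias grid (default 100).
#' @param ba_axis Bland-Altman abscissa, `"reference"` or `"mean"`.
#' @param conf_level Confidence level (default 0.95).
#' @param seed Seed for any stochastic step (default 1).
#' @return A list of class `run_config`.
#' @export
run_config <- function(alpha = 0.05, rb_tolerance_pct = 20, lambda = 1,
                       weighted = TRUE, jackknife_min_n = 10,
                       pb_grid_size = 100,
                       ba_axis = c("reference", "mean"),
                       conf_level = 0.95, seed = 1L) {
  ba_axis <- match.arg(ba_axis)
  stopifnot(alpha > 0, alpha < 1, rb_tolerance_pct > 0, lambda > 0,
            jackknife_min_n >= 3, pb_grid_size >= 2,
            conf_level > 0, conf_level < 1)
  structure(
    list(alpha = alpha, rb_tolerance_pct = rb_tolerance_pct,
         lambda = lambda, weighted = weighted,
         jackknife_min_n = jackknife_min_n, pb_grid_size = pb_grid_size,
         ba_axis = ba_axis, conf_level = conf_level, seed = as.integer(seed)),
    class = "run_config"
  )
}

#' Write / read a configuration as YAML
#'
#' The round trip is lossless: `read_config(write_config(cfg, path))`
#' reproduces `cfg` exactly.
#'
#' @param config A [run_config()].
#' @param path File path.
#' @return `write_config()` returns `path` invisibly; `read_config()`
#'   returns a `run_config`.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(run_config, vals)
}
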