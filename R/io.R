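# Readers/writers for study tables and result records, and the top-level
# driver used by the command-line script.

#' Read a study table from CSV
#'
#' Expects the header `study_id, mean_t, sd_t, n_t, mean_c, sd_c, n_c`;
#' extra columns (moderators such as dose) are kept. Validation errors name
#' the offending row.
#'
#' @param path Path to a CSV file.
#' @param require_positive_means Passed to [validate_studies()].
#' @return A validated study table.
#' @export
read_study_table <- function(path, require_positive_means = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  studies <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_studies(studies, require_positive_means = require_positive_means)
}

# 1-decimal display companions for percent-scale columns
with_rounded <- function(df) {
  pct_cols <- intersect(
    c("va_eup", "paco2_eup", "co2_reserve", "va_reserve", "plant_gain",
      "loop_gain", "dlg_pct"),
    names(df)
  )
  for (cn in pct_cols) df[[paste0(cn, "_1dp")]] <- round(df[[cn]], 1)
  df
}

#' Write result records to CSV or JSON
#'
#' Data frames (intervention tables, sweep results, study tables,
#' leave-one-out tables) are written with stable column order and full
#' float precision; percent-scale columns additionally get 1-decimal
#' display companions (`*_1dp`). Lists and model records are written as
#' JSON.
#'
#' @param records A data frame or a list of named scalars.
#' @param path Output file path.
#' @param dialect `"csv"` or `"json"`; defaults by file extension.
#' @return `path`, invisibly.
#' @export
write_results <- function(records, path, dialect = c("auto", "csv", "json")) {
  dialect <- match.arg(dialect)
  if (dialect == "auto") {
    dialect <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  }
  if (is.data.frame(records)) records <- with_rounded(as.data.frame(records))
  if (dialect == "csv") {
    if (!is.data.frame(records)) records <- as.data.frame(records)
    utils::write.csv(records, path, row.names = FALSE)
  } else {
    jsonlite::write_json(records, path, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows")
  }
  invisible(path)
}

#' Solve the baseline model and optionally an intervention
#'
#' The top-level driver behind the command-line interface: solves the
#' operating point for the given baseline anchors and, if an intervention
#' is supplied, the post-intervention comparison.
#'
#' @param base A [baseline_inputs()]; defaults to the pooled control values.
#' @param spec Optional [intervention_spec()].
#' @return A list with `baseline` (named record of the operating point) and,
#'   when `spec` is given, `comparison` (the [apply_intervention()] result)
#'   plus `pct_change` and `delta_mmHg` records.
#' @examples
#' run_model()
#' run_model(spec = intervention_spec(at_shift_pct = -15))
#' @export
run_model <- function(base = baseline_inputs(), spec = NULL) {
  m <- model_from_baseline(base)
  out <- list(baseline = as_record(m$op))
  if (!is.null(spec)) {
    cmp <- apply_intervention(base, spec)
    out$comparison <- cmp
    out$pct_change <- cmp$pct_change
    out$delta_mmHg <- cmp$delta_mmHg
  }
  out
}
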