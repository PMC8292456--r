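# Report-only validation of a long visit table.

#' Validate a long visit table
#'
#' Checks the schema and plausibility of a long-format visit table
#' without mutating it: required columns, numeric values, valid group
#' labels, non-negative hemoglobin, duplicated subject-marker-visit
#' rows. Purely report-producing; [run_pipeline()] stops only on missing
#' required columns.
#'
#' @param visits A data.frame to check.
#' @return Data.frame of issues (`row`, `column`, `problem`); zero rows
#'   when the table is well formed.
#' @export
validate_input <- function(visits) {
  issues <- list()
  add <- function(row, column, problem) {
    issues[[length(issues) + 1L]] <<- data.frame(
      row = row, column = column, problem = problem,
      stringsAsFactors = FALSE)
  }
  required <- c("subject_id", "group", "marker", "duration_years", "value")
  missing_cols <- setdiff(required, names(visits))
  for (mc in missing_cols) add(NA_integer_, mc, "missing_column")
  if (length(missing_cols) == 0L) {
    bad_group <- which(!visits$group %in% c("pd", "control"))
    for (i in bad_group) add(i, "group", "unknown_group_label")
    if (!is.numeric(visits$value)) {
      suppressWarnings(v <- as.numeric(visits$value))
      for (i in which(is.na(v) & !is.na(visits$value)))
        add(i, "value", "non_numeric_value")
    }
    if (!is.numeric(visits$duration_years)) {
      suppressWarnings(d <- as.numeric(visits$duration_years))
      for (i in which(is.na(d) & !is.na(visits$duration_years)))
        add(i, "duration_years", "non_numeric_duration")
    } else {
      for (i in which(!is.finite(visits$duration_years)))
        add(i, "duration_years", "non_finite_duration")
    }
    key_cols <- intersect(c("subject_id", "marker", "visit_label"),
                          names(visits))
    key <- do.call(paste, c(visits[key_cols], sep = "\r"))
    for (i in which(duplicated(key)))
      add(i, paste(key_cols, collapse = "+"), "duplicated_visit_row")
  }
  if ("hemoglobin_ng_ml" %in% names(visits)) {
    for (i in which(visits$hemoglobin_ng_ml < 0))
      add(i, "hemoglobin_ng_ml", "negative_hemoglobin")
  }
  if (length(issues)) do.call(rbind, issues) else
    data.frame(row = integer(), column = character(),
               problem = character(), stringsAsFactors = FALSE)
}
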