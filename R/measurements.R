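# Ingest of long-format intraoperative measurement tables and the artifact
# filter that gates all downstream computation.

#' Monitored variable names
#'
#' The six variables the pipeline understands: mean arterial pressure, the
#' bispectral index, and the four inhaled anesthetic agents whose end-tidal
#' concentrations are summed into a total MAC.
#'
#' @return Character vector of valid `variable` codes.
#' @export
tvi_variables <- function() {
  c("MAP", "BIS", "ISOFLURANE", "DESFLURANE", "SEVOFLURANE", "NITROUS_OXIDE")
}

inhaled_agents <- function() {
  c("ISOFLURANE", "DESFLURANE", "SEVOFLURANE", "NITROUS_OXIDE")
}

#' Physiologic artifact limits
#'
#' Extreme values are treated as monitoring artifacts and removed before any
#' statistic is computed: MAP outside (10, 250) mmHg, BIS outside (1, 100)
#' (a BIS of exactly 0 is a monitor connect/disconnect artifact and falls
#' below the lower limit), and summed MAC above 3. All comparisons are
#' strict, so boundary values (MAP of exactly 10 or 250, BIS of 1 or 100,
#' MAC of 3) are retained.
#'
#' @param map_low,map_high MAP retention bounds, mmHg.
#' @param bis_low,bis_high BIS retention bounds.
#' @param mac_high Upper retention bound for the summed MAC.
#' @return An object of class `artifact_limits`.
#' @export
artifact_limits <- function(map_low = 10, map_high = 250,
                            bis_low = 1, bis_high = 100,
                            mac_high = 3) {
  lims <- list(map_low = map_low, map_high = map_high,
               bis_low = bis_low, bis_high = bis_high,
               mac_high = mac_high)
  if (any(!vapply(lims, is.numeric, logical(1))) ||
      any(unlist(lims) <= 0)) {
    stop_input("all artifact limits must be positive numbers")
  }
  if (map_low >= map_high || bis_low >= bis_high) {
    stop_input("lower artifact limits must be below upper limits")
  }
  structure(lims, class = "artifact_limits")
}

measurement_columns <- c("case_id", "t_min", "variable", "value", "source")

#' Read a long-format measurement table
#'
#' Expects a CSV with columns `case_id,t_min,variable,value,source`. Times
#' are minutes from the first recorded measurement of each case; they are
#' rounded to `t_round` minutes (default one second) so that "simultaneous"
#' measurements from different monitors compare equal. The `source` column
#' (ARTERIAL / NONINVASIVE) is meaningful only for MAP and must be empty for
#' other variables.
#'
#' @param path CSV file path.
#' @param t_round Timestamp rounding precision in minutes; `NULL` disables
#'   rounding.
#' @return A `data.frame` of measurements sorted by case and time.
#' @export
read_measurements <- function(path, t_round = 1 / 60) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  missing_cols <- setdiff(measurement_columns, names(raw))
  if (length(missing_cols) > 0L) {
    stop_input("measurement file is missing required column(s): ",
               paste(missing_cols, collapse = ", "))
  }
  raw <- raw[measurement_columns]
  value <- suppressWarnings(as.numeric(raw$value))
  bad <- which(is.na(value))
  if (length(bad) > 0L) {
    stop_input("non-numeric measurement value at row(s): ",
               paste(utils::head(bad, 10L), collapse = ", "))
  }
  t_min <- suppressWarnings(as.numeric(raw$t_min))
  bad_t <- which(is.na(t_min) | t_min < 0)
  if (length(bad_t) > 0L) {
    stop_input("missing, non-numeric or negative t_min at row(s): ",
               paste(utils::head(bad_t, 10L), collapse = ", "))
  }
  variable <- toupper(trimws(raw$variable))
  unknown <- setdiff(unique(variable), tvi_variables())
  if (length(unknown) > 0L) {
    stop_input("unknown variable name(s): ", paste(unknown, collapse = ", "))
  }
  source <- toupper(trimws(raw$source))
  source[source == "" | source == "NA"] <- NA_character_
  bad_src <- setdiff(unique(source[!is.na(source)]),
                     c("ARTERIAL", "NONINVASIVE"))
  if (length(bad_src) > 0L) {
    stop_input("unknown MAP source(s): ", paste(bad_src, collapse = ", "))
  }
  if (any(is.na(source) & variable == "MAP")) {
    stop_input("MAP rows must carry a source (ARTERIAL or NONINVASIVE)")
  }
  if (any(!is.na(source) & variable != "MAP")) {
    stop_input("source must be empty for non-MAP variables")
  }
  if (!is.null(t_round)) t_min <- round(t_min / t_round) * t_round
  out <- data.frame(case_id = raw$case_id, t_min = t_min,
                    variable = variable, value = value, source = source,
                    stringsAsFactors = FALSE)
  out <- out[order(out$case_id, out$t_min), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read a per-case metadata table
#'
#' Columns: `case_id,patient_id,age_years,sex,asa_status,emergent,specialty,`
#' `procedure,cpb_used,cpb_start_min,cpb_end_min,repeat_surgery,days_to_death`.
#'
#' @param path CSV file path.
#' @return A `data.frame` with one row per case.
#' @export
read_cases <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("case_id", "patient_id", "age_years", "sex", "asa_status",
            "emergent", "specialty", "procedure", "cpb_used",
            "cpb_start_min", "cpb_end_min", "repeat_surgery",
            "days_to_death")
  missing_cols <- setdiff(need, names(x))
  if (length(missing_cols) > 0L) {
    stop_input("case file is missing required column(s): ",
               paste(missing_cols, collapse = ", "))
  }
  x$case_id <- as.character(x$case_id)
  x$patient_id <- as.character(x$patient_id)
  x$age_years <- as.numeric(x$age_years)
  x$asa_status <- as.integer(x$asa_status)
  x$emergent <- as.logical(x$emergent)
  x$cpb_used <- as.logical(x$cpb_used)
  x$repeat_surgery <- as.logical(x$repeat_surgery)
  x$cpb_start_min <- suppressWarnings(as.numeric(x$cpb_start_min))
  x$cpb_end_min <- suppressWarnings(as.numeric(x$cpb_end_min))
  x$days_to_death <- suppressWarnings(as.integer(x$days_to_death))
  if (any(!is.na(x$days_to_death) & x$days_to_death < 0)) {
    stop_input("days_to_death must be non-negative")
  }
  if (any(x$age_years < 18, na.rm = TRUE)) {
    stop_input("adult cohort expected: age_years must be >= 18")
  }
  if (any(!x$cpb_used & (!is.na(x$cpb_start_min) | !is.na(x$cpb_end_min)))) {
    stop_input("cpb interval present for a case with cpb_used = FALSE")
  }
  x[order(x$case_id), , drop = FALSE]
}

#' Read a medication administration table
#'
#' Columns: `case_id,drug,total_dose` (one row per case-drug pair, dose
#' totalled over the case).
#'
#' @param path CSV file path.
#' @return A `data.frame`.
#' @export
read_medications <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("case_id", "drug", "total_dose")
  missing_cols <- setdiff(need, names(x))
  if (length(missing_cols) > 0L) {
    stop_input("medication file is missing required column(s): ",
               paste(missing_cols, collapse = ", "))
  }
  x$case_id <- as.character(x$case_id)
  x$total_dose <- as.numeric(x$total_dose)
  if (any(!is.na(x$total_dose) & x$total_dose < 0)) {
    stop_input("total_dose must be non-negative")
  }
  x
}

#' Read a cohort directory
#'
#' Reads `measurements.csv`, `cases.csv`, `medications.csv` (and, when
#' present, `truth.csv` from the synthetic generator) from one directory.
#'
#' @param dir Directory path.
#' @param t_round Passed to [read_measurements()].
#' @return A list of class `tvi_cohort`.
#' @export
read_cohort <- function(dir, t_round = 1 / 60) {
  out <- list(
    measurements = read_measurements(file.path(dir, "measurements.csv"),
                                     t_round = t_round),
    cases = read_cases(file.path(dir, "cases.csv")),
    medications = read_medications(file.path(dir, "medications.csv"))
  )
  truth_path <- file.path(dir, "truth.csv")
  if (file.exists(truth_path)) {
    out$truth <- utils::read.csv(truth_path, stringsAsFactors = FALSE)
    out$truth$case_id <- as.character(out$truth$case_id)
  }
  structure(out, class = "tvi_cohort")
}

#' Prefer arterial-line MAP over noninvasive MAP
#'
#' At any timestamp where a case has both an ARTERIAL and a NONINVASIVE MAP
#' value, only the arterial value is retained; lone values of either source
#' pass through, as do duplicate values of the same source.
#'
#' @param measurements Measurement `data.frame` (see [read_measurements()]).
#' @return The measurements with shadowed noninvasive MAP rows dropped.
#' @export
resolve_map_source <- function(measurements) {
  is_map <- measurements$variable == "MAP"
  if (!any(is_map)) return(measurements)
  key <- paste0(measurements$case_id, "\r", format(measurements$t_min, digits = 15))
  art_keys <- unique(key[is_map & measurements$source == "ARTERIAL"])
  drop <- is_map & measurements$source == "NONINVASIVE" & key %in% art_keys
  out <- measurements[!drop, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Remove physiologically impossible (artifact) values
#'
#' Applies the strict retention bounds of [artifact_limits()] to MAP, BIS,
#' and summed-MAC rows; inhaled-agent rows are not bounded here because the
#' MAC limit applies to the agent-summed value (see [summed_mac_stream()]).
#' The removed rows are returned with a `reason` column for audit logging.
#'
#' @param measurements Measurement `data.frame`; `variable` may include
#'   `"MAC"` rows produced by [summed_mac_stream()].
#' @param limits An [artifact_limits()] object.
#' @return A list with elements `retained` and `removed` (the latter with a
#'   `reason` column). The two partition the input.
#' @export
remove_artifacts <- function(measurements, limits = artifact_limits()) {
  stopifnot(inherits(limits, "artifact_limits"))
  v <- measurements$variable
  x <- measurements$value
  reason <- rep(NA_character_, length(x))
  reason[v == "MAP" & x > limits$map_high] <- "map_above_limit"
  reason[v == "MAP" & x < limits$map_low] <- "map_below_limit"
  reason[v == "BIS" & x > limits$bis_high] <- "bis_above_limit"
  reason[v == "BIS" & x < limits$bis_low] <- "bis_below_limit"
  reason[v == "MAC" & x > limits$mac_high] <- "mac_above_limit"
  keep <- is.na(reason)
  removed <- measurements[!keep, , drop = FALSE]
  removed$reason <- reason[!keep]
  retained <- measurements[keep, , drop = FALSE]
  rownames(retained) <- NULL
  rownames(removed) <- NULL
  list(retained = retained, removed = removed)
}

#' Write the artifact audit log
#'
#' @param removed The `removed` element of [remove_artifacts()] /
#'   [prepare_stream()].
#' @param path Output CSV path.
#' @return The path, invisibly.
#' @export
write_artifact_log <- function(removed, path) {
  utils::write.csv(removed, path, row.names = FALSE, na = "")
  invisible(path)
}
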