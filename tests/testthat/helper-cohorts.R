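# Shared fixtures, built in code. The 2000-case recovery cohort and its fit
# are expensive, so they are generated once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

regime_names_for_test <- c("elevated", "mixed", "depressed")

recovery_cohort <- function() {
  if (is.null(.fixture_cache$cohort)) {
    .fixture_cache$cohort <- generate_cohort(cohort_spec(n_cases = 2000,
                                                         seed = 11))
  }
  .fixture_cache$cohort
}

recovery_fit <- function() {
  if (is.null(.fixture_cache$fit)) {
    .fixture_cache$fit <- tvi_fit(recovery_cohort(), seed = 7)
  }
  .fixture_cache$fit
}

small_cohort <- function() {
  if (is.null(.fixture_cache$small)) {
    .fixture_cache$small <- generate_cohort(cohort_spec(n_cases = 200,
                                                        seed = 5))
  }
  .fixture_cache$small
}

# Quick long-format measurement rows.
meas <- function(case_id, t_min, variable, value, source = NA_character_) {
  data.frame(case_id = case_id, t_min = t_min, variable = variable,
             value = value, source = source, stringsAsFactors = FALSE)
}

# Assemble a tvi_profiles object directly from a windows table (for event /
# featurization tests that need exact window means).
make_profiles <- function(windows, stats = NULL) {
  need <- c("map_mean_z", "bis_mean_z", "mac_mean_z",
            "map_mean", "bis_mean", "mac_mean")
  for (col in setdiff(need, names(windows))) windows[[col]] <- NA_real_
  if (is.null(windows$tvi)) {
    windows$tvi <- windows$map_mean_z + windows$bis_mean_z + windows$mac_mean_z
  }
  if (is.null(windows$n_timepoints)) windows$n_timepoints <- 5L
  if (is.null(windows$t_start)) windows$t_start <- windows$window_index * 10
  if (is.null(windows$t_end)) windows$t_end <- windows$window_index * 10 + 9
  t_first <- tapply(windows$t_start, windows$case_id, min)
  t_last <- tapply(windows$t_end, windows$case_id, max)
  spans <- data.frame(case_id = names(t_first),
                      t_first = as.vector(t_first),
                      t_last = as.vector(t_last),
                      stringsAsFactors = FALSE)
  spans$n_windows <- as.vector(
    tapply(windows$window_index, windows$case_id, max)[spans$case_id]) + 1L
  spans$n_tvi <- as.vector(
    tapply(!is.na(windows$tvi), windows$case_id, sum)[spans$case_id])
  structure(list(windows = windows, spans = spans, stats = stats,
                 excluded = data.frame(case_id = character(0),
                                       reason = character(0)),
                 window_size = 5L),
            class = "tvi_profiles")
}

write_csv_tmp <- function(df) {
  path <- tempfile(fileext = ".csv")
  utils::write.csv(df, path, row.names = FALSE, na = "")
  path
}
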