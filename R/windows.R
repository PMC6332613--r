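# Windowed TVI profile assembly. A window spans five consecutive distinct
# measurement timepoints (any of MAP/BIS/MAC, alone or in combination); the
# last window of a case holds the 1-4 remaining timepoints. Within a window
# each variable's z-scores are averaged, and the TVI is the sum of the three
# averages - defined only when all three variables have data in the window.

# Vectorized window construction over a whole (multi-case) stream.
window_table <- function(stream, stats, window_size = 5L) {
  if (nrow(stream) == 0L) stop_input("cannot build windows from an empty stream")
  if (!is.numeric(window_size) || window_size < 1L) {
    stop_input("window_size must be a positive integer")
  }
  window_size <- as.integer(window_size)
  s <- stream[order(stream$case_id, stream$t_min), , drop = FALSE]
  z <- zscore(s$value, s$variable, stats)
  tkey <- paste0(s$case_id, "\r", format(s$t_min, digits = 15))
  new_tp <- !duplicated(tkey)
  tp_idx <- stats::ave(as.integer(new_tp), s$case_id, FUN = cumsum)
  win <- (tp_idx - 1L) %/% window_size
  wkey <- paste0(s$case_id, "\r", win)

  first <- !duplicated(wkey)
  out <- data.frame(case_id = s$case_id[first],
                    window_index = win[first],
                    stringsAsFactors = FALSE)
  out$n_timepoints <- as.vector(
    rowsum(as.integer(new_tp), wkey)[paste0(out$case_id, "\r", out$window_index), ])
  tmin <- tapply(s$t_min, wkey, min)
  tmax <- tapply(s$t_min, wkey, max)
  rkey <- paste0(out$case_id, "\r", out$window_index)
  out$t_start <- as.vector(tmin[rkey])
  out$t_end <- as.vector(tmax[rkey])

  for (v in c("MAP", "BIS", "MAC")) {
    sel <- s$variable == v
    col <- tolower(v)
    if (any(sel)) {
      mz <- grouped_mean(z[sel], wkey[sel])
      mr <- grouped_mean(s$value[sel], wkey[sel])
      out[[paste0(col, "_mean_z")]] <- unname(mz[rkey])
      out[[paste0(col, "_mean")]] <- unname(mr[rkey])
    } else {
      out[[paste0(col, "_mean_z")]] <- NA_real_
      out[[paste0(col, "_mean")]] <- NA_real_
    }
  }
  out$tvi <- out$map_mean_z + out$bis_mean_z + out$mac_mean_z
  out <- out[order(out$case_id, out$window_index), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Build TVI windows for one case
#'
#' Groups the case's distinct measurement timepoints five at a time (in
#' chronological order, non-overlapping; the final window keeps the 1-4
#' remaining timepoints) and averages each variable's z-scores within each
#' window. A variable absent from a window yields an `NA` mean; the window
#' TVI (see [compute_tvi()]) is `NA` unless all three means exist. Raw-scale
#' window means are carried alongside for triple-low-state evaluation.
#'
#' @param case_stream Prepared measurement stream of a single case.
#' @param stats A [fit_population_stats()] object (fitted on the whole
#'   population, not this case).
#' @param window_size Distinct timepoints per window (default 5).
#' @return A `data.frame` with one row per window: `case_id`,
#'   `window_index` (0-based), `n_timepoints`, `t_start`, `t_end`, per-variable
#'   z-score means (`map_mean_z`, ...), raw means (`map_mean`, ...), and `tvi`.
#' @export
build_windows <- function(case_stream, stats, window_size = 5L) {
  if (nrow(case_stream) == 0L) stop_input("empty case: no retained measurements")
  if (length(unique(case_stream$case_id)) != 1L) {
    stop_input("build_windows expects a single case; use assemble_profiles ",
               "for a cohort")
  }
  window_table(case_stream, stats, window_size)
}

#' Window TVI value
#'
#' The Triple Variable Index of a window: the sum of the window's mean MAP,
#' BIS, and MAC z-scores, defined only when all three variables have data in
#' the window.
#'
#' @param window A one-row window `data.frame` (or list) with elements
#'   `map_mean_z`, `bis_mean_z`, `mac_mean_z`.
#' @return The TVI value, or `NA` if any variable mean is missing.
#' @export
compute_tvi <- function(window) {
  zs <- c(window$map_mean_z, window$bis_mean_z, window$mac_mean_z)
  if (length(zs) != 3L || anyNA(zs)) return(NA_real_)
  sum(zs)
}

#' Assemble TVI profiles for a cohort
#'
#' Builds the windowed TVI profile of every case in the prepared stream.
#' Cases in which no window attains a TVI value (i.e. concurrent MAP, BIS,
#' and MAC monitoring never occurred within one window) do not constitute
#' study profiles; they are excluded here with a logged reason, mirroring
#' the cohort inclusion requirement that at least one TVI value exist per
#' surgery.
#'
#' @param prepared Output of [prepare_stream()], or a stream `data.frame`.
#' @param stats Optional [fit_population_stats()]; fitted from the stream
#'   when `NULL`.
#' @param window_size Distinct timepoints per window (default 5).
#' @return An object of class `tvi_profiles`: list with `windows` (all
#'   admitted windows), `spans` (per-case monitoring span and window count),
#'   `stats`, `excluded` (cases dropped, with reason), and `window_size`.
#' @export
assemble_profiles <- function(prepared, stats = NULL, window_size = 5L) {
  stream <- if (is.data.frame(prepared)) prepared else prepared$stream
  if (is.null(stats)) stats <- fit_population_stats(stream)
  win <- window_table(stream, stats, window_size)

  t_first <- tapply(stream$t_min, stream$case_id, min)
  t_last <- tapply(stream$t_min, stream$case_id, max)
  spans <- data.frame(case_id = names(t_first),
                      t_first = as.vector(t_first),
                      t_last = as.vector(t_last),
                      stringsAsFactors = FALSE)
  n_windows <- tapply(win$window_index, win$case_id, max) + 1L
  n_tvi <- tapply(!is.na(win$tvi), win$case_id, sum)
  spans$n_windows <- as.vector(n_windows[spans$case_id])
  spans$n_tvi <- as.vector(n_tvi[spans$case_id])

  bad <- spans$case_id[spans$n_tvi == 0L]
  excluded <- data.frame(case_id = bad,
                         reason = rep("no_tvi_window", length(bad)),
                         stringsAsFactors = FALSE)
  if (length(bad) > 0L) {
    win <- win[!(win$case_id %in% bad), , drop = FALSE]
    spans <- spans[!(spans$case_id %in% bad), , drop = FALSE]
    rownames(win) <- NULL
    rownames(spans) <- NULL
  }
  structure(list(windows = win, spans = spans, stats = stats,
                 excluded = excluded, window_size = as.integer(window_size)),
            class = "tvi_profiles")
}

#' @export
print.tvi_profiles <- function(x, ...) {
  cat("TVI profiles:", nrow(x$spans), "cases,",
      nrow(x$windows), "windows (window size", x$window_size, ")\n")
  cat("  TVI values:", sum(!is.na(x$windows$tvi)),
      "| windows lacking TVI:", sum(is.na(x$windows$tvi)), "\n")
  if (nrow(x$excluded) > 0L) {
    cat("  excluded cases (no TVI window):", nrow(x$excluded), "\n")
  }
  invisible(x)
}

#' Map a timestamp to a proportion of the monitoring period
#'
#' A measurement recorded at minute `t` of a case whose first and last
#' recorded measurements span `span` is assigned
#' `(t - t_first) / (t_last - t_first)`; e.g. minute 6 of a 60-minute span
#' maps to 0.10.
#'
#' @param t Time(s) in minutes.
#' @param span Numeric length-2 vector `c(t_first, t_last)`.
#' @return Proportion(s) in `[0, 1]`.
#' @export
temporal_proportion <- function(t, span) {
  if (length(span) != 2L || !is.numeric(span)) {
    stop_input("span must be numeric c(t_first, t_last)")
  }
  if (span[2] <= span[1]) stop_input("zero- or negative-length monitoring span")
  if (any(t < span[1] | t > span[2])) {
    stop_input("t outside the monitoring span")
  }
  (t - span[1]) / (span[2] - span[1])
}

#' Map a window index to a proportion of the profile
#'
#' Window-level analogue of [temporal_proportion()]: window `i` (0-based) of
#' a `W`-window profile maps to `i / (W - 1)`, so the first window is 0 and
#' the last is 1; a single-window profile maps to 0.
#'
#' @param i 0-based window index (vectorized).
#' @param w Total number of windows in the profile.
#' @return Proportion(s) in `[0, 1]`.
#' @export
window_proportion <- function(i, w) {
  if (any(w < 1L)) stop_input("profile must contain at least one window")
  if (any(i < 0L | i > w - 1L)) stop_input("window index out of range")
  ifelse(w == 1L, 0, i / (w - 1))
}

#' Write profiles as a tidy CSV
#'
#' One row per window: `case_id,window_index,n_timepoints,map_mean_z,
#' bis_mean_z,mac_mean_z,tvi` plus raw-scale means; absent values are empty
#' cells.
#'
#' @param profiles A [assemble_profiles()] object.
#' @param path Output CSV path.
#' @return The path, invisibly.
#' @export
write_profiles <- function(profiles, path) {
  stopifnot(inherits(profiles, "tvi_profiles"))
  utils::write.csv(profiles$windows, path, row.names = FALSE, na = "")
  invisible(path)
}
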