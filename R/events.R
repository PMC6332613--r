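# Intraoperative event detection (hypotension, triple low state), mortality
# window classification, and per-cluster characterization tables.

#' Triple low state criteria
#'
#' A profile window is in the triple low state when its mean MAP, BIS, and
#' MAC are all strictly below the thresholds: MAP < 75 mmHg, BIS < 45,
#' MAC < 0.8.
#'
#' @param map_thresh,bis_thresh,mac_thresh Strict upper thresholds.
#' @return An object of class `triple_low_criteria`.
#' @export
triple_low_criteria <- function(map_thresh = 75, bis_thresh = 45,
                                mac_thresh = 0.8) {
  if (any(c(map_thresh, bis_thresh, mac_thresh) <= 0)) {
    stop_input("triple low thresholds must be positive")
  }
  structure(list(map_thresh = map_thresh, bis_thresh = bis_thresh,
                 mac_thresh = mac_thresh),
            class = "triple_low_criteria")
}

#' Detect intraoperative hypotension
#'
#' A case experienced intraoperative hypotension (IOH) when any recorded
#' (post-artifact-removal) MAP measurement was strictly below the threshold.
#' Unlike triple-low detection, this is evaluated on raw measurements, not
#' window means.
#'
#' @param stream Prepared measurement stream (one or many cases).
#' @param threshold IOH threshold in mmHg (default 55, strict `<`).
#' @return Named logical vector, one element per case.
#' @export
detect_ioh <- function(stream, threshold = 55) {
  m <- stream[stream$variable == "MAP", , drop = FALSE]
  cases <- unique(stream$case_id)
  if (!all(cases %in% m$case_id)) {
    stop_input("case(s) without any MAP measurement: ",
               paste(utils::head(setdiff(cases, m$case_id), 5L),
                     collapse = ", "))
  }
  mins <- tapply(m$value, m$case_id, min)
  out <- as.vector(mins[cases]) < threshold
  stats::setNames(out, cases)
}

#' Detect triple low state exposure per profile
#'
#' A window qualifies when its raw-scale MAP, BIS, and MAC means are all
#' present and strictly below the [triple_low_criteria()] thresholds.
#' Cumulative exposure is the count of qualifying windows.
#'
#' @param profiles A [assemble_profiles()] object.
#' @param criteria A [triple_low_criteria()] object.
#' @return `data.frame` with `case_id`, `tls_any`, `tls_window_count`.
#' @export
detect_tls <- function(profiles, criteria = triple_low_criteria()) {
  stopifnot(inherits(profiles, "tvi_profiles"),
            inherits(criteria, "triple_low_criteria"))
  w <- profiles$windows
  qual <- !is.na(w$map_mean) & !is.na(w$bis_mean) & !is.na(w$mac_mean) &
    w$map_mean < criteria$map_thresh &
    w$bis_mean < criteria$bis_thresh &
    w$mac_mean < criteria$mac_thresh
  counts <- tapply(qual, w$case_id, sum)
  out <- data.frame(case_id = profiles$spans$case_id, stringsAsFactors = FALSE)
  out$tls_window_count <- as.integer(counts[out$case_id])
  out$tls_any <- out$tls_window_count >= 1L
  out[c("case_id", "tls_any", "tls_window_count")]
}

mortality_classes <- c("d30", "d31_365", "d366_730",
                       "survived_beyond_730", "unknown")

#' Classify postoperative mortality windows
#'
#' Death on postoperative day `d` maps to `d30` when `d <= 30`, `d31_365`
#' when `31 <= d <= 365`, `d366_730` when `366 <= d <= 730`, and
#' `survived_beyond_730` otherwise. Cases without a recorded death are
#' `survived_beyond_730` when follow-up reaches 730 days (the default
#' assumption), else `unknown`.
#'
#' @param days_to_death Integer vector; `NA` = no recorded death.
#' @param followup_days Follow-up duration for cases without a death; a
#'   scalar or vector. Default `Inf` (complete follow-up).
#' @return Factor with levels `d30`, `d31_365`, `d366_730`,
#'   `survived_beyond_730`, `unknown`.
#' @export
classify_mortality <- function(days_to_death, followup_days = Inf) {
  d <- days_to_death
  if (any(!is.na(d) & d < 0)) stop_input("days_to_death must be non-negative")
  fu <- rep_len(followup_days, length(d))
  cls <- rep("unknown", length(d))
  cls[!is.na(d) & d <= 30] <- "d30"
  cls[!is.na(d) & d >= 31 & d <= 365] <- "d31_365"
  cls[!is.na(d) & d >= 366 & d <= 730] <- "d366_730"
  cls[!is.na(d) & d > 730] <- "survived_beyond_730"
  cls[is.na(d) & fu >= 730] <- "survived_beyond_730"
  factor(cls, levels = mortality_classes)
}

#' Per-case event flags
#'
#' Convenience combination of [detect_ioh()] and [detect_tls()] for the
#' admitted profiles.
#'
#' @param stream Prepared measurement stream.
#' @param profiles A [assemble_profiles()] object.
#' @param criteria A [triple_low_criteria()] object.
#' @param ioh_threshold IOH threshold (default 55 mmHg).
#' @return `data.frame`: `case_id`, `ioh`, `tls_any`, `tls_window_count`.
#' @export
event_flags <- function(stream, profiles,
                        criteria = triple_low_criteria(),
                        ioh_threshold = 55) {
  tls <- detect_tls(profiles, criteria)
  sub <- stream[stream$case_id %in% tls$case_id, , drop = FALSE]
  ioh <- detect_ioh(sub, ioh_threshold)
  tls$ioh <- unname(ioh[tls$case_id])
  tls[c("case_id", "ioh", "tls_any", "tls_window_count")]
}

ci_row <- function(cluster, metric, est) {
  data.frame(cluster = cluster, metric = metric,
             estimate = unname(est[1]), lower = unname(est[2]),
             upper = unname(est[3]), stringsAsFactors = FALSE)
}

#' Characterize TVI expression patterns
#'
#' Builds the per-cluster summary table: profile and patient counts, repeat
#' surgery, ASA distribution, emergency status, age, sex, top specialties
#' and procedures, procedure length, raw and z-scored MAP/BIS/MAC means,
#' TVI, IOH and triple-low exposure, data-capture rates, and mortality
#' proportions per window. Proportions carry Wilson 95% intervals, means
#' normal-theory t intervals, and medians seeded bootstrap percentile
#' intervals.
#'
#' @param fit A [tvi_fit()] object.
#' @param n_boot Bootstrap replicates for median intervals (default 1000).
#' @param boot_size Resample size per replicate; `NULL` (default) uses each
#'   statistic's own sample size.
#' @param conf Confidence level (default 0.95).
#' @param seed RNG seed for the bootstrap.
#' @return An object of class `tvi_characterization`: list with `table`
#'   (long `data.frame`: cluster, metric, estimate, lower, upper), `top`
#'   (top-3 specialties/procedures per cluster), and `patient_level`
#'   (the [patient_level_sensitivity()] table).
#' @export
characterize_clusters <- function(fit, n_boot = 1000L, boot_size = NULL,
                                  conf = 0.95, seed = 1L) {
  stopifnot(inherits(fit, "tvi_fit"))
  asg <- cluster_assignments(fit$model)
  cases <- fit$cases[match(asg$case_id, fit$cases$case_id), , drop = FALSE]
  flags <- fit$flags[match(asg$case_id, fit$flags$case_id), , drop = FALSE]
  spans <- fit$profiles$spans[match(asg$case_id, fit$profiles$spans$case_id), ,
                              drop = FALSE]
  win <- fit$profiles$windows
  stream <- fit$stream
  cl_of_case <- stats::setNames(asg$cluster_label, asg$case_id)
  mort <- classify_mortality(cases$days_to_death)

  labels <- unname(fit$model$labels)
  rows <- list()
  tops <- list()
  boot_med <- function(x) {
    x <- x[is.finite(x)]
    if (length(x) == 0L) return(c(NA_real_, NA_real_, NA_real_))
    b <- bootstrap_median_ci(x, n_boot = n_boot,
                             sample_size = boot_size %||% length(x),
                             alpha = 1 - conf, seed = seed)
    c(b$median, b$lower, b$upper)
  }

  for (lab in labels) {
    ids <- asg$case_id[asg$cluster_label == lab]
    if (length(ids) == 0L) stop_input("empty cluster: ", lab)
    sel <- asg$cluster_label == lab
    ca <- cases[sel, , drop = FALSE]
    fl <- flags[sel, , drop = FALSE]
    sp <- spans[sel, , drop = FALSE]
    n <- length(ids)

    add <- function(metric, est) rows[[length(rows) + 1L]] <<-
      ci_row(lab, metric, est)

    add("n_profiles", c(n, NA, NA))
    add("n_patients", c(length(unique(ca$patient_id)), NA, NA))
    add("pct_repeat_surgery", 100 * wilson_ci(sum(ca$repeat_surgery), n, conf))
    for (a in 1:5) {
      add(paste0("pct_asa_", a), 100 * wilson_ci(sum(ca$asa_status == a), n, conf))
    }
    add("pct_emergent", 100 * wilson_ci(sum(ca$emergent), n, conf))
    add("mean_age", t_ci(ca$age_years, conf))
    add("pct_male", 100 * wilson_ci(sum(ca$sex == "M"), n, conf))

    dur_hr <- (sp$t_last - sp$t_first) / 60
    add("median_procedure_hr", boot_med(dur_hr))

    wsel <- win[cl_of_case[win$case_id] == lab, , drop = FALSE]
    ssel <- stream[stream$case_id %in% ids, , drop = FALSE]
    for (v in c("MAP", "BIS", "MAC")) {
      x <- ssel$value[ssel$variable == v]
      add(paste0("mean_", tolower(v)), t_ci(x, conf))
      add(paste0("mean_", tolower(v), "_z"),
          t_ci(zscore(x, v, fit$profiles$stats), conf))
    }
    tvi_vals <- wsel$tvi[!is.na(wsel$tvi)]
    add("mean_tvi", t_ci(tvi_vals, conf))
    add("median_tvi_per_profile", boot_med(as.vector(
      tapply(!is.na(wsel$tvi), wsel$case_id, sum))))

    add("pct_ioh", 100 * wilson_ci(sum(fl$ioh), n, conf))
    add("pct_tls", 100 * wilson_ci(sum(fl$tls_any), n, conf))

    hrs <- pmax(dur_hr, 1e-9)
    maps_per_hr <- as.vector(tapply(ssel$variable == "MAP", ssel$case_id,
                                    sum)[ids]) / hrs
    tvis_per_hr <- as.vector(tapply(!is.na(wsel$tvi),
                                    wsel$case_id, sum)[ids]) / hrs
    add("median_maps_per_hr", boot_med(maps_per_hr))
    add("median_tvis_per_hr", boot_med(tvis_per_hr))

    mo <- mort[sel]
    add("pct_mortality_d30", 100 * wilson_ci(sum(mo == "d30"), n, conf))
    add("pct_mortality_d31_365",
        100 * wilson_ci(sum(mo == "d31_365"), n, conf))
    add("pct_mortality_d366_730",
        100 * wilson_ci(sum(mo == "d366_730"), n, conf))

    top3 <- function(x) {
      tb <- sort(table(x), decreasing = TRUE)
      utils::head(data.frame(value = names(tb),
                             pct = 100 * as.vector(tb) / n,
                             stringsAsFactors = FALSE), 3L)
    }
    ts <- top3(ca$specialty); ts$kind <- "specialty"
    tp <- top3(ca$procedure); tp$kind <- "procedure"
    tt <- rbind(ts, tp); tt$cluster <- lab
    tops[[lab]] <- tt
  }

  structure(list(table = do.call(rbind, rows),
                 top = do.call(rbind, c(tops, list(make.row.names = FALSE))),
                 patient_level = patient_level_sensitivity(fit)),
            class = "tvi_characterization")
}

#' @export
print.tvi_characterization <- function(x, ...) {
  wide <- stats::reshape(x$table[c("cluster", "metric", "estimate")],
                         idvar = "metric", timevar = "cluster",
                         direction = "wide")
  names(wide) <- sub("^estimate\\.", "", names(wide))
  cat("TVI cluster characterization (estimates; intervals in $table):\n")
  print(wide, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Patient-level mortality sensitivity analysis
#'
#' Recomputes per-cluster mortality proportions over distinct patients
#' rather than profiles (a patient with several profiles in one cluster is
#' counted once there; a patient appearing in several clusters is counted
#' once in each). Guards against repeat surgery inflating profile-level
#' proportions.
#'
#' @param fit A [tvi_fit()] object.
#' @return `data.frame` with `cluster`, `n_patients`, and the proportion (%)
#'   of patients in each mortality window.
#' @export
patient_level_sensitivity <- function(fit) {
  stopifnot(inherits(fit, "tvi_fit"))
  asg <- cluster_assignments(fit$model)
  cases <- fit$cases[match(asg$case_id, fit$cases$case_id), , drop = FALSE]
  d <- data.frame(cluster = asg$cluster_label,
                  patient_id = cases$patient_id,
                  days_to_death = cases$days_to_death,
                  stringsAsFactors = FALSE)
  d <- d[!duplicated(d[c("cluster", "patient_id")]), , drop = FALSE]
  d$class <- classify_mortality(d$days_to_death)
  out <- lapply(split(d, d$cluster), function(g) {
    n <- nrow(g)
    data.frame(cluster = g$cluster[1L], n_patients = n,
               pct_mortality_d30 = 100 * sum(g$class == "d30") / n,
               pct_mortality_d31_365 = 100 * sum(g$class == "d31_365") / n,
               pct_mortality_d366_730 = 100 * sum(g$class == "d366_730") / n,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Pearson correlations between the window means of MAP, BIS, and MAC
#'
#' Computed per group (each cluster plus the whole population) over windows
#' where both variables of a pair are present. Pearson r is invariant to the
#' z-scoring, so z-means and raw means give identical correlations; a
#' measurement-level mode pairs raw values recorded at identical timepoints.
#'
#' @param profiles A [assemble_profiles()] object.
#' @param assignments Optional `data.frame` from [cluster_assignments()];
#'   when `NULL` only the pooled group `all` is reported.
#' @param level `"window"` (default) or `"measurement"`.
#' @param stream Required for `level = "measurement"`.
#' @return `data.frame` with `group`, `pair`, `r`, `n`.
#' @export
compute_correlations <- function(profiles, assignments = NULL,
                                 level = c("window", "measurement"),
                                 stream = NULL) {
  level <- match.arg(level)
  stopifnot(inherits(profiles, "tvi_profiles"))
  if (level == "window") {
    d <- profiles$windows[c("case_id", "map_mean", "bis_mean", "mac_mean")]
    names(d) <- c("case_id", "MAP", "BIS", "MAC")
  } else {
    if (is.null(stream)) stop_input("measurement-level mode needs the stream")
    s <- stream[stream$variable %in% c("MAP", "BIS", "MAC"), , drop = FALSE]
    key <- paste0(s$case_id, "\r", format(s$t_min, digits = 15))
    d <- data.frame(case_id = s$case_id[!duplicated(key)],
                    stringsAsFactors = FALSE)
    for (v in c("MAP", "BIS", "MAC")) {
      m <- grouped_mean(s$value[s$variable == v], key[s$variable == v])
      d[[v]] <- unname(m[unique(key)])
    }
  }
  groups <- list(all = unique(d$case_id))
  if (!is.null(assignments)) {
    groups <- c(groups,
                split(assignments$case_id, assignments$cluster_label))
  }
  pairs <- list(c("MAP", "BIS"), c("MAP", "MAC"), c("BIS", "MAC"))
  out <- list()
  for (g in names(groups)) {
    sub <- d[d$case_id %in% groups[[g]], , drop = FALSE]
    for (p in pairs) {
      ok <- stats::complete.cases(sub[p])
      n <- sum(ok)
      r <- if (n >= 3L) {
        suppressWarnings(stats::cor(sub[ok, p[1]], sub[ok, p[2]]))
      } else NA_real_
      if (!is.na(r) && !is.finite(r)) r <- NA_real_
      out[[length(out) + 1L]] <- data.frame(
        group = g, pair = paste(p, collapse = "-"), r = r, n = n,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Write per-case event flags as CSV
#'
#' @param flags Output of [event_flags()].
#' @param path Output CSV path.
#' @return The path, invisibly.
#' @export
write_flags <- function(flags, path) {
  utils::write.csv(flags, path, row.names = FALSE)
  invisible(path)
}
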