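# Seeded synthetic intraoperative cohort generator. Emits the CSV dialects
# the ingest module reads, with three latent physiologic regimes (elevated /
# mixed / depressed) whose MAP/BIS/MAC means, prevalences, and mortality
# follow the published cluster-level summary statistics, multi-rate
# measurement grids with jitter, artifact contamination, arterial/cuff MAP
# duplication, cardiopulmonary-bypass MAC gaps, and regime-linked mortality.
#
# Within-case variation is modelled as smooth, case-centered drift (a shared
# anesthetic-depth process coupling BIS negatively to MAC, plus a
# variable-specific drift) with a smaller white measurement-noise component;
# the loadings are normalized so the pooled marginal SDs reproduce the
# published population SDs.

#' Synthetic cohort specification
#'
#' Defaults encode the study conditions: regime prevalences 891/2931/1474 of
#' 5296; regime MAP means 86.5/82.3/76.6 mmHg, BIS 45.3/41.8/38.0, MAC
#' 0.980/0.817/0.666; 30-day mortality 0.8/2.7/5.6% (later windows
#' 4.9/6.7/7.4% and 3.3/3.8/4.3%); MAP recorded ~q3min and BIS/agents ~q5min
#' with +/-20% jitter; procedure duration lognormal with median 1.8 h. The
#' variation around the regime means has a per-case random effect (MAP
#' 2 mmHg, BIS 1.2, MAC 0.035) plus within-case variation of clinically
#' typical magnitude under stable anesthesia (MAP 6 mmHg, BIS 3.5, MAC
#' 0.10), sized so the three planted regimes remain statistically
#' recoverable from windowed profiles. Within-case variation is mostly
#' smooth, case-centered drift: a shared latent anesthetic-depth process
#' (loadings `rho_*`, coupling BIS negatively to MAC) plus a
#' variable-specific drift (loadings `drift_*`), with the remainder white
#' measurement noise. The pooled SDs are consequently narrower than a real
#' cohort's, whose spread is dominated by continuous case-mix heterogeneity
#' that a three-regime model intentionally collapses.
#'
#' @param n_cases Number of surgeries to simulate.
#' @param prevalence Regime prevalences (elevated, mixed, depressed);
#'   normalized to sum to 1.
#' @param map_mean,bis_mean,mac_mean Regime mean levels (length 3).
#' @param mortality_30d,mortality_31_365,mortality_366_730 Regime mortality
#'   probabilities per postoperative window.
#' @param map_case_sd,bis_case_sd,mac_case_sd Between-case SD of the case
#'   mean level around its regime mean.
#' @param map_sd,bis_sd,mac_sd Within-case measurement SD.
#' @param map_interval_min,bis_interval_min,mac_interval_min Nominal
#'   recording intervals, minutes.
#' @param jitter Uniform timestamp jitter as a fraction of the interval.
#' @param duration_meanlog,duration_sdlog,duration_min Lognormal procedure
#'   duration (minutes); `duration_min` is a floor.
#' @param artifact_rate Per-measurement probability of an injected artifact
#'   (out-of-limits MAP/MAC, or a BIS of 0).
#' @param cpb_fraction Overall fraction of cases with a cardiopulmonary
#'   bypass gap (agent data blanked over the middle third of the case).
#' @param repeat_patient_fraction Probability a case belongs to an
#'   already-seen patient.
#' @param depth_coupling Couple MAP/BIS/MAC to a shared latent depth
#'   process (gives the negative within-case BIS-MAC correlation). When
#'   `FALSE` the shared loading is folded into the variable-specific drift,
#'   preserving marginal SDs.
#' @param rho_map,rho_bis,rho_mac Loadings of each variable on the shared
#'   latent depth process (fractions of the within-case SD).
#' @param drift_map,drift_bis,drift_mac Loadings on the variable-specific
#'   smooth drift process; the white-noise loading is
#'   `sqrt(1 - rho^2 - drift^2)`.
#' @param arterial_fraction Fraction of non-cardiac cases with an arterial
#'   line (cardiac cases always have one).
#' @param dual_source_rate Fraction of arterial-line MAP timepoints that
#'   also emit a concurrent noninvasive value (exercises source precedence).
#' @param mortality_link `"regime"` (regime-specific probabilities) or
#'   `"logistic"` (30-day death probability is a logistic function of the
#'   case's true mean TVI level).
#' @param logistic_intercept,logistic_slope Parameters of the logistic link.
#' @param t_round Timestamp rounding, minutes.
#' @param seed Default RNG seed.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(
    n_cases = 2000L,
    prevalence = c(elevated = 891, mixed = 2931, depressed = 1474) / 5296,
    map_mean = c(86.5, 82.3, 76.6),
    bis_mean = c(45.3, 41.8, 38.0),
    mac_mean = c(0.980, 0.817, 0.666),
    mortality_30d = c(0.008, 0.027, 0.056),
    mortality_31_365 = c(0.049, 0.067, 0.074),
    mortality_366_730 = c(0.033, 0.038, 0.043),
    map_case_sd = 2, bis_case_sd = 1.2, mac_case_sd = 0.035,
    map_sd = 6, bis_sd = 3.5, mac_sd = 0.10,
    map_interval_min = 3, bis_interval_min = 5, mac_interval_min = 5,
    jitter = 0.2,
    duration_meanlog = log(108), duration_sdlog = 0.9, duration_min = 15,
    artifact_rate = 0.005, cpb_fraction = 0.04,
    repeat_patient_fraction = 0.177,
    depth_coupling = TRUE, rho_map = -0.25, rho_bis = -0.55, rho_mac = 0.55,
    drift_map = 0.80, drift_bis = 0.76, drift_mac = 0.76,
    arterial_fraction = 0.3, dual_source_rate = 0.05,
    mortality_link = c("regime", "logistic"),
    logistic_intercept = -3.55, logistic_slope = -0.38,
    t_round = 1 / 60, seed = 1L) {
  mortality_link <- match.arg(mortality_link)
  if (n_cases < 1L) stop_input("n_cases must be >= 1")
  if (any(prevalence < 0) || sum(prevalence) <= 0) {
    stop_input("prevalences must be non-negative and not all zero")
  }
  prevalence <- prevalence / sum(prevalence)
  sds <- c(map_case_sd, bis_case_sd, mac_case_sd, map_sd, bis_sd, mac_sd)
  if (any(sds <= 0)) stop_input("all SDs must be positive")
  probs <- c(mortality_30d, mortality_31_365, mortality_366_730,
             artifact_rate, cpb_fraction, repeat_patient_fraction,
             arterial_fraction, dual_source_rate)
  if (any(probs < 0 | probs > 1)) stop_input("probabilities must be in [0, 1]")
  if (any(c(map_interval_min, bis_interval_min, mac_interval_min) <= 0)) {
    stop_input("recording intervals must be positive")
  }
  if (any(c(rho_map, rho_bis, rho_mac)^2 +
            c(drift_map, drift_bis, drift_mac)^2 > 1)) {
    stop_input("rho^2 + drift^2 must not exceed 1 for any variable")
  }
  spec <- as.list(environment())
  structure(spec, class = "cohort_spec")
}

regime_names <- c("elevated", "mixed", "depressed")

# Pooled mean/SD per variable implied by a spec (between-regime + case +
# within components) - the anchor used for the case's "true" TVI level.
spec_pooled <- function(spec) {
  out <- list()
  for (v in c("map", "bis", "mac")) {
    mu <- spec[[paste0(v, "_mean")]]
    pm <- sum(spec$prevalence * mu)
    pv <- sum(spec$prevalence * (mu - pm)^2) +
      spec[[paste0(v, "_case_sd")]]^2 + spec[[paste0(v, "_sd")]]^2
    out[[v]] <- c(mean = pm, sd = sqrt(pv))
  }
  out
}

jittered_grid <- function(duration, interval, jitter, t_round) {
  base <- seq(0, duration, by = interval)
  t <- base + stats::runif(length(base), -jitter * interval, jitter * interval)
  t[1] <- 0
  t <- round(pmax(0, pmin(t, duration)) / t_round) * t_round
  sort(unique(t))
}

#' Generate a synthetic intraoperative cohort
#'
#' @param spec A [cohort_spec()].
#' @param n_cases Optional override of `spec$n_cases`.
#' @param seed Optional override of `spec$seed`.
#' @return An object of class `tvi_cohort`: list with `measurements`,
#'   `cases`, `medications` (the CSV dialects the readers accept), `truth`
#'   (latent regime, true mean TVI level, and mortality draw per case), and
#'   the `spec` used.
#' @export
generate_cohort <- function(spec = cohort_spec(), n_cases = NULL,
                            seed = NULL) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (!is.null(n_cases)) spec$n_cases <- as.integer(n_cases)
  if (!is.null(seed)) spec$seed <- seed
  if (spec$n_cases < 1L) stop_input("n_cases must be >= 1")
  n <- spec$n_cases
  pooled <- spec_pooled(spec)

  with_seed(spec$seed, {
    r <- sample.int(3L, n, replace = TRUE, prob = spec$prevalence)
    duration <- pmax(spec$duration_min,
                     stats::rlnorm(n, spec$duration_meanlog,
                                   spec$duration_sdlog))

    map_case <- spec$map_mean[r] + stats::rnorm(n, 0, spec$map_case_sd)
    bis_case <- spec$bis_mean[r] + stats::rnorm(n, 0, spec$bis_case_sd)
    mac_case <- pmax(0.1, spec$mac_mean[r] + stats::rnorm(n, 0, spec$mac_case_sd))
    tvi_true <- (map_case - pooled$map["mean"]) / pooled$map["sd"] +
      (bis_case - pooled$bis["mean"]) / pooled$bis["sd"] +
      (mac_case - pooled$mac["mean"]) / pooled$mac["sd"]

    cardiac_p <- c(0.022, 0.065, 0.161)
    cardiac <- stats::runif(n) < cardiac_p[r]
    exp_cardiac <- sum(spec$prevalence * cardiac_p)
    cpb <- cardiac & stats::runif(n) < min(1, spec$cpb_fraction / exp_cardiac)

    other_spec <- c("General", "Orthopedic", "Thoracic", "Neurosurgery",
                    "Urology")
    specialty <- ifelse(cardiac, "Cardiac",
                        sample(other_spec, n, replace = TRUE,
                               prob = c(0.35, 0.22, 0.12, 0.16, 0.15)))
    card_proc <- c("Aortic Valve Replacement/Repair",
                   "Coronary Artery Bypass Graft")
    other_proc <- c("Irrigation and Debridement of Wound",
                    "Exploratory Laparotomy",
                    "Anterior Cervical Discectomy and Fusion",
                    "Total Knee Arthroplasty", "Craniotomy")
    procedure <- ifelse(cardiac,
                        sample(card_proc, n, replace = TRUE),
                        sample(other_proc, n, replace = TRUE,
                               prob = c(0.30, 0.20, 0.15, 0.20, 0.15)))

    asa_probs <- rbind(c(5.2, 36.8, 51.1, 6.7, 0.1),
                       c(4.6, 29.6, 49.0, 16.1, 0.6),
                       c(3.9, 22.7, 44.4, 27.3, 1.6))
    asa <- vapply(r, function(ri) {
      sample.int(5L, 1L, prob = asa_probs[ri, ])
    }, integer(1))
    emergent <- stats::runif(n) < c(0.058, 0.105, 0.128)[r]
    age <- pmin(95, pmax(18, stats::rnorm(n, c(52, 53.7, 54.5)[r], 16.8)))
    sex <- ifelse(stats::runif(n) < c(0.569, 0.534, 0.527)[r], "M", "F")

    patient_id <- character(n)
    pool <- character(0)
    for (i in seq_len(n)) {
      if (length(pool) > 0L &&
          stats::runif(1) < spec$repeat_patient_fraction) {
        patient_id[i] <- pool[sample.int(length(pool), 1L)]
      } else {
        patient_id[i] <- sprintf("P%05d", length(pool) + 1L)
        pool <- c(pool, patient_id[i])
      }
    }
    repeat_surgery <- duplicated(patient_id)

    p30 <- if (spec$mortality_link == "logistic") {
      stats::plogis(spec$logistic_intercept +
                      spec$logistic_slope * as.vector(tvi_true))
    } else {
      spec$mortality_30d[r]
    }
    p2 <- spec$mortality_31_365[r]
    p3 <- spec$mortality_366_730[r]
    u <- stats::runif(n)
    days_to_death <- rep(NA_integer_, n)
    sel <- u < p30
    days_to_death[sel] <- sample(0:30, sum(sel), replace = TRUE)
    sel2 <- !sel & u < p30 + p2
    days_to_death[sel2] <- sample(31:365, sum(sel2), replace = TRUE)
    sel3 <- !sel & !sel2 & u < p30 + p2 + p3
    days_to_death[sel3] <- sample(366:730, sum(sel3), replace = TRUE)

    case_id <- sprintf("C%05d", seq_len(n))
    arterial <- cardiac | stats::runif(n) < spec$arterial_fraction
    rho <- c(map = spec$rho_map, bis = spec$rho_bis, mac = spec$rho_mac)
    drift <- c(map = spec$drift_map, bis = spec$drift_bis,
               mac = spec$drift_mac)
    if (!spec$depth_coupling) {
      # fold the shared-process variance into the private drift
      drift <- sqrt(drift^2 + rho^2)
      rho[] <- 0
    }
    white <- sqrt(pmax(1 - rho^2 - drift^2, 0))  # pmax(v, 0) keeps names
    sevo_eq <- mac_equivalents()$equivalents[["SEVOFLURANE"]]

    # Smooth, case-centered unit-SD process on 5-min nodes.
    smooth_process <- function(dur) {
      nodes <- seq(0, dur, by = 5)
      if (length(nodes) < 2L) nodes <- c(0, dur)
      w <- cumsum(stats::rnorm(length(nodes)))
      w <- w - mean(w)
      sw <- stats::sd(w)
      if (!is.finite(sw) || sw == 0) w <- rep(0, length(nodes)) else w <- w / sw
      function(t) stats::approx(nodes, w, xout = t, rule = 2)$y
    }

    acc <- vector("list", n)
    cpb_start <- rep(NA_real_, n)
    cpb_end <- rep(NA_real_, n)
    for (i in seq_len(n)) {
      dur <- duration[i]
      tm <- jittered_grid(dur, spec$map_interval_min, spec$jitter, spec$t_round)
      tb <- jittered_grid(dur, spec$bis_interval_min, spec$jitter, spec$t_round)
      ta <- jittered_grid(dur, spec$mac_interval_min, spec$jitter, spec$t_round)

      depth <- smooth_process(dur)
      d_map <- smooth_process(dur)
      d_bis <- smooth_process(dur)
      d_mac <- smooth_process(dur)

      mv <- map_case[i] + spec$map_sd *
        (rho["map"] * depth(tm) + drift["map"] * d_map(tm) +
           white["map"] * stats::rnorm(length(tm)))
      bv <- bis_case[i] + spec$bis_sd *
        (rho["bis"] * depth(tb) + drift["bis"] * d_bis(tb) +
           white["bis"] * stats::rnorm(length(tb)))
      av <- mac_case[i] + spec$mac_sd *
        (rho["mac"] * depth(ta) + drift["mac"] * d_mac(ta) +
           white["mac"] * stats::rnorm(length(ta)))
      mv <- pmin(245, pmax(12, mv))
      bv <- pmin(98, pmax(2, bv))
      av <- pmin(2.9, pmax(0.02, av))

      if (cpb[i]) {
        cpb_start[i] <- round(dur / 3, 2)
        cpb_end[i] <- round(2 * dur / 3, 2)
        keep <- ta < cpb_start[i] | ta > cpb_end[i]
        ta <- ta[keep]
        av <- av[keep]
      }

      art_m <- stats::runif(length(mv)) < spec$artifact_rate
      if (any(art_m)) {
        hi <- stats::runif(sum(art_m)) < 0.5
        mv[art_m] <- ifelse(hi, stats::runif(sum(art_m), 251, 400),
                            stats::runif(sum(art_m), 0.5, 9.9))
      }
      art_b <- stats::runif(length(bv)) < spec$artifact_rate
      bv[art_b] <- 0
      art_a <- stats::runif(length(av)) < spec$artifact_rate
      av[art_a] <- stats::runif(sum(art_a), 3.05, 5)

      src <- rep(if (arterial[i]) "ARTERIAL" else "NONINVASIVE", length(tm))
      # Concurrent cuff readings alongside some arterial timepoints.
      if (arterial[i] && spec$dual_source_rate > 0) {
        dup <- stats::runif(length(tm)) < spec$dual_source_rate
        if (any(dup)) {
          tm <- c(tm, tm[dup])
          mv <- c(mv, pmin(245, pmax(12, mv[dup] + stats::rnorm(sum(dup), 0, 5))))
          src <- c(src, rep("NONINVASIVE", sum(dup)))
        }
      }

      acc[[i]] <- list(
        t = c(tm, tb, ta),
        variable = c(rep("MAP", length(tm)), rep("BIS", length(tb)),
                     rep("SEVOFLURANE", length(ta))),
        value = c(mv, bv, av * sevo_eq),
        source = c(src, rep(NA_character_, length(tb) + length(ta)))
      )
    }

    n_rows <- vapply(acc, function(a) length(a$t), integer(1))
    measurements <- data.frame(
      case_id = rep(case_id, n_rows),
      t_min = unlist(lapply(acc, `[[`, "t"), use.names = FALSE),
      variable = unlist(lapply(acc, `[[`, "variable"), use.names = FALSE),
      value = unlist(lapply(acc, `[[`, "value"), use.names = FALSE),
      source = unlist(lapply(acc, `[[`, "source"), use.names = FALSE),
      stringsAsFactors = FALSE
    )
    measurements <- measurements[order(measurements$case_id,
                                       measurements$t_min), , drop = FALSE]
    rownames(measurements) <- NULL

    cases <- data.frame(
      case_id = case_id, patient_id = patient_id,
      age_years = round(age, 1), sex = sex, asa_status = asa,
      emergent = emergent, specialty = specialty, procedure = procedure,
      cpb_used = cpb, cpb_start_min = cpb_start, cpb_end_min = cpb_end,
      repeat_surgery = repeat_surgery, days_to_death = days_to_death,
      stringsAsFactors = FALSE
    )

    drug_p <- list(
      propofol = list(p = c(0.97, 0.97, 0.96), meanlog = log(c(185, 170, 150)),
                      sdlog = 0.4),
      fentanyl = list(p = c(0.97, 0.97, 0.97), meanlog = log(c(250, 250, 250)),
                      sdlog = 0.5),
      hydromorphone = list(p = c(0.476, 0.263, 0.252),
                           meanlog = log(c(1, 1, 1)), sdlog = 0.5),
      etomidate = list(p = c(0.030, 0.073, 0.126),
                       meanlog = log(c(14, 14, 14)), sdlog = 0.3),
      ketamine = list(p = c(0.112, 0.046, 0.030),
                      meanlog = log(c(30, 30, 30)), sdlog = 0.5),
      phenylephrine = list(p = c(0.740, 0.748, 0.830),
                           meanlog = log(c(400, 400, 500)), sdlog = 0.8),
      norepinephrine = list(p = c(0.024, 0.075, 0.212),
                            meanlog = log(c(0.5, 0.5, 0.8)), sdlog = 0.8),
      vasopressin = list(p = c(0.034, 0.076, 0.210),
                         meanlog = log(c(2, 2, 2.5)), sdlog = 0.6),
      succinylcholine = list(p = c(0.740, 0.690, 0.619),
                             meanlog = log(c(120, 120, 120)), sdlog = 0.3)
    )
    med_list <- lapply(names(drug_p), function(drug) {
      d <- drug_p[[drug]]
      given <- stats::runif(n) < d$p[r]
      if (!any(given)) return(NULL)
      data.frame(case_id = case_id[given], drug = drug,
                 total_dose = round(stats::rlnorm(sum(given),
                                                  d$meanlog[r[given]],
                                                  d$sdlog), 2),
                 stringsAsFactors = FALSE)
    })
    medications <- do.call(rbind, med_list)
    medications <- medications[order(medications$case_id, medications$drug), ,
                               drop = FALSE]
    rownames(medications) <- NULL

    truth <- data.frame(case_id = case_id, regime = regime_names[r],
                        days_to_death = days_to_death,
                        tvi_true = as.vector(tvi_true),
                        p30 = p30, duration_min = round(duration, 2),
                        stringsAsFactors = FALSE)

    structure(list(measurements = measurements, cases = cases,
                   medications = medications, truth = truth, spec = spec),
              class = "tvi_cohort")
  })
}

#' @export
print.tvi_cohort <- function(x, ...) {
  cat("Synthetic intraoperative cohort:", nrow(x$cases), "cases,",
      nrow(x$measurements), "measurements\n")
  if (!is.null(x$truth)) {
    cat("  regimes:", paste(names(table(x$truth$regime)),
                            table(x$truth$regime),
                            sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}

#' Write a cohort to CSV files
#'
#' Writes `measurements.csv`, `cases.csv`, `medications.csv`, and (when
#' present) `truth.csv` to `dir`, in the dialects [read_cohort()] accepts.
#' Output is byte-identical for identical cohort objects.
#'
#' @param cohort A [generate_cohort()] result (or compatible list).
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(cohort$measurements, file.path(dir, "measurements.csv"),
                   row.names = FALSE, na = "")
  utils::write.csv(cohort$cases, file.path(dir, "cases.csv"),
                   row.names = FALSE, na = "")
  utils::write.csv(cohort$medications, file.path(dir, "medications.csv"),
                   row.names = FALSE, na = "")
  if (!is.null(cohort$truth)) {
    utils::write.csv(cohort$truth, file.path(dir, "truth.csv"),
                     row.names = FALSE, na = "")
  }
  invisible(dir)
}

#' A tiny hand-checkable worked case
#'
#' Twelve timepoints one minute apart, each with a MAP, BIS, and
#' sevoflurane measurement, producing exactly three windows of 5, 5, and 2
#' timepoints. The raw values are returned alongside so tests can recompute
#' every window statistic by direct arithmetic.
#'
#' @return List with `measurements` (long format, ready for the pipeline)
#'   and `raw` (a 12-row table of t, MAP, BIS, MAC).
#' @export
generate_worked_micro_case <- function() {
  raw <- data.frame(
    t = 0:11,
    map = c(80, 82, 78, 76, 84, 70, 68, 72, 74, 66, 90, 88),
    bis = c(45, 47, 43, 40, 50, 38, 36, 34, 42, 39, 55, 52),
    mac = c(1.0, 1.1, 0.9, 0.8, 1.2, 0.7, 0.6, 0.65, 0.75, 0.7, 1.3, 1.25)
  )
  sevo_eq <- mac_equivalents()$equivalents[["SEVOFLURANE"]]
  measurements <- data.frame(
    case_id = "MICRO1",
    t_min = rep(raw$t, 3L),
    variable = rep(c("MAP", "BIS", "SEVOFLURANE"), each = nrow(raw)),
    value = c(raw$map, raw$bis, raw$mac * sevo_eq),
    source = c(rep("NONINVASIVE", nrow(raw)),
               rep(NA_character_, 2L * nrow(raw))),
    stringsAsFactors = FALSE
  )
  measurements <- measurements[order(measurements$t_min), , drop = FALSE]
  rownames(measurements) <- NULL
  list(measurements = measurements, raw = raw)
}
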