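# Bootstrap median confidence intervals, Mann-Whitney ROC AUC, and the
# paired bootstrap comparison of two risk models' AUCs.

#' Bootstrap percentile confidence interval for a median
#'
#' Draws `n_boot` resamples of `sample_size` values with replacement,
#' computes each resample's median, and takes the empirical
#' `alpha/2` / `1 - alpha/2` quantiles of those medians as the interval.
#' The point estimate is the sample median. Defaults follow the original
#' analysis scale (10,000 resamples of 1,000,000 draws); scale down for
#' routine use - only Monte-Carlo precision changes.
#'
#' @param values Non-empty numeric vector.
#' @param n_boot Number of bootstrap resamples.
#' @param sample_size Draws (with replacement) per resample.
#' @param alpha 1 - confidence level (default 0.05).
#' @param seed Optional RNG seed.
#' @return List with `median`, `lower`, `upper`, `n_boot`, `sample_size`.
#' @export
bootstrap_median_ci <- function(values, n_boot = 10000L,
                                sample_size = 1000000L, alpha = 0.05,
                                seed = NULL) {
  values <- values[!is.na(values)]
  if (length(values) == 0L) stop_input("empty input to bootstrap_median_ci")
  if (n_boot < 1L || sample_size < 1L) {
    stop_input("n_boot and sample_size must be >= 1")
  }
  med <- stats::median(values)
  if (length(unique(values)) == 1L) {
    return(list(median = med, lower = med, upper = med,
                n_boot = n_boot, sample_size = sample_size))
  }
  meds <- with_seed(seed, vapply(seq_len(n_boot), function(b) {
    stats::median(sample(values, sample_size, replace = TRUE))
  }, numeric(1)))
  qs <- unname(stats::quantile(meds, c(alpha / 2, 1 - alpha / 2)))
  list(median = med, lower = qs[1], upper = qs[2],
       n_boot = n_boot, sample_size = sample_size)
}

#' ROC area under the curve
#'
#' The probability that a randomly chosen positive case outranks a randomly
#' chosen negative one: the Mann-Whitney U statistic divided by `n1 * n0`,
#' with midranks so exact ties contribute 1/2. Higher scores must mean
#' higher predicted risk.
#'
#' @param scores Numeric risk scores.
#' @param labels Binary outcomes (logical, or 0/1); both classes required.
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(scores, labels) {
  y <- as.logical(labels)
  if (anyNA(scores) || anyNA(y)) stop_input("scores/labels must not be NA")
  n1 <- sum(y)
  n0 <- sum(!y)
  if (n1 == 0L || n0 == 0L) {
    stop_input("both outcome classes must be present")
  }
  r <- rank(scores)
  (sum(r[y]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Compare two models' AUCs by paired bootstrap
#'
#' Resamples cases with replacement (paired scores and label together),
#' recomputes both AUCs per replicate, standardizes the observed AUC
#' difference by the bootstrap standard deviation of the difference, and
#' reports a two-sided normal p-value. Inputs are canonically sorted before
#' resampling so the result is invariant to case order under the same seed.
#' A degenerate resample containing one outcome class is redrawn, up to
#' `max_redraw` attempts per replicate.
#'
#' @param scores_a,scores_b Paired risk scores on identical cases.
#' @param labels Binary outcomes.
#' @param n_boot Bootstrap replicates (default 2000).
#' @param seed Optional RNG seed.
#' @param max_redraw Redraw cap per replicate for single-class resamples.
#' @return Object of class `tvi_auc_comparison`: `auc_a`, `auc_b`, `delta`,
#'   `p_value`, `sd_boot`, `n_boot`, `n`, `seed`.
#' @export
compare_auc_bootstrap <- function(scores_a, scores_b, labels,
                                  n_boot = 2000L, seed = NULL,
                                  max_redraw = 100L) {
  y <- as.logical(labels)
  n <- length(y)
  if (length(scores_a) != n || length(scores_b) != n) {
    stop_input("scores_a, scores_b, labels must have equal length")
  }
  ord <- order(scores_a, scores_b, y)
  a <- scores_a[ord]; b <- scores_b[ord]; y <- y[ord]
  auc_a <- roc_auc(a, y)
  auc_b <- roc_auc(b, y)
  delta <- auc_a - auc_b
  deltas <- with_seed(seed, vapply(seq_len(n_boot), function(i) {
    for (try in seq_len(max_redraw)) {
      idx <- sample.int(n, n, replace = TRUE)
      if (any(y[idx]) && !all(y[idx])) {
        return(roc_auc(a[idx], y[idx]) - roc_auc(b[idx], y[idx]))
      }
    }
    stop_input("could not draw a two-class bootstrap resample in ",
               max_redraw, " attempts")
  }, numeric(1)))
  sd_boot <- stats::sd(deltas)
  p <- if (!is.finite(sd_boot) || sd_boot == 0) {
    if (delta == 0) 1 else 0
  } else {
    2 * stats::pnorm(-abs(delta / sd_boot))
  }
  structure(list(auc_a = auc_a, auc_b = auc_b, delta = delta,
                 p_value = p, sd_boot = sd_boot, n_boot = n_boot,
                 n = n, seed = seed),
            class = "tvi_auc_comparison")
}

#' @export
print.tvi_auc_comparison <- function(x, ...) {
  cat(sprintf("Paired bootstrap AUC comparison (n = %d, %d resamples)\n",
              x$n, x$n_boot))
  cat(sprintf("  AUC A = %.4f | AUC B = %.4f | delta = %.4f | p = %.4g\n",
              x$auc_a, x$auc_b, x$delta, x$p_value))
  invisible(x)
}

#' 30-day mortality prediction contest: median TVI vs cumulative triple low
#'
#' Compares two single-variable risk models for death within 30 days of
#' surgery: (A) the median TVI value generated during surgery, sign-flipped
#' so that a depressed TVI means higher risk, and (B) the cumulative count
#' of profile windows meeting triple low criteria. AUCs are compared with
#' [compare_auc_bootstrap()].
#'
#' @param x A [tvi_fit()] object, or a numeric vector of per-case median
#'   TVI values.
#' @param ... Passed on to methods.
#' @return Object of class `tvi_contest`: `auc_tvi`, `auc_tls`, `delta`,
#'   `p_value`, `n_boot`, `seed`, `n_cases`, `n_deaths`.
#' @export
mortality_prediction_contest <- function(x, ...) {
  UseMethod("mortality_prediction_contest")
}

#' @rdname mortality_prediction_contest
#' @param tls_count Per-case triple-low window counts (default method).
#' @param died_30d Logical per-case 30-day death outcome (default method).
#' @param n_boot Bootstrap replicates (default 2000).
#' @param seed Optional RNG seed.
#' @export
mortality_prediction_contest.default <- function(x, tls_count, died_30d,
                                                 n_boot = 2000L,
                                                 seed = NULL, ...) {
  median_tvi <- x
  if (!any(died_30d) || all(died_30d)) {
    stop_input("both 30-day outcome classes must be present")
  }
  cmp <- compare_auc_bootstrap(-median_tvi, tls_count, died_30d,
                               n_boot = n_boot, seed = seed)
  structure(list(auc_tvi = cmp$auc_a, auc_tls = cmp$auc_b,
                 delta = cmp$delta, p_value = cmp$p_value,
                 n_boot = n_boot, seed = seed,
                 n_cases = cmp$n, n_deaths = sum(died_30d)),
            class = "tvi_contest")
}

#' @rdname mortality_prediction_contest
#' @export
mortality_prediction_contest.tvi_fit <- function(x, n_boot = 2000L,
                                                 seed = NULL, ...) {
  win <- x$profiles$windows
  med_tvi <- tapply(win$tvi, win$case_id, stats::median, na.rm = TRUE)
  ids <- x$flags$case_id
  died <- classify_mortality(
    x$cases$days_to_death[match(ids, x$cases$case_id)]) == "d30"
  mortality_prediction_contest(as.vector(med_tvi[ids]),
                               x$flags$tls_window_count, died,
                               n_boot = n_boot, seed = seed)
}

#' @export
print.tvi_contest <- function(x, ...) {
  cat(sprintf("30-day mortality prediction: median TVI vs cumulative TLS\n"))
  cat(sprintf("  n = %d cases, %d deaths\n", x$n_cases, x$n_deaths))
  cat(sprintf("  AUC (median TVI) = %.4f | AUC (TLS count) = %.4f\n",
              x$auc_tvi, x$auc_tls))
  cat(sprintf("  delta = %.4f, bootstrap p = %.4g (%d resamples)\n",
              x$delta, x$p_value, x$n_boot))
  invisible(x)
}

#' Write the contest result as JSON
#'
#' @param contest A [mortality_prediction_contest()] result.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_contest <- function(contest, path) {
  stopifnot(inherits(contest, "tvi_contest"))
  jsonlite::write_json(unclass(contest), path, auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}
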