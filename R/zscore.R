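# Population z-scoring. Every MAP, BIS, and MAC value is normalized against
# the pooled post-artifact-removal distribution of its variable over the
# WHOLE study population, not per case.

#' Fit population mean/SD per variable
#'
#' Computes the z-scoring reference: pooled mean and sample standard
#' deviation (divisor n-1) of each of MAP, BIS, and summed MAC over every
#' retained measurement in the dataset.
#'
#' @param stream Prepared measurement stream (see [prepare_stream()]); rows
#'   with `variable` in MAP/BIS/MAC are used.
#' @return An object of class `population_stats`: a `data.frame` with
#'   columns `variable`, `mean`, `sd`, `n`.
#' @export
fit_population_stats <- function(stream) {
  vars <- c("MAP", "BIS", "MAC")
  rows <- lapply(vars, function(v) {
    x <- stream$value[stream$variable == v]
    if (length(x) < 2L) {
      stop_input("cannot fit population stats: fewer than 2 values for ", v)
    }
    s <- stats::sd(x)
    if (!is.finite(s) || s == 0) {
      stop_input("cannot fit population stats: zero variance for ", v)
    }
    data.frame(variable = v, mean = mean(x), sd = s, n = length(x),
               stringsAsFactors = FALSE)
  })
  structure(do.call(rbind, rows), class = c("population_stats", "data.frame"))
}

#' Z-score values against the population reference
#'
#' @param value Numeric vector of raw values.
#' @param variable Character vector (recycled) naming the variable of each
#'   value: `"MAP"`, `"BIS"`, or `"MAC"`.
#' @param stats A [fit_population_stats()] object.
#' @return Numeric vector of z-scores `(value - mean) / sd`.
#' @export
zscore <- function(value, variable, stats) {
  stopifnot(inherits(stats, "population_stats"))
  if (length(variable) == 1L) variable <- rep(variable, length(value))
  idx <- match(variable, stats$variable)
  if (anyNA(idx)) {
    stop_input("unknown variable(s) for z-scoring: ",
               paste(unique(variable[is.na(idx)]), collapse = ", "))
  }
  (value - stats$mean[idx]) / stats$sd[idx]
}

#' Invert a z-score back to the raw scale
#'
#' @inheritParams zscore
#' @param z Numeric vector of z-scores.
#' @return Raw-scale values `z * sd + mean`.
#' @export
unzscore <- function(z, variable, stats) {
  stopifnot(inherits(stats, "population_stats"))
  if (length(variable) == 1L) variable <- rep(variable, length(z))
  idx <- match(variable, stats$variable)
  if (anyNA(idx)) {
    stop_input("unknown variable(s): ",
               paste(unique(variable[is.na(idx)]), collapse = ", "))
  }
  z * stats$sd[idx] + stats$mean[idx]
}

#' @export
print.population_stats <- function(x, ...) {
  cat("Population z-scoring reference (pooled, post-artifact-removal):\n")
  print.data.frame(x, row.names = FALSE, digits = 6)
  invisible(x)
}
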