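# The one fitting function: cohort in, fitted TVI pattern model out.

#' Fit TVI profiles and expression patterns to a cohort
#'
#' Runs the full index construction on an intraoperative cohort: arterial
#' MAP precedence, MAC summation, artifact removal, population z-scoring,
#' five-timepoint windowing, TVI profile assembly, fixed-grid featurization,
#' k-means pattern discovery with elevated/mixed/depressed labelling, and
#' intraoperative event flagging (hypotension, triple low state).
#'
#' @param cohort A `tvi_cohort` (from [generate_cohort()] or
#'   [read_cohort()]), or a list with at least `measurements` and `cases`.
#' @param k Number of expression patterns (default 3; only `k = 3` gets the
#'   canonical elevated/mixed/depressed labels).
#' @param window_size Distinct measurement timepoints per window (default 5).
#' @param grid_length Featurization grid length (default 20).
#' @param fill Featurization fill rule, `"profile_mean"` (default) or
#'   `"zero"` (see [featurization_params()]).
#' @param n_starts,max_iter k-means random starts and iteration cap
#'   (defaults 10 and 100).
#' @param seed RNG seed for the k-means starts.
#' @param limits An [artifact_limits()] object.
#' @param equivalents A [mac_equivalents()] object.
#' @param criteria A [triple_low_criteria()] object.
#' @param ioh_threshold Intraoperative hypotension threshold, mmHg.
#' @return An object of class `tvi_fit` with elements `profiles`
#'   ([assemble_profiles()]), `model` (labelled [cluster_profiles()]),
#'   `features`, `flags` ([event_flags()]), `stream`, `removed` (artifact
#'   audit), `cases`, `medications`, `params`, and `call`. Methods:
#'   `print`, `summary` (cluster characterization), `plot` (profile-matrix
#'   heatmap), `predict` (assign new cases to patterns), `coef` (centroids).
#' @examples
#' cohort <- generate_cohort(cohort_spec(n_cases = 60, seed = 42))
#' fit <- tvi_fit(cohort, seed = 1)
#' print(fit)
#' @export
tvi_fit <- function(cohort, k = 3L, window_size = 5L, grid_length = 20L,
                    fill = c("profile_mean", "zero"), n_starts = 10L,
                    max_iter = 100L, seed = 1L,
                    limits = artifact_limits(),
                    equivalents = mac_equivalents(),
                    criteria = triple_low_criteria(),
                    ioh_threshold = 55) {
  fill <- match.arg(fill)
  if (is.null(cohort$measurements) || is.null(cohort$cases)) {
    stop_input("cohort must contain measurements and cases")
  }
  prep <- prepare_stream(cohort$measurements, limits, equivalents)
  stats <- fit_population_stats(prep$stream)
  profiles <- assemble_profiles(prep, stats, window_size)
  params <- featurization_params(grid_length, fill)
  features <- featurize_profiles(profiles, params)
  model <- cluster_profiles(features, k = k, n_starts = n_starts,
                            max_iter = max_iter, seed = seed)
  model <- label_clusters(model, profiles)
  flags <- event_flags(prep$stream, profiles, criteria, ioh_threshold)

  structure(list(profiles = profiles, model = model, features = features,
                 flags = flags, stream = prep$stream, removed = prep$removed,
                 cases = cohort$cases, medications = cohort$medications,
                 params = list(k = k, window_size = window_size,
                               featurization = params, limits = limits,
                               equivalents = equivalents,
                               criteria = criteria,
                               ioh_threshold = ioh_threshold,
                               n_starts = n_starts, max_iter = max_iter,
                               seed = seed),
                 call = match.call()),
            class = "tvi_fit")
}

#' @export
print.tvi_fit <- function(x, ...) {
  cat("Triple Variable Index fit\n")
  cat("  profiles:", nrow(x$profiles$spans),
      "| windows:", nrow(x$profiles$windows),
      "| TVI values:", sum(!is.na(x$profiles$windows$tvi)), "\n")
  cat("  excluded cases (no TVI window):", nrow(x$profiles$excluded),
      "| artifact rows removed:", nrow(x$removed), "\n")
  print(x$model)
  invisible(x)
}

#' @rdname tvi_fit
#' @param object,x A `tvi_fit` object.
#' @param ... Passed to [characterize_clusters()] (for `summary`) or ignored.
#' @export
summary.tvi_fit <- function(object, ...) {
  characterize_clusters(object, ...)
}

#' @rdname tvi_fit
#' @export
coef.tvi_fit <- function(object, ...) {
  object$model$centroids
}

#' @rdname tvi_fit
#' @param newdata A cohort (as in `cohort`) of new cases to assign to the
#'   fitted patterns using the training population's z-scoring reference and
#'   centroids.
#' @export
predict.tvi_fit <- function(object, newdata, ...) {
  prep <- prepare_stream(newdata$measurements, object$params$limits,
                         object$params$equivalents)
  profiles <- assemble_profiles(prep, object$profiles$stats,
                                object$params$window_size)
  features <- featurize_profiles(profiles, object$params$featurization)
  cl <- predict(object$model, features)
  data.frame(case_id = names(cl), cluster_index = unname(cl),
             cluster_label = unname(object$model$labels[as.character(cl)]),
             stringsAsFactors = FALSE)
}

#' @rdname tvi_fit
#' @param order Row ordering for the heatmap: by cluster or by procedure
#'   length within cluster.
#' @export
plot.tvi_fit <- function(x, order = c("cluster", "procedure_length"), ...) {
  order <- match.arg(order)
  mat <- export_profile_matrix(x$profiles, x$model, order = order,
                               path = NULL)
  plot_profile_matrix(mat, ...)
  invisible(mat)
}

#' Per-case median TVI values
#'
#' @param fit A [tvi_fit()] object.
#' @return Named numeric vector (case id -> median of present TVI values).
#' @export
median_tvi <- function(fit) {
  stopifnot(inherits(fit, "tvi_fit"))
  win <- fit$profiles$windows
  out <- tapply(win$tvi, win$case_id, stats::median, na.rm = TRUE)
  stats::setNames(as.vector(out), names(out))
}
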