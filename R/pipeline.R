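# Pipeline orchestration: synth/ingest -> TVI -> cluster -> events ->
# characterization -> mortality contest, with a run manifest for
# reproducibility. All numeric outputs are a pure function of (inputs,
# config).

#' Run the full TVI pipeline
#'
#' Either generates a synthetic cohort (when `config$synth` is given) or
#' reads one from `config$input_dir`, fits the TVI pattern model, detects
#' events, characterizes clusters, runs the 30-day mortality prediction
#' contest, and writes every stage output plus a manifest to `out_dir`.
#'
#' @param config Named list. Recognized entries: `synth` (list of
#'   [cohort_spec()] arguments) or `input_dir`; `k`, `window_size`,
#'   `grid_length`, `fill`, `n_starts`, `max_iter`, `seed`; `limits`,
#'   `equivalents`, `criteria`, `ioh_threshold`; `characterize_n_boot`,
#'   `contest_n_boot`. A YAML file path is also accepted (requires the
#'   `yaml` package).
#' @param out_dir Output directory.
#' @return Invisibly, a list with the `fit`, `characterization`, `contest`,
#'   and the written file paths.
#' @export
run_pipeline <- function(config = list(), out_dir) {
  if (is.character(config) && length(config) == 1L) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop_input("reading a YAML config requires the yaml package")
    }
    config <- yaml::read_yaml(config)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  cohort <- if (!is.null(config$input_dir)) {
    read_cohort(config$input_dir)
  } else {
    synth_args <- config$synth %||% list()
    generate_cohort(do.call(cohort_spec, synth_args))
  }

  seed <- config$seed %||% 1L
  fit <- tvi_fit(cohort,
                 k = config$k %||% 3L,
                 window_size = config$window_size %||% 5L,
                 grid_length = config$grid_length %||% 20L,
                 fill = config$fill %||% "zero",
                 n_starts = config$n_starts %||% 10L,
                 max_iter = config$max_iter %||% 100L,
                 seed = seed,
                 limits = config$limits %||% artifact_limits(),
                 equivalents = config$equivalents %||% mac_equivalents(),
                 criteria = config$criteria %||% triple_low_criteria(),
                 ioh_threshold = config$ioh_threshold %||% 55)

  characterization <- characterize_clusters(
    fit, n_boot = config$characterize_n_boot %||% 1000L, seed = seed)
  contest <- mortality_prediction_contest(
    fit, n_boot = config$contest_n_boot %||% 2000L, seed = seed)

  paths <- list(
    profiles = file.path(out_dir, "profiles.csv"),
    assignments = file.path(out_dir, "assignments.csv"),
    model = file.path(out_dir, "model.json"),
    flags = file.path(out_dir, "flags.csv"),
    characterization = file.path(out_dir, "characterization.csv"),
    patient_level = file.path(out_dir, "patient_level_mortality.csv"),
    correlations = file.path(out_dir, "correlations.csv"),
    contest = file.path(out_dir, "contest.json"),
    artifact_log = file.path(out_dir, "artifact_log.csv"),
    profile_matrix = file.path(out_dir, "profile_matrix.csv"),
    manifest = file.path(out_dir, "manifest.json")
  )
  write_profiles(fit$profiles, paths$profiles)
  utils::write.csv(cluster_assignments(fit$model), paths$assignments,
                   row.names = FALSE)
  write_cluster_model(fit$model, paths$model, fit$params$featurization)
  write_flags(fit$flags, paths$flags)
  utils::write.csv(characterization$table, paths$characterization,
                   row.names = FALSE, na = "")
  utils::write.csv(characterization$patient_level, paths$patient_level,
                   row.names = FALSE)
  utils::write.csv(
    compute_correlations(fit$profiles, cluster_assignments(fit$model)),
    paths$correlations, row.names = FALSE, na = "")
  write_contest(contest, paths$contest)
  write_artifact_log(fit$removed, paths$artifact_log)
  export_profile_matrix(fit$profiles, fit$model, order = "cluster",
                        path = paths$profile_matrix, cases = fit$cases)

  manifest <- list(
    package = "tviprofiles",
    version = as.character(utils::packageVersion("tviprofiles")),
    seed = seed,
    k = fit$params$k,
    window_size = fit$params$window_size,
    grid_length = fit$params$featurization$grid_length,
    fill = fit$params$featurization$fill,
    n_starts = fit$params$n_starts,
    max_iter = fit$params$max_iter,
    synth = config$synth,
    input_dir = config$input_dir,
    input_md5 = if (!is.null(config$input_dir)) {
      as.list(tools::md5sum(list.files(config$input_dir, full.names = TRUE,
                                       pattern = "\\.csv$")))
    },
    n_profiles = nrow(fit$profiles$spans),
    n_excluded = nrow(fit$profiles$excluded)
  )
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       digits = NA, null = "null")

  invisible(list(fit = fit, characterization = characterization,
                 contest = contest, paths = paths))
}

#' Export the profile matrix
#'
#' Rows are profiles, columns are window indices, cells are TVI values (`NA`
#' where no TVI exists); ragged profiles are right-padded with `NA`. Rows
#' can be ordered by cluster, or by procedure length within cluster (useful
#' for visualizing bypass gaps).
#'
#' @param profiles A [assemble_profiles()] object.
#' @param model Optional labelled [cluster_profiles()] model for ordering
#'   and the `cluster_label` column.
#' @param order `"cluster"` or `"procedure_length"` (shortest first within
#'   cluster).
#' @param path Optional CSV output path.
#' @param cases Unused placeholder for future orderings.
#' @return A `data.frame`: `case_id`, `cluster_label` (if a model is given),
#'   then `w0 ... w(max-1)` TVI columns.
#' @export
export_profile_matrix <- function(profiles, model = NULL,
                                  order = c("cluster", "procedure_length"),
                                  path = NULL, cases = NULL) {
  order <- match.arg(order)
  stopifnot(inherits(profiles, "tvi_profiles"))
  win <- profiles$windows
  spans <- profiles$spans
  wmax <- max(spans$n_windows)
  mat <- matrix(NA_real_, nrow = nrow(spans), ncol = wmax,
                dimnames = list(spans$case_id, paste0("w", seq_len(wmax) - 1L)))
  mat[cbind(match(win$case_id, spans$case_id), win$window_index + 1L)] <- win$tvi

  out <- data.frame(case_id = spans$case_id, stringsAsFactors = FALSE)
  if (!is.null(model)) {
    asg <- cluster_assignments(model)
    out$cluster_label <- asg$cluster_label[match(out$case_id, asg$case_id)]
  }
  out <- cbind(out, as.data.frame(mat, row.names = FALSE))

  dur <- spans$t_last - spans$t_first
  ord <- if (!is.null(model) && order == "procedure_length") {
    order(out$cluster_label, dur)
  } else if (!is.null(model)) {
    order(out$cluster_label)
  } else {
    order(dur)
  }
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  if (!is.null(path)) utils::write.csv(out, path, row.names = FALSE, na = "")
  out
}

#' Plot a profile matrix as a heatmap
#'
#' Diverging palette: red for positive TVI, blue for negative, white for
#' windows without a TVI value. A convenience over the canonical CSV
#' artifact; draws on the current graphics device.
#'
#' @param mat Output of [export_profile_matrix()].
#' @param ... Passed to [graphics::image()].
#' @return Invisibly, the numeric matrix drawn.
#' @export
plot_profile_matrix <- function(mat, ...) {
  num <- as.matrix(mat[grep("^w[0-9]+$", names(mat))])
  lim <- max(abs(num), na.rm = TRUE)
  pal <- grDevices::colorRampPalette(c("blue", "white", "red"))(64)
  graphics::image(x = seq_len(ncol(num)) - 1L, y = seq_len(nrow(num)),
                  z = t(num[rev(seq_len(nrow(num))), , drop = FALSE]),
                  zlim = c(-lim, lim), col = pal,
                  xlab = "window index", ylab = "profile",
                  useRaster = FALSE, ...)
  invisible(num)
}
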