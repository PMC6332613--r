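# Fixed-length embedding of variable-length TVI profiles. Each present TVI
# value is placed on a proportion grid of length L at position
# round(window_proportion * (L - 1)); collisions are averaged and unfilled
# positions receive a fill value (0 = population-average TVI, or the
# profile's own mean). This makes profiles of any length comparable for
# k-means without interpolating data that was never measured.

#' Featurization parameters
#'
#' @param grid_length Number of grid positions `L` (default 20; must be >= 2).
#' @param fill Fill rule for grid positions no TVI value maps to:
#'   `"profile_mean"` (default; the profile's own mean TVI, so sparse
#'   profiles keep their expression level) or `"zero"` (missing positions
#'   treated as population-average TVI; shrinks short profiles toward a
#'   neutral pattern, available for sensitivity analysis).
#' @return An object of class `featurization_params`.
#' @export
featurization_params <- function(grid_length = 20L,
                                 fill = c("profile_mean", "zero")) {
  fill <- match.arg(fill)
  if (!is.numeric(grid_length) || grid_length < 2L) {
    stop_input("grid_length must be an integer >= 2")
  }
  structure(list(grid_length = as.integer(grid_length), fill = fill),
            class = "featurization_params")
}

#' Embed TVI profiles on a fixed-length proportion grid
#'
#' @param profiles A [assemble_profiles()] object.
#' @param params A [featurization_params()] object.
#' @return Numeric matrix, one row per admitted profile (rownames =
#'   `case_id`), `grid_length` columns.
#' @export
featurize_profiles <- function(profiles, params = featurization_params()) {
  stopifnot(inherits(profiles, "tvi_profiles"),
            inherits(params, "featurization_params"))
  L <- params$grid_length
  win <- profiles$windows
  spans <- profiles$spans
  if (any(spans$n_tvi == 0L)) {
    stop_input("profile(s) without any TVI value cannot be featurized")
  }
  present <- win[!is.na(win$tvi), c("case_id", "window_index", "tvi")]
  w_tot <- spans$n_windows[match(present$case_id, spans$case_id)]
  prop <- ifelse(w_tot == 1L, 0, present$window_index / (w_tot - 1))
  pos <- as.integer(round(prop * (L - 1)))

  row <- match(present$case_id, spans$case_id)
  key <- (row - 1L) * L + pos + 1L
  sums <- rowsum(present$tvi, key)
  counts <- rowsum(rep(1, length(key)), key)
  mat <- matrix(NA_real_, nrow = nrow(spans), ncol = L,
                dimnames = list(spans$case_id, NULL))
  idx <- as.integer(rownames(sums))
  mat[cbind(((idx - 1L) %/% L) + 1L, ((idx - 1L) %% L) + 1L)] <-
    as.vector(sums) / as.vector(counts)

  if (params$fill == "zero") {
    mat[is.na(mat)] <- 0
  } else {
    pm <- grouped_mean(present$tvi, present$case_id)[spans$case_id]
    na_idx <- which(is.na(mat), arr.ind = TRUE)
    mat[na_idx] <- pm[na_idx[, 1L]]
  }
  mat
}
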