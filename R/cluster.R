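# k-means discovery of TVI expression patterns and their canonical
# elevated/mixed/depressed labels.

#' Cluster featurized TVI profiles with k-means
#'
#' Lloyd k-means on the fixed-length feature grid (Euclidean distance, no
#' further scaling: every position is already in TVI z-sum units), best of
#' `n_starts` random starts by within-cluster sum of squares, deterministic
#' given `seed`.
#'
#' @param features Feature matrix from [featurize_profiles()] (rownames =
#'   case ids).
#' @param k Number of clusters (default 3).
#' @param n_starts Random starts (default 10).
#' @param max_iter Maximum Lloyd iterations per start (default 100).
#' @param seed RNG seed for the random starts.
#' @return An object of class `tvi_kmeans`: `k`, `centroids` (k x L),
#'   `cluster` (named integer vector, case id -> cluster index), `sizes`,
#'   `inertia` (total within-cluster sum of squares), `n_starts`,
#'   `max_iter`, `seed`. Cluster labels are added by [label_clusters()].
#' @export
cluster_profiles <- function(features, k = 3L, n_starts = 10L,
                             max_iter = 100L, seed = 1L) {
  features <- as.matrix(features)
  if (nrow(unique(features)) < k) {
    stop_input("fewer than k distinct feature vectors")
  }
  km <- with_seed(seed, suppressWarnings(
    stats::kmeans(features, centers = k, nstart = n_starts,
                  iter.max = max_iter, algorithm = "Lloyd")
  ))
  structure(list(k = as.integer(k),
                 centroids = km$centers,
                 cluster = stats::setNames(km$cluster, rownames(features)),
                 sizes = km$size,
                 inertia = km$tot.withinss,
                 n_starts = as.integer(n_starts),
                 max_iter = as.integer(max_iter),
                 seed = seed,
                 labels = NULL,
                 cluster_mean_tvi = NULL),
            class = "tvi_kmeans")
}

#' Label clusters elevated / mixed / depressed
#'
#' Ranks clusters by the mean TVI over their member profiles' present TVI
#' values. With `k = 3` the highest-mean cluster is labelled `elevated`, the
#' lowest `depressed`, and the middle `mixed`; for other `k`, rank labels
#' `cluster_0` (highest) .. `cluster_(k-1)` are used. Exact ties in mean TVI
#' are broken by cluster size (larger ranks toward the middle) with a
#' message.
#'
#' @param model A [cluster_profiles()] object.
#' @param profiles The [assemble_profiles()] object the features came from.
#' @return The model with `labels` (cluster index -> label) and
#'   `cluster_mean_tvi` filled in.
#' @export
label_clusters <- function(model, profiles) {
  stopifnot(inherits(model, "tvi_kmeans"), inherits(profiles, "tvi_profiles"))
  win <- profiles$windows[!is.na(profiles$windows$tvi), ]
  cl <- model$cluster[win$case_id]
  if (anyNA(cl)) stop_input("profiles contain cases absent from the model")
  means <- as.vector(rowsum(win$tvi, cl) / rowsum(rep(1, nrow(win)), cl))
  names(means) <- rownames(rowsum(win$tvi, cl))
  means <- means[as.character(seq_len(model$k))]
  if (anyNA(means)) stop_input("empty cluster: cannot label")
  if (anyDuplicated(means)) {
    message("tie in cluster mean TVI; breaking by cluster size ",
            "(larger cluster ranks toward the middle)")
  }
  ord <- order(-means, -model$sizes)  # cluster indices, highest mean first
  labels <- if (model$k == 3L) {
    c("elevated", "mixed", "depressed")
  } else {
    paste0("cluster_", seq_len(model$k) - 1L)
  }
  lab <- character(model$k)
  lab[ord] <- labels
  model$labels <- stats::setNames(lab, as.character(seq_len(model$k)))
  model$cluster_mean_tvi <- means
  model
}

#' Cluster assignments as a data frame
#'
#' @param model A labelled [cluster_profiles()] object.
#' @return `data.frame` with `case_id`, `cluster_index`, `cluster_label`.
#' @export
cluster_assignments <- function(model) {
  stopifnot(inherits(model, "tvi_kmeans"))
  data.frame(case_id = names(model$cluster),
             cluster_index = unname(model$cluster),
             cluster_label = if (is.null(model$labels)) NA_character_ else
               unname(model$labels[as.character(model$cluster)]),
             stringsAsFactors = FALSE)
}

#' @export
print.tvi_kmeans <- function(x, ...) {
  cat("TVI k-means pattern model: k =", x$k,
      "| inertia =", format(x$inertia, digits = 6),
      "| seed =", x$seed, "\n")
  tab <- data.frame(cluster = seq_len(x$k),
                    size = x$sizes,
                    mean_tvi = if (is.null(x$cluster_mean_tvi)) NA_real_
                               else round(unname(x$cluster_mean_tvi), 3),
                    label = if (is.null(x$labels)) NA_character_
                            else unname(x$labels))
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Assign new feature vectors to the nearest centroid
#'
#' @param object A [cluster_profiles()] model.
#' @param newdata Feature matrix with the model's grid length.
#' @param ... Unused.
#' @return Named integer vector of cluster indices (labels as an attribute
#'   when the model is labelled).
#' @export
predict.tvi_kmeans <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != ncol(object$centroids)) {
    stop_input("newdata must have ", ncol(object$centroids), " columns")
  }
  d2 <- outer(rowSums(newdata^2), rep(1, object$k)) -
    2 * newdata %*% t(object$centroids) +
    outer(rep(1, nrow(newdata)), rowSums(object$centroids^2))
  cl <- max.col(-d2, ties.method = "first")
  out <- stats::setNames(cl, rownames(newdata))
  if (!is.null(object$labels)) {
    attr(out, "labels") <- unname(object$labels[as.character(cl)])
  }
  out
}

#' Write the cluster model as JSON
#'
#' @param model A labelled [cluster_profiles()] model.
#' @param path Output path.
#' @param params Optional [featurization_params()] to record.
#' @return The path, invisibly.
#' @export
write_cluster_model <- function(model, path, params = NULL) {
  stopifnot(inherits(model, "tvi_kmeans"))
  obj <- list(k = model$k, seed = model$seed, n_starts = model$n_starts,
              max_iter = model$max_iter, inertia = model$inertia,
              centroids = unname(apply(model$centroids, 1L, identity,
                                       simplify = FALSE)),
              labels = as.list(model$labels %||% list()),
              params = if (!is.null(params)) unclass(params))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
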