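planted_features <- function(n_per = 40, L = 12, gap = 4, seed = 42) {
  withr::with_seed(seed, {
    mu <- c(-gap, 0, gap)
    x <- do.call(rbind, lapply(1:3, function(g) {
      matrix(rnorm(n_per * L, mu[g]), n_per, L)
    }))
    rownames(x) <- sprintf("C%03d", seq_len(3 * n_per))
    list(x = x, truth = rep(1:3, each = n_per))
  })
}

test_that("k-means recovers well-separated planted groups", {
  pf <- planted_features()
  m <- cluster_profiles(pf$x, k = 3, seed = 9)
  expect_gte(mclust::adjustedRandIndex(m$cluster, pf$truth), 0.9)
  expect_equal(sort(unname(m$sizes)), rep(40L, 3))
})

test_that("k = 1 collapses to the grand centroid with inertia = TSS", {
  pf <- planted_features(n_per = 15)
  m <- cluster_profiles(pf$x, k = 1, seed = 9)
  tss <- sum(scale(pf$x, scale = FALSE)^2)
  expect_equal(m$inertia, tss)
  expect_true(all(m$cluster == 1L))
})

test_that("uniform duplication leaves the centroids unchanged", {
  pf <- planted_features(n_per = 20)
  x2 <- rbind(pf$x, pf$x)
  rownames(x2) <- c(paste0(rownames(pf$x), "a"), paste0(rownames(pf$x), "b"))
  m1 <- cluster_profiles(pf$x, k = 3, seed = 9)
  m2 <- cluster_profiles(x2, k = 3, seed = 9)
  sort_ctr <- function(m) m$centroids[order(rowMeans(m$centroids)), ]
  expect_equal(unname(sort_ctr(m2)), unname(sort_ctr(m1)), tolerance = 1e-8)
})

test_that("the found partition is invariant to input row order", {
  pf <- planted_features(n_per = 25)
  m1 <- cluster_profiles(pf$x, k = 3, seed = 9)
  perm <- withr::with_seed(1, sample(nrow(pf$x)))
  m2 <- cluster_profiles(pf$x[perm, ], k = 3, seed = 9)
  expect_equal(
    mclust::adjustedRandIndex(m1$cluster[rownames(pf$x)],
                              m2$cluster[rownames(pf$x)]), 1)
})

test_that("fewer than k distinct vectors is an error", {
  x <- matrix(rep(c(0, 1), each = 6), nrow = 4, byrow = TRUE)
  rownames(x) <- paste0("C", 1:4)
  expect_error(cluster_profiles(x, k = 3), "distinct")
})

test_that("within-cluster sum of squares is non-increasing over Lloyd
           iterations", {
  pf <- planted_features(n_per = 30, gap = 1)  # slow convergence regime
  init <- pf$x[c(1, 2, 3), ]
  wcss <- vapply(1:8, function(it) {
    suppressWarnings(stats::kmeans(pf$x, centers = init, iter.max = it,
                                   algorithm = "Lloyd"))$tot.withinss
  }, numeric(1))
  expect_true(all(diff(wcss) <= 1e-8))
})

test_that("clusters are labelled by mean TVI rank", {
  # three cases, one window each, known TVI
  w <- data.frame(case_id = c("A", "B", "C"), window_index = 0L,
                  map_mean_z = c(1.2, 0, -1.3), bis_mean_z = 0,
                  mac_mean_z = 0, map_mean = 80, bis_mean = 50, mac_mean = 1,
                  tvi = c(1.2, 0, -1.3))
  prof <- make_profiles(w)
  model <- structure(list(k = 3L, centroids = diag(3),
                          cluster = c(A = 2L, B = 3L, C = 1L),
                          sizes = c(1L, 1L, 1L), inertia = 0,
                          n_starts = 10L, max_iter = 100L, seed = 1L),
                     class = "tvi_kmeans")
  lab <- label_clusters(model, prof)
  expect_equal(unname(lab$labels[c("2", "3", "1")]),
               c("elevated", "mixed", "depressed"))
  asg <- cluster_assignments(lab)
  expect_equal(asg$cluster_label[match(c("A", "B", "C"), asg$case_id)],
               c("elevated", "mixed", "depressed"))

  # k = 2 falls back to rank labels, highest mean first
  model2 <- structure(list(k = 2L, centroids = diag(2),
                           cluster = c(A = 2L, B = 1L, C = 1L),
                           sizes = c(2L, 1L), inertia = 0,
                           n_starts = 10L, max_iter = 100L, seed = 1L),
                      class = "tvi_kmeans")
  lab2 <- label_clusters(model2, prof)
  expect_equal(unname(lab2$labels), c("cluster_1", "cluster_0"))
})

test_that("label assignment is invariant to cluster index permutation", {
  w <- data.frame(case_id = c("A", "B", "C"), window_index = 0L,
                  map_mean_z = c(2, 0, -2), bis_mean_z = 0, mac_mean_z = 0,
                  map_mean = 80, bis_mean = 50, mac_mean = 1,
                  tvi = c(2, 0, -2))
  prof <- make_profiles(w)
  base <- list(k = 3L, centroids = diag(3), sizes = c(1L, 1L, 1L),
               inertia = 0, n_starts = 10L, max_iter = 100L, seed = 1L)
  m1 <- structure(c(base, list(cluster = c(A = 1L, B = 2L, C = 3L))),
                  class = "tvi_kmeans")
  m2 <- structure(c(base, list(cluster = c(A = 3L, B = 1L, C = 2L))),
                  class = "tvi_kmeans")
  a1 <- cluster_assignments(label_clusters(m1, prof))
  a2 <- cluster_assignments(label_clusters(m2, prof))
  expect_equal(a1$cluster_label[order(a1$case_id)],
               a2$cluster_label[order(a2$case_id)])
})

test_that("nearest-centroid prediction matches training assignments on
           separated data", {
  pf <- planted_features(n_per = 20)
  m <- cluster_profiles(pf$x, k = 3, seed = 9)
  pred <- predict(m, pf$x)
  expect_equal(unname(pred), unname(m$cluster[rownames(pf$x)]))
})
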