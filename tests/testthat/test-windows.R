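test_that("worked micro case: 12 timepoints yield windows of 5, 5, 2 with
           hand-computable TVI", {
  mc <- generate_worked_micro_case()
  prep <- prepare_stream(mc$measurements)
  st <- fit_population_stats(prep$stream)
  prof <- assemble_profiles(prep, st)
  w <- prof$windows
  expect_equal(nrow(w), 3L)
  expect_equal(w$n_timepoints, c(5L, 5L, 2L))
  expect_equal(w$window_index, 0:2)

  # direct-arithmetic oracle from the raw value table
  raw <- mc$raw
  zmean <- function(x, all) (mean(x) - mean(all)) / stats::sd(all)
  idx <- list(1:5, 6:10, 11:12)
  expected <- vapply(idx, function(i) {
    zmean(raw$map[i], raw$map) + zmean(raw$bis[i], raw$bis) +
      zmean(raw$mac[i], raw$mac)
  }, numeric(1))
  expect_equal(w$tvi, expected, tolerance = 1e-12)
  expect_equal(w$map_mean, vapply(idx, function(i) mean(raw$map[i]),
                                  numeric(1)), tolerance = 1e-12)
})

test_that("a case shorter than one window yields a single remainder window", {
  df <- rbind(meas("A", c(1, 2, 3), "MAP", c(80, 82, 84), "NONINVASIVE"),
              meas("A", c(1, 2, 3), "BIS", c(40, 42, 44)),
              meas("A", c(1, 2, 3), "MAC", c(0.8, 0.9, 1.0)))
  st <- fit_population_stats(df)
  w <- build_windows(df, st)
  expect_equal(nrow(w), 1L)
  expect_equal(w$n_timepoints, 3L)
  expect_false(is.na(w$tvi))
})

test_that("windows lacking a variable have absent means and no TVI", {
  df <- rbind(meas("A", 1:5, "MAP", rep(80, 5) + 1:5, "NONINVASIVE"),
              meas("A", 20, "BIS", 45), meas("A", 21, "BIS", 40),
              meas("A", 20, "MAC", 0.9), meas("A", 21, "MAC", 1.0))
  st <- fit_population_stats(df)
  w <- build_windows(df, st)
  expect_equal(nrow(w), 2L)
  expect_false(is.na(w$map_mean_z[1]))
  expect_true(is.na(w$bis_mean_z[1]))
  expect_true(is.na(w$tvi[1]))      # MAP-only window
  expect_true(is.na(w$tvi[2]))      # BIS+MAC window, MAP absent
  expect_false(is.na(w$bis_mean_z[2]))
  expect_true(is.na(w$map_mean_z[2]))
})

test_that("simultaneous measurements count as one timepoint", {
  df <- rbind(meas("A", c(1, 1, 2, 2, 3, 3), "MAP", 80 + 1:6, "NONINVASIVE"),
              meas("A", c(1, 2, 3), "BIS", c(40, 42, 44)),
              meas("A", c(1, 2, 3), "MAC", c(0.8, 0.9, 1.0)))
  st <- fit_population_stats(df)
  w <- build_windows(df, st)
  expect_equal(nrow(w), 1L)
  expect_equal(w$n_timepoints, 3L)
  # duplicate values at one timepoint all enter the window mean
  expect_equal(w$map_mean, mean(80 + 1:6))
})

test_that("every distinct timepoint lands in exactly one window", {
  co <- small_cohort()
  prep <- prepare_stream(co$measurements)
  prof <- assemble_profiles(prep)
  w <- prof$windows
  s <- prep$stream[prep$stream$case_id %in% prof$spans$case_id, ]
  n_tp <- tapply(s$t_min, s$case_id, function(t) length(unique(t)))
  sum_tp <- tapply(w$n_timepoints, w$case_id, sum)
  expect_equal(as.vector(sum_tp[names(n_tp)]), as.vector(n_tp))
  # all but the last window of each case hold exactly window_size timepoints
  last <- as.vector(tapply(w$window_index, w$case_id, max)[w$case_id])
  expect_true(all(w$n_timepoints[w$window_index < last] == 5L))
  expect_true(all(w$n_timepoints >= 1L & w$n_timepoints <= 5L))
  # TVI present exactly when all three means are present
  expect_equal(is.na(w$tvi),
               is.na(w$map_mean_z) | is.na(w$bis_mean_z) | is.na(w$mac_mean_z))
  # and equals their sum exactly
  ok <- !is.na(w$tvi)
  expect_identical(w$tvi[ok],
                   w$map_mean_z[ok] + w$bis_mean_z[ok] + w$mac_mean_z[ok])
})

test_that("cases with no computable TVI window are excluded with a reason", {
  df <- rbind(meas("A", 1:6, "MAP", 80 + 1:6, "NONINVASIVE"),
              meas("B", 1:5, "MAP", rep(80, 5) + 1:5, "NONINVASIVE"),
              meas("B", 1:5, "BIS", 40 + 1:5),
              meas("B", 1:5, "MAC", seq(0.8, 1.2, 0.1)))
  prof <- assemble_profiles(df)
  expect_equal(prof$excluded$case_id, "A")
  expect_equal(prof$excluded$reason, "no_tvi_window")
  expect_equal(unique(prof$windows$case_id), "B")
})

test_that("a bypass-style MAC gap yields windows without TVI mid-profile", {
  t <- 1:15
  df <- rbind(meas("A", t, "MAP", 80 + t, "NONINVASIVE"),
              meas("A", t, "BIS", 40 + t %% 5),
              meas("A", t[t <= 5 | t > 10], "MAC",
                   0.9 + 0.01 * t[t <= 5 | t > 10]))
  prof <- assemble_profiles(df)
  w <- prof$windows
  expect_equal(nrow(w), 3L)
  expect_equal(is.na(w$tvi), c(FALSE, TRUE, FALSE))
})

test_that("compute_tvi sums the three window means or returns NA", {
  expect_equal(compute_tvi(list(map_mean_z = 0.5, bis_mean_z = -0.2,
                                mac_mean_z = 0.1)), 0.4)
  expect_equal(compute_tvi(list(map_mean_z = 0, bis_mean_z = 0,
                                mac_mean_z = 0)), 0)
  expect_true(is.na(compute_tvi(list(map_mean_z = 0.5, bis_mean_z = -0.2,
                                     mac_mean_z = NA_real_))))
})

test_that("temporal proportion maps times onto the monitoring period", {
  expect_identical(temporal_proportion(6, c(0, 60)), 0.1)
  expect_identical(temporal_proportion(0, c(0, 60)), 0)
  expect_identical(temporal_proportion(60, c(0, 60)), 1)
  t <- sort(runif(20, 3, 47))
  p <- temporal_proportion(t, c(3, 47))
  expect_true(all(diff(p) >= 0))
  expect_error(temporal_proportion(5, c(10, 10)), "span")
  expect_error(temporal_proportion(61, c(0, 60)), "outside")
})

test_that("window proportion spans [0, 1] over the profile", {
  expect_identical(window_proportion(0L, 11L), 0)
  expect_identical(window_proportion(10L, 11L), 1)
  expect_identical(window_proportion(5L, 11L), 0.5)
  expect_identical(window_proportion(0L, 1L), 0)
  expect_error(window_proportion(3L, 3L), "out of range")
})

test_that("window size 1 makes every timepoint its own window", {
  df <- rbind(meas("A", 1:7, "MAP", 80 + 1:7, "NONINVASIVE"),
              meas("A", 1:7, "BIS", 40 + 1:7),
              meas("A", 1:7, "MAC", seq(0.7, 1.3, 0.1)))
  prof <- assemble_profiles(df, window_size = 1L)
  expect_equal(nrow(prof$windows), 7L)
  expect_true(all(prof$windows$n_timepoints == 1L))
  expect_error(build_windows(df[0, ], fit_population_stats(df)), "empty")
  expect_error(
    build_windows(rbind(df, meas("B", 1, "MAP", 80, "ARTERIAL")),
                  fit_population_stats(df)),
    "single case")
})
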