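tls_profile <- function(map, bis, mac) {
  make_profiles(data.frame(case_id = "A",
                           window_index = seq_along(map) - 1L,
                           map_mean_z = 0, bis_mean_z = 0, mac_mean_z = 0,
                           map_mean = map, bis_mean = bis, mac_mean = mac,
                           tvi = 0, stringsAsFactors = FALSE))
}

test_that("triple low windows require all three means strictly below
           threshold", {
  expect_equal(detect_tls(tls_profile(74, 44, 0.79))$tls_window_count, 1L)
  expect_equal(detect_tls(tls_profile(75, 44, 0.79))$tls_window_count, 0L)
  expect_equal(detect_tls(tls_profile(74, 45, 0.79))$tls_window_count, 0L)
  expect_equal(detect_tls(tls_profile(74, 44, 0.8))$tls_window_count, 0L)

  # qualifying, MAC-absent, qualifying -> count 2
  fl <- detect_tls(tls_profile(c(74, 74, 74), c(44, 44, 44),
                               c(0.79, NA, 0.79)))
  expect_equal(fl$tls_window_count, 2L)
  expect_true(fl$tls_any)
  expect_equal(detect_tls(tls_profile(80, 50, 1))$tls_any, FALSE)
})

test_that("intraoperative hypotension uses raw MAP measurements, strict <55", {
  s54 <- meas("A", 1:3, "MAP", c(80, 54, 90), "NONINVASIVE")
  s55 <- meas("A", 1:3, "MAP", c(80, 55, 90), "NONINVASIVE")
  expect_true(unname(detect_ioh(s54)["A"]))
  expect_false(unname(detect_ioh(s55)["A"]))
  expect_false(unname(detect_ioh(meas("A", 1:3, "MAP", rep(80, 3),
                                      "NONINVASIVE"))["A"]))
  expect_error(detect_ioh(meas("A", 1, "BIS", 45)), "without any MAP")
})

test_that("mortality windows follow the day boundaries their names force", {
  cls <- classify_mortality(c(0, 30, 31, 365, 366, 730, 731, NA))
  expect_equal(as.character(cls),
               c("d30", "d30", "d31_365", "d31_365", "d366_730", "d366_730",
                 "survived_beyond_730", "survived_beyond_730"))
  expect_equal(as.character(classify_mortality(NA_integer_,
                                               followup_days = 100)),
               "unknown")
  expect_error(classify_mortality(-1), "non-negative")
})

test_that("tls window count never exceeds the number of TVI windows", {
  fit <- tvi_fit(small_cohort(), seed = 7)
  w <- fit$profiles$windows
  n_tvi <- tapply(!is.na(w$tvi), w$case_id, sum)
  expect_true(all(fit$flags$tls_window_count <=
                    as.vector(n_tvi[fit$flags$case_id])))
  expect_equal(fit$flags$tls_any, fit$flags$tls_window_count >= 1L)
})

fake_fit <- function(cases, labels_by_case) {
  k <- length(unique(labels_by_case))
  lev <- unique(labels_by_case)
  cl <- match(labels_by_case, lev)
  names(cl) <- cases$case_id
  model <- structure(list(k = k, centroids = diag(k), cluster = cl,
                          sizes = as.vector(table(cl)), inertia = 0,
                          n_starts = 10L, max_iter = 100L, seed = 1L,
                          labels = stats::setNames(lev, seq_along(lev))),
                     class = "tvi_kmeans")
  structure(list(model = model, cases = cases), class = "tvi_fit")
}

test_that("patient-level sensitivity counts each patient once per cluster", {
  cases <- data.frame(
    case_id = c("S1", "S2", "S3", "S4", "S5"),
    patient_id = c("P1", "P1", "P2", "P3", "P1"),
    days_to_death = c(10L, 10L, NA, 200L, 10L),
    stringsAsFactors = FALSE)
  labs <- c("depressed", "depressed", "depressed", "elevated", "elevated")
  out <- patient_level_sensitivity(fake_fit(cases, labs))
  dep <- out[out$cluster == "depressed", ]
  # P1 (died d10, two depressed profiles) counted once of 2 patients
  expect_equal(dep$n_patients, 2L)
  expect_equal(dep$pct_mortality_d30, 50)
  # P1 also appears in elevated: counted once there too
  ele <- out[out$cluster == "elevated", ]
  expect_equal(ele$n_patients, 2L)
  expect_equal(ele$pct_mortality_d30, 50)
  expect_equal(ele$pct_mortality_d31_365, 50)
})

test_that("patient- and profile-level proportions agree when patients are
           unique", {
  fit <- tvi_fit(small_cohort(), seed = 7)
  # force unique patients
  fit$cases$patient_id <- paste0("U", seq_len(nrow(fit$cases)))
  pl <- patient_level_sensitivity(fit)
  asg <- cluster_assignments(fit$model)
  mort <- classify_mortality(
    fit$cases$days_to_death[match(asg$case_id, fit$cases$case_id)])
  for (lab in pl$cluster) {
    sel <- asg$cluster_label == lab
    expect_equal(pl$pct_mortality_d30[pl$cluster == lab],
                 100 * mean(mort[sel] == "d30"))
  }
})

test_that("window-level Pearson correlations behave on canonical cases", {
  w <- data.frame(case_id = "A", window_index = 0:9,
                  map_mean = seq(60, 105, 5), bis_mean = seq(30, 48, 2),
                  mac_mean = 1, map_mean_z = 0, bis_mean_z = 0,
                  mac_mean_z = 0, tvi = 0)
  out <- compute_correlations(make_profiles(w))
  expect_equal(out$r[out$pair == "MAP-BIS"], 1)           # exact linear
  expect_true(is.na(out$r[out$pair == "MAP-MAC"]))        # constant series

  big <- withr::with_seed(8, data.frame(
    case_id = "A", window_index = 0:9999,
    map_mean = rnorm(10000), bis_mean = rnorm(10000), mac_mean = rnorm(10000),
    map_mean_z = 0, bis_mean_z = 0, mac_mean_z = 0, tvi = 0))
  out2 <- compute_correlations(make_profiles(big))
  expect_true(all(abs(out2$r) < 0.05))                    # independent pairs
})

test_that("the depth-coupled generator yields negative BIS-MAC correlation", {
  co <- generate_cohort(cohort_spec(n_cases = 120,
                                    prevalence = c(0, 1, 0), seed = 21))
  prof <- assemble_profiles(prepare_stream(co$measurements))
  r_on <- compute_correlations(prof)
  expect_lt(r_on$r[r_on$pair == "BIS-MAC"], 0)

  co_off <- generate_cohort(cohort_spec(n_cases = 120,
                                        prevalence = c(0, 1, 0),
                                        depth_coupling = FALSE, seed = 21))
  prof_off <- assemble_profiles(prepare_stream(co_off$measurements))
  r_off <- compute_correlations(prof_off)
  expect_gt(r_off$r[r_off$pair == "BIS-MAC"],
            r_on$r[r_on$pair == "BIS-MAC"])
})

test_that("cluster characterization recovers planted orderings", {
  fit <- tvi_fit(small_cohort(), seed = 7)
  ch <- characterize_clusters(fit, n_boot = 100, seed = 3)
  tab <- ch$table
  get <- function(metric, cluster)
    tab$estimate[tab$metric == metric & tab$cluster == cluster]
  expect_gt(get("mean_map", "elevated"), get("mean_map", "mixed"))
  expect_gt(get("mean_map", "mixed"), get("mean_map", "depressed"))
  expect_gt(get("mean_tvi", "elevated"), get("mean_tvi", "depressed"))
  expect_gt(get("pct_tls", "depressed"), get("pct_tls", "elevated"))
  # profile counts partition the cohort
  expect_equal(sum(tab$estimate[tab$metric == "n_profiles"]),
               nrow(fit$profiles$spans))
  # proportions sit in [0, 100] with CI lower bound never below 0
  props <- tab[grepl("^pct_", tab$metric), ]
  expect_true(all(props$estimate >= 0 & props$estimate <= 100))
  expect_true(all(props$lower >= 0))
  # a zero-event proportion reports 0 with lower bound 0
  zero <- props[props$estimate == 0, ]
  if (nrow(zero) > 0) expect_true(all(zero$lower == 0))
  # mortality classes never exceed cluster size
  for (lab in unique(tab$cluster)) {
    n <- get("n_profiles", lab)
    mort_sum <- sum(vapply(c("pct_mortality_d30", "pct_mortality_d31_365",
                             "pct_mortality_d366_730"),
                           get, numeric(1), cluster = lab)) / 100 * n
    expect_lte(mort_sum, n + 1e-9)
  }
})

test_that("a single-cluster run reproduces the whole-population summary", {
  fit <- tvi_fit(small_cohort(), k = 1, seed = 7)
  ch <- characterize_clusters(fit, n_boot = 50, seed = 3)
  tab <- ch$table
  expect_equal(unique(tab$cluster), "cluster_0")
  expect_equal(tab$estimate[tab$metric == "n_profiles"],
               nrow(fit$profiles$spans))
  expect_equal(tab$estimate[tab$metric == "mean_age"],
               mean(fit$cases$age_years[fit$cases$case_id %in%
                                          fit$profiles$spans$case_id]))
})
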