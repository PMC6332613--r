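test_that("the generator is deterministic given a seed", {
  s <- cohort_spec(n_cases = 40, seed = 77)
  c1 <- generate_cohort(s)
  c2 <- generate_cohort(s)
  expect_identical(c1$measurements, c2$measurements)
  expect_identical(c1$cases, c2$cases)
  expect_identical(c1$medications, c2$medications)
  expect_identical(c1$truth, c2$truth)

  d1 <- tempfile(); d2 <- tempfile()
  write_cohort(c1, d1); write_cohort(c2, d2)
  for (f in list.files(d1)) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))))
  }
  c3 <- generate_cohort(s, seed = 78)
  expect_false(identical(c1$measurements, c3$measurements))
})

test_that("written cohorts survive the reader round trip", {
  co <- generate_cohort(cohort_spec(n_cases = 30, seed = 14))
  dir <- tempfile()
  write_cohort(co, dir)
  back <- read_cohort(dir)
  expect_equal(back$measurements$value, co$measurements$value)
  expect_equal(back$measurements$t_min, co$measurements$t_min)
  expect_equal(back$cases$case_id, co$cases$case_id)
  expect_equal(back$truth$regime, co$truth$regime)
})

test_that("per-regime sample means land on the specified regime means", {
  co <- recovery_cohort()   # n = 2000, default spec
  stream <- prepare_stream(co$measurements)$stream
  reg <- co$truth$regime[match(stream$case_id, co$truth$case_id)]
  spec <- co$spec
  for (v in c("MAP", "BIS", "MAC")) {
    mu <- tapply(stream$value[stream$variable == v],
                 reg[stream$variable == v], mean)
    target <- stats::setNames(spec[[paste0(tolower(v), "_mean")]],
                              c("elevated", "mixed", "depressed"))
    tol <- c(MAP = 1, BIS = 0.6, MAC = 0.02)[[v]]
    expect_true(all(abs(mu[names(target)] - target) < tol),
                label = paste("regime means for", v))
  }
})

test_that("zero artifact rate produces a clean stream", {
  co <- generate_cohort(cohort_spec(n_cases = 30, artifact_rate = 0,
                                    seed = 9))
  mb <- co$measurements[co$measurements$variable %in% c("MAP", "BIS"), ]
  expect_equal(nrow(remove_artifacts(mb)$removed), 0L)
  prep <- prepare_stream(co$measurements)
  expect_equal(nrow(prep$removed), 0L)
})

test_that("injected artifacts are caught by the filter at roughly the
           configured rate", {
  co <- recovery_cohort()
  prep <- prepare_stream(co$measurements)
  n_art <- sum(prep$removed$reason != "negligible_mac")
  rate <- n_art / nrow(co$measurements)
  expect_gt(rate, 0.002)
  expect_lt(rate, 0.010)
})

test_that("30-day mortality per planted regime is within 3 binomial SEs", {
  co <- recovery_cohort()
  spec <- co$spec
  tr <- co$truth
  d30 <- !is.na(tr$days_to_death) & tr$days_to_death <= 30
  for (i in 1:3) {
    sel <- tr$regime == regime_names_for_test[i]
    p <- spec$mortality_30d[i]
    se <- sqrt(p * (1 - p) / sum(sel))
    expect_lt(abs(mean(d30[sel]) - p), 3 * se + 1e-12)
  }
})

test_that("bypass cases blank agent data over the middle third of the case", {
  co <- generate_cohort(cohort_spec(n_cases = 300, cpb_fraction = 0.15,
                                    seed = 33))
  cpb_cases <- co$cases[co$cases$cpb_used, ]
  expect_gt(nrow(cpb_cases), 0L)
  m <- co$measurements
  for (cid in cpb_cases$case_id) {
    row <- cpb_cases[cpb_cases$case_id == cid, ]
    agents <- m[m$case_id == cid & m$variable == "SEVOFLURANE", ]
    inside <- agents$t_min >= row$cpb_start_min &
      agents$t_min <= row$cpb_end_min
    expect_equal(sum(inside), 0L)
    # MAP monitoring continues through bypass
    maps <- m[m$case_id == cid & m$variable == "MAP", ]
    expect_gt(sum(maps$t_min > row$cpb_start_min &
                    maps$t_min < row$cpb_end_min), 0L)
  }
})

test_that("the micro case collapses to zero TVI values without its MAC
           stream", {
  mc <- generate_worked_micro_case()
  no_mac <- mc$measurements[mc$measurements$variable != "SEVOFLURANE", ]
  prof <- assemble_profiles(prepare_stream(no_mac)$stream,
                            stats = fit_population_stats(
                              prepare_stream(mc$measurements)$stream))
  expect_equal(prof$excluded$case_id, "MICRO1")
  expect_equal(nrow(prof$spans), 0L)
})

test_that("invalid specs fail before any output", {
  expect_error(cohort_spec(n_cases = 0), "n_cases")
  expect_error(cohort_spec(map_sd = -1), "SDs")
  expect_error(cohort_spec(artifact_rate = 1.5), "probabilities")
  expect_error(cohort_spec(rho_bis = 0.9, drift_bis = 0.9), "rho")
})
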