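test_that("worked absence-event fixtures follow the definition", {
  # event at the FIRST visit of the earliest consecutive-zero pair
  r <- event_time_to_absence(c(0, 4, 8, 12, 16), c(3, 1, 0, 0, 2))
  expect_equal(r$status, "event")
  expect_equal(r$time, 8)
  # isolated zeros never qualify: censored at the last visit
  r <- event_time_to_absence(seq(0, 48, 4),
                             c(2, 0, 1, 0, 1, 2, 1, 1, 2, 1, 1, 0, 1))
  expect_equal(r$status, "censored")
  expect_equal(r$time, 48)
  # zero at baseline and week 4: event on/before baseline, excluded
  r <- event_time_to_absence(c(0, 4, 8), c(0, 0, 1))
  expect_equal(r$status, "excluded")
  # single-visit series: censored at that visit
  r <- event_time_to_absence(4, 2)
  expect_equal(r$status, "censored")
  expect_equal(r$time, 4)
})

test_that("event definition matches the exhaustive scan oracle", {
  for (len in 2:6) {
    weeks <- seq(0, by = 4, length.out = len)
    for (code in 0:(2^len - 1)) {
      counts <- as.integer(intToBits(code))[1:len]  # 0/1 count patterns
      got <- event_time_to_absence(weeks, counts)
      want <- scan_absence_oracle(weeks, counts)
      expect_equal(got$status, want$status,
                   info = paste("pattern", paste(counts, collapse = "")))
      if (want$status != "excluded")
        expect_equal(got$time, want$time)
    }
  }
})

test_that("KM estimate equals the hand product-limit computation", {
  km <- km_estimate(c(1, 2, 3), c(1, 0, 1))
  sm <- summary(km$fit, times = c(1, 3))
  expect_equal(sm$surv[1], 2 / 3, tolerance = 1e-12)
  expect_equal(sm$surv[2], 0, tolerance = 1e-12)
})

test_that("KM matches brute-force product-limit on random fixtures", {
  set.seed(17)
  for (k in 1:10) {
    n <- sample(10:50, 1)
    time <- sample(seq(4, 48, 4), n, replace = TRUE)
    event <- rbinom(n, 1, 0.6)
    km <- km_estimate(time, event)
    oracle <- brute_force_km(time, event)
    sm <- summary(km$fit, times = oracle$time)
    expect_equal(sm$surv, oracle$surv, tolerance = 1e-12)
  }
})

test_that("with no events the curve stays at 1 and percentiles are not reached", {
  km <- km_estimate(rep(48, 20), rep(0, 20))
  expect_true(all(km$fit$surv == 1))
  expect_true(all(is.na(km$percentiles$time_weeks)))
})

test_that("percentiles use the earliest time with incidence >= p", {
  # 4 subjects, events at 4 and 8 -> incidence 0.25 at week 4, 0.5 at week 8
  km <- km_estimate(c(4, 8, 48, 48), c(1, 1, 0, 0))
  expect_equal(km$percentiles$time_weeks[km$percentiles$percentile == 0.25], 4)
  expect_equal(km$percentiles$time_weeks[km$percentiles$percentile == 0.50], 8)
})

test_that("single-stratum Cox equals the unstratified fit", {
  set.seed(3)
  d <- rbind(
    data.frame(arm = "aflibercept_q8w", simulate_grid_events(100, 0.05)),
    data.frame(arm = "faricimab_q8w", simulate_grid_events(100, 0.09)))
  d$bcva_stratum <- ">=64"; d$prior_anti_vegf <- "no"
  d$region_stratum <- "asia"
  strat <- stratified_cox(d)
  unstrat <- stratified_cox(d, strata_cols = character(0))
  expect_equal(strat$contrasts$hr, unstrat$contrasts$hr, tolerance = 1e-8)
})

test_that("identical event processes give an HR whose CI covers 1", {
  set.seed(11)
  d <- rbind(
    data.frame(arm = "aflibercept_q8w", simulate_grid_events(1000, 0.05)),
    data.frame(arm = "faricimab_q8w", simulate_grid_events(1000, 0.05)))
  d$bcva_stratum <- sample(c("<64", ">=64"), 2000, replace = TRUE)
  d$prior_anti_vegf <- sample(c("yes", "no"), 2000, replace = TRUE)
  d$region_stratum <- sample(c("us_canada", "asia", "rest_of_world"), 2000,
                             replace = TRUE)
  fit <- stratified_cox(d)
  expect_lt(fit$contrasts$lower, 1)
  expect_gt(fit$contrasts$upper, 1)
})

test_that("absence_events excludes baseline-zero patients and keeps strata", {
  spec <- trajectory_spec(p_zero_baseline = 0.5, dropout_p = 0)
  tr <- generate_trial(spec, 20, seed = 31)
  ev <- absence_events(tr)
  expect_gt(attr(ev, "n_excluded"), 0)
  expect_equal(attr(ev, "n_excluded") + nrow(ev),
               length(unique(tr$patient_id)))
  expect_true(all(c("bcva_stratum", "prior_anti_vegf", "region_stratum")
                  %in% names(ev)))
})
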