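test_that("trial generation is deterministic for a fixed seed", {
  spec <- trajectory_spec()
  a <- generate_trial(spec, 5, seed = 42)
  b <- generate_trial(spec, 5, seed = 42)
  expect_identical(as.data.frame(a), as.data.frame(b))
})

test_that("zero arm separation and zero noise give identical arm means", {
  vols <- trajectory_spec()$volumes
  for (e in names(vols)) vols[[e]]$wk48[] <- vols[[e]]$wk48[["aflibercept_q8w"]]
  spec <- trajectory_spec(volumes = vols, noise_sd = 0, dropout_p = 0,
                          p_zero_baseline = 0)
  tr <- generate_trial(spec, 10, seed = 1)
  agg <- aggregate(vol_inner_r1_pl ~ arm + visit_week, data = tr, FUN = mean)
  for (w in unique(agg$visit_week)) {
    m <- agg$vol_inner_r1_pl[agg$visit_week == w]
    expect_lt(diff(range(m)), 1e-9)
  }
})

test_that("early-rise amplitude 0.25 puts the noise-free week-8 mean at 1.25x baseline", {
  spec <- trajectory_spec(noise_sd = 0, dropout_p = 0, p_zero_baseline = 0)
  expect_equal(trajectory_mean(spec, "aflibercept_q8w", "inner_r1", 8),
               1.25 * 250)
  tr <- generate_trial(spec, 4, seed = 2)
  w8 <- tr$vol_inner_r1_pl[tr$visit_week == 8]
  expect_true(all(abs(w8 - 1.25 * 250) < 1e-9))
})

test_that("the dataset satisfies the trial-table invariants", {
  tr <- generate_trial(trajectory_spec(), 20, seed = 7)
  key <- paste(tr$patient_id, tr$visit_week)
  expect_false(any(duplicated(key)))
  expect_length(attr(tr, "no_baseline"), 0)  # week 0 always observed
  expect_true(all(tr$visit_week <= tr$last_week))
  expect_true(all(tr$bcva_stratum %in% c("<64", ">=64")))
  expect_true(all((tr$bcva_baseline < 64) == (tr$bcva_stratum == "<64")))
})

test_that("counts become zero exactly from the absorbing HRF-free visit", {
  spec <- trajectory_spec(p_zero_ref = 0.3, dropout_p = 0,
                          p_zero_baseline = 0)
  tr <- generate_trial(spec, 15, seed = 9)
  for (pid in unique(tr$patient_id)) {
    cts <- tr$count_inner_r1[tr$patient_id == pid]
    z <- which(cts == 0)
    if (length(z) > 0)
      expect_equal(z, seq(z[1], length(cts)))   # zeros form a terminal run
  }
})

test_that("non-positive-definite residual correlation is rejected", {
  K <- 13
  bad <- matrix(0.99, K, K); diag(bad) <- 1; bad[1, 2] <- bad[2, 1] <- -0.99
  expect_error(trajectory_spec(resid_cor = "unstructured",
                               resid_cor_matrix = bad),
               "positive definite")
})

test_that("grid event simulator matches the geometric distribution", {
  set.seed(5)
  d <- simulate_grid_events(4000, p = 0.1)
  # P(T = week 4k) = (1-p)^(k-1) p; compare empirical vs theoretical CDF
  k <- d$time[d$event == 1] / 4
  emp <- mean(d$event == 1 & d$time <= 12)
  theo <- 1 - (1 - 0.1)^3
  expect_lt(abs(emp - theo), 0.02)
})
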