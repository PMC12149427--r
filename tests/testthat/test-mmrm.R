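# Reduced 12-weekly visit grid keeps the covariance small in unit tests;
# the full 4-weekly grid is exercised in the end-to-end pipeline test.
short_spec <- function(...) {
  trajectory_spec(visit_weeks = seq(0, 48, 12), dropout_p = 0,
                  p_zero_baseline = 0, ...)
}

test_that("noiseless balanced data reproduce the planted means exactly", {
  spec <- short_spec(noise_sd = 0)
  tr <- generate_trial(spec, 6, seed = 1)
  fit <- fit_mmrm(tr, "vol_inner_r1_pl")
  expect_true(fit$degenerate)
  for (i in seq_len(nrow(fit$adjusted_means))) {
    am <- fit$adjusted_means[i, ]
    expect_equal(am$estimate,
                 trajectory_mean(spec, as.character(am$arm), "inner_r1",
                                 am$week),
                 tolerance = 1e-9)
  }
  # contrasts at week 48 equal the planted differences
  ct <- fit$contrasts[fit$contrasts$week == 48, ]
  expect_equal(sort(ct$estimate), sort(c(104.1 - 180.3, 110.1 - 180.3)),
               tolerance = 1e-9)
})

test_that("the unstructured fit returns a valid covariance and CIs", {
  spec <- short_spec(noise_sd = 0.4)
  tr <- generate_trial(spec, 40, seed = 2)
  fit <- fit_mmrm(tr, "vol_inner_r1_pl", covariance = "unstructured")
  expect_true(fit$converged)
  expect_equal(fit$covariance_used, "unstructured")
  v <- fit$covariance
  expect_equal(dim(v), c(4, 4))
  expect_equal(v, t(v), tolerance = 1e-8)
  expect_true(all(eigen(v, symmetric = TRUE,
                        only.values = TRUE)$values > -1e-8))
  am <- fit$adjusted_means
  expect_true(all(am$lower <= am$estimate & am$estimate <= am$upper))
  ct <- fit$contrasts
  expect_true(all(ct$lower <= ct$estimate & ct$estimate <= ct$upper))
})

test_that("adjusted means are invariant to patient relabelling", {
  spec <- short_spec(noise_sd = 0.4)
  tr <- generate_trial(spec, 25, seed = 3)
  fit1 <- fit_mmrm(tr, "vol_inner_r1_pl", covariance = "exchangeable")
  shuffled <- as.data.frame(tr)
  shuffled$arm <- as.character(shuffled$arm)
  ids <- unique(shuffled$patient_id)
  set.seed(4)
  remap <- setNames(sprintf("Q%04d", sample(seq_along(ids))), ids)
  shuffled$patient_id <- unname(remap[shuffled$patient_id])
  fit2 <- fit_mmrm(validate_trial_table(shuffled), "vol_inner_r1_pl",
                   covariance = "exchangeable")
  o1 <- fit1$adjusted_means[order(fit1$adjusted_means$arm,
                                  fit1$adjusted_means$week), ]
  o2 <- fit2$adjusted_means[order(fit2$adjusted_means$arm,
                                  fit2$adjusted_means$week), ]
  expect_equal(o1$estimate, o2$estimate, tolerance = 1e-8)
})

test_that("unit rescaling scales the adjusted means exactly (pL vs um^3)", {
  spec <- short_spec(noise_sd = 0.4)
  tr <- generate_trial(spec, 25, seed = 5)
  df <- as.data.frame(tr); df$arm <- as.character(df$arm)
  df$vol_um3 <- df$vol_inner_r1_pl * 1000   # 1 pL = 1000 um^3
  fit_pl <- fit_mmrm(validate_trial_table(df), "vol_inner_r1_pl",
                     covariance = "exchangeable")
  fit_um <- fit_mmrm(validate_trial_table(df), "vol_um3",
                     covariance = "exchangeable")
  expect_equal(fit_um$adjusted_means$estimate,
               1000 * fit_pl$adjusted_means$estimate, tolerance = 1e-6)
  expect_equal(fit_um$contrasts$p, fit_pl$contrasts$p, tolerance = 1e-8)
})

test_that("patients without a baseline value are excluded from the fit", {
  spec <- short_spec(noise_sd = 0.4)
  tr <- generate_trial(spec, 10, seed = 6)
  df <- as.data.frame(tr); df$arm <- as.character(df$arm)
  drop_pid <- df$patient_id[1]
  df <- df[!(df$patient_id == drop_pid & df$visit_week == 0), ]
  suppressWarnings(ds <- validate_trial_table(df))
  fit <- fit_mmrm(ds, "vol_inner_r1_pl", covariance = "exchangeable")
  expect_equal(fit$n_patients, 29)
})

test_that("print, coef and plot methods run", {
  spec <- short_spec(noise_sd = 0.4)
  tr <- generate_trial(spec, 10, seed = 7)
  fit <- fit_mmrm(tr, "vol_inner_r1_pl", covariance = "exchangeable")
  expect_output(print(fit), "adjusted means at week 48")
  cf <- coef(fit)
  expect_equal(nrow(cf), 3)
  f <- withr::local_tempfile(fileext = ".png")
  grDevices::png(f); plot(fit); grDevices::dev.off()
  expect_true(file.exists(f))
})
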