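test_that("an object-free spec yields an empty mask and truth table", {
  g <- small_geometry(n_bscans = 5L)
  ph <- generate_phantom(phantom_spec(g, n_hrf = 0, n_oversized = 0,
                                      n_undersized = 0, seed = 1))
  expect_true(all(ph$mask == 0L))
  expect_equal(nrow(ph$truth), 0)
})

test_that("truth table rows carry the planted size classes", {
  g <- small_geometry()
  ph <- generate_phantom(phantom_spec(g, n_hrf = 5, n_oversized = 2,
                                      n_undersized = 0, seed = 2))
  expect_equal(nrow(ph$truth), 7)
  expect_equal(sum(ph$truth$size_class == "oversized"), 2)
  expect_equal(sum(ph$truth$size_class == "hrf"), 5)
})

test_that("generation is deterministic for a fixed seed", {
  g <- small_geometry()
  spec <- phantom_spec(g, n_hrf = 6, n_oversized = 1, n_undersized = 1,
                       noise_sd = 4, seed = 99)
  a <- generate_phantom(spec)
  b <- generate_phantom(spec)
  expect_identical(a$mask, b$mask)
  expect_identical(a$intensity, b$intensity)
  expect_identical(a$truth, b$truth)
})

test_that("planted objects lie between the ILM and the RPE", {
  g <- small_geometry()
  ph <- generate_phantom(phantom_spec(g, n_hrf = 10, n_oversized = 2,
                                      n_undersized = 2, seed = 13))
  for (k in seq_len(nrow(ph$truth))) {
    s <- surfaces_at(ph$surfaces, ph$truth$bscan[k], ph$truth$ascan[k])
    expect_gt(ph$truth$z_um[k], s[["ilm"]])
    expect_lt(ph$truth$z_um[k], s[["rpe"]])
  }
})

test_that("planted mask voxels render at RPE-band reflectivity", {
  g <- small_geometry()
  ph <- generate_phantom(phantom_spec(g, n_hrf = 4, seed = 3, noise_sd = 0))
  expect_true(all(ph$intensity[ph$mask == 1L] == 220))
})

test_that("turbidity masking removes the stated fraction of voxels", {
  g <- small_geometry(n_bscans = 3L)
  cyst <- data.frame(bscan = 1L, ascan = 80, z_um = 230,
                     radius_ascan = 60, radius_um = 120, turbidity = 0)
  mask <- array(0L, c(3, 120, 160))
  set.seed(4)
  mask[2, 40:80, 30:130] <- rbinom(41 * 101, 1, 0.5)
  n0 <- sum(mask)
  # probability 0: unchanged
  expect_identical(degrade_with_turbidity(mask, cyst, g, seed = 1), mask)
  # probability 1: nothing inside the cyst survives
  cyst$turbidity <- 1
  m1 <- degrade_with_turbidity(mask, cyst, g, seed = 1)
  inside <- hrfoct:::cyst_pixels(cyst, g)
  expect_equal(sum(m1[cbind(2L, inside$depth + 1L, inside$ascan + 1L)]), 0)
  # probability 0.5: removed fraction within +-0.05 (binomial check)
  cyst$turbidity <- 0.5
  m5 <- degrade_with_turbidity(mask, cyst, g, seed = 2)
  idx <- cbind(2L, inside$depth + 1L, inside$ascan + 1L)
  was_on <- sum(mask[idx])
  removed <- was_on - sum(m5[idx])
  expect_gt(was_on, 500)                    # enough voxels for the check
  expect_lt(abs(removed / was_on - 0.5), 0.05)
})
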