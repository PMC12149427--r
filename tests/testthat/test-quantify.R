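test_that("connectivity controls whether corner-touching pixels merge", {
  g <- small_geometry(n_bscans = 1L, depth_px = 10L, n_ascans = 10L)
  mask <- array(0L, c(1, 10, 10))
  mask[1, 3, 3] <- 1L; mask[1, 4, 4] <- 1L   # share only a corner
  expect_length(extract_components(mask, 0, quant_config(connectivity = 8)), 1)
  expect_length(extract_components(mask, 0, quant_config(connectivity = 4)), 2)
  expect_length(extract_components(array(0L, c(1, 10, 10)), 0), 0)
})

test_that("component sizes conserve the number of set pixels", {
  set.seed(19)
  for (k in 1:5) {
    mask <- array(rbinom(1 * 40 * 40, 1, 0.25), c(1, 40, 40))
    for (conn in c(4L, 8L)) {
      comps <- extract_components(mask, 0, quant_config(connectivity = conn))
      expect_equal(sum(vapply(comps, nrow, integer(1))), sum(mask))
      # components are disjoint
      all_px <- do.call(rbind, comps)
      expect_false(any(duplicated(all_px)))
    }
  }
})

test_that("4-connected labelling agrees with EBImage::bwlabel", {
  skip_if_not_installed("EBImage")
  set.seed(23)
  for (k in 1:3) {
    m <- matrix(rbinom(50 * 60, 1, 0.3), 50, 60)
    mask <- array(m, c(1, 50, 60))
    comps <- extract_components(mask, 0, quant_config(connectivity = 4))
    lab <- EBImage::bwlabel(m)
    expect_equal(length(comps), max(lab))
    # identical partition: each of our components maps to one bwlabel id
    ids <- vapply(comps, function(cp)
      length(unique(lab[cbind(cp$depth + 1L, cp$ascan + 1L)])), integer(1))
    expect_true(all(ids == 1L))
  }
})

test_that("size classification is inclusive at both window boundaries", {
  cfg <- quant_config()
  expect_equal(classify_object(50, cfg), "hrf")
  expect_equal(classify_object(50.1, cfg), "oversized")
  expect_equal(classify_object(20, cfg), "hrf")
  expect_equal(classify_object(19, cfg), "undersized")
})

test_that("ring assignment uses cumulative inclusive discs", {
  cfg <- quant_config()
  expect_equal(assign_region(0.4, cfg), "R1")
  expect_equal(assign_region(0.5, cfg), "R1")
  expect_equal(assign_region(1.2, cfg), "R3")
  expect_equal(assign_region(1.5, cfg), "R3")
  expect_equal(assign_region(2.0, cfg), "outside")
})

test_that("the OPL-HFL boundary belongs to the inner retina", {
  s <- c(ilm = 100, oplhfl = 250, rpe = 350)
  expect_equal(assign_compartment(250, s), "inner")
  expect_equal(assign_compartment(251, s), "outer")
  expect_equal(assign_compartment(99, s), NA_character_)   # above ILM
  expect_equal(assign_compartment(351, s), NA_character_)  # below RPE
})

test_that("objects outside the retina are excluded and QC-counted", {
  g <- small_geometry(n_bscans = 1L, depth_px = 120L, n_ascans = 160L)
  s <- flat_surfaces(g)
  mask <- array(0L, c(1, 120, 160))
  mask[1, 5:8, 80:82] <- 1L          # z about 15-27 um: above the ILM
  expect_warning(q <- quantify_volume(mask, s, g), "outside ILM-RPE")
  expect_equal(nrow(q$objects), 0)
  expect_equal(q$qc$outside_retina, 1)
})

test_that("volume follows area x B-scan spacing in picoliters", {
  # 10 pixels at 11.5 x 3.87 um with 62 um spacing:
  # 10 * 44.505 * 62 = 27593.1 um^3 = 27.5931 pL
  g <- small_geometry()
  s <- flat_surfaces(g)
  mask <- array(0L, c(25, 120, 160))
  mask[13, 40:44, 80:81] <- 1L       # 5 x 2 block of 10 pixels
  q <- quantify_volume(mask, s, g)
  expect_equal(nrow(q$objects), 1)
  expect_equal(q$objects$volume_pl, 27.5931, tolerance = 1e-10)
  tot <- q$summary[q$summary$region == "R1" &
                     q$summary$compartment == "total", ]
  expect_equal(tot$hrf_volume_pl, 27.5931, tolerance = 1e-10)
})

test_that("an empty mask summarises to all-zero counts and volumes", {
  g <- small_geometry(n_bscans = 3L)
  q <- quantify_volume(array(0L, c(3, 120, 160)), flat_surfaces(g), g)
  expect_true(all(q$summary$hrf_count == 0))
  expect_true(all(q$summary$hrf_volume_pl == 0))
})

test_that("inner + outer = total and R3 >= R1 on random phantoms", {
  g <- small_geometry()
  for (s in 1:5) {
    ph <- generate_phantom(phantom_spec(g, n_hrf = 10, seed = 100 + s))
    q <- quantify_volume(ph$mask, ph$surfaces, ph$geometry)
    sm <- q$summary
    for (ring in c("R1", "R3")) {
      r <- sm[sm$region == ring, ]
      for (col in c("hrf_count", "hrf_volume_pl")) {
        expect_equal(r[[col]][r$compartment == "total"],
                     r[[col]][r$compartment == "inner"] +
                       r[[col]][r$compartment == "outer"])
      }
    }
    for (comp in c("inner", "outer", "total")) {
      expect_gte(sm$hrf_count[sm$region == "R3" & sm$compartment == comp],
                 sm$hrf_count[sm$region == "R1" & sm$compartment == comp])
    }
  }
})

test_that("adding a voxel never decreases any count or volume", {
  g <- small_geometry()
  s <- flat_surfaces(g)
  set.seed(31)
  ph <- generate_phantom(phantom_spec(g, n_hrf = 6, seed = 8))
  q0 <- quantify_volume(ph$mask, ph$surfaces, g)
  mask2 <- ph$mask
  # add one voxel adjacent to an existing object (grows it)
  obj <- q0$objects[1, ]
  b <- obj$bscan + 1L
  i <- which(mask2[b, , ] == 1L, arr.ind = TRUE)[1, ]
  mask2[b, i[1] + 1L, i[2]] <- 1L
  q1 <- quantify_volume(mask2, ph$surfaces, g)
  expect_true(all(q1$summary$hrf_count >= q0$summary$hrf_count))
  expect_true(all(q1$summary$hrf_volume_pl >=
                    q0$summary$hrf_volume_pl - 1e-12))
})

test_that("annulus mode splits the 3-mm disc into a 1-3 mm ring", {
  g <- small_geometry()
  ph <- generate_phantom(phantom_spec(g, n_hrf = 12, seed = 77))
  q_cum <- quantify_volume(ph$mask, ph$surfaces, g,
                           quant_config(ring_mode = "cumulative"))
  q_ann <- quantify_volume(ph$mask, ph$surfaces, g,
                           quant_config(ring_mode = "annulus"))
  for (comp in c("inner", "outer", "total")) {
    cum3 <- q_cum$summary$hrf_count[q_cum$summary$region == "R3" &
                                      q_cum$summary$compartment == comp]
    ann3 <- q_ann$summary$hrf_count[q_ann$summary$region == "R3" &
                                      q_ann$summary$compartment == comp]
    r1 <- q_cum$summary$hrf_count[q_cum$summary$region == "R1" &
                                    q_cum$summary$compartment == comp]
    expect_equal(cum3, ann3 + r1)
  }
})

test_that("the intensity-threshold detector recovers planted objects", {
  g <- small_geometry()
  ph <- generate_phantom(phantom_spec(g, n_hrf = 5, seed = 21,
                                      noise_sd = 0))
  det <- detect_candidates(ph$intensity, ph$surfaces, g)
  q <- quantify_volume(det, ph$surfaces, g)
  expect_equal(nrow(q$objects), 5)
  # all-background volume gives an empty mask
  ph0 <- generate_phantom(phantom_spec(g, n_hrf = 0, n_oversized = 0,
                                       n_undersized = 0, seed = 1))
  det0 <- detect_candidates(ph0$intensity, ph0$surfaces, g)
  expect_equal(sum(det0), 0)
})
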