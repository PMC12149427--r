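# Shared fixtures and independent oracles.

trial_regions_for_tests <- c("us_canada", "asia", "rest_of_world")

small_geometry <- function(n_bscans = 25L, depth_px = 120L, n_ascans = 160L,
                           axial_px_um = 3.87, lateral_px_um = 11.5,
                           bscan_spacing_um = 62) {
  scan_geometry(n_bscans = n_bscans, depth_px = depth_px,
                n_ascans = n_ascans, axial_px_um = axial_px_um,
                lateral_px_um = lateral_px_um,
                bscan_spacing_um = bscan_spacing_um)
}

flat_surfaces <- function(geometry, ilm = 100, oplhfl = 250, rpe = 350) {
  nb <- geometry$n_bscans; na <- geometry$n_ascans
  layer_surfaces(matrix(ilm, nb, na), matrix(oplhfl, nb, na),
                 matrix(rpe, nb, na))
}

# Brute-force second-central-moment ellipse: explicit double loop over
# pixels in physical coordinates. Independent of fit_ellipse's vectorised
# implementation.
brute_force_ellipse <- function(component, geometry) {
  lat <- geometry$lateral_px_um; ax <- geometry$axial_px_um
  n <- nrow(component)
  sx <- 0; sz <- 0
  for (i in seq_len(n)) {
    sx <- sx + component$ascan[i] * lat
    sz <- sz + component$depth[i] * ax
  }
  mx <- sx / n; mz <- sz / n
  sxx <- 0; szz <- 0; sxz <- 0
  for (i in seq_len(n)) {
    dx <- component$ascan[i] * lat - mx
    dz <- component$depth[i] * ax - mz
    sxx <- sxx + dx * dx; szz <- szz + dz * dz; sxz <- sxz + dx * dz
  }
  mxx <- sxx / n + lat^2 / 12
  mzz <- szz / n + ax^2 / 12
  mxz <- sxz / n
  ev <- eigen(matrix(c(mxx, mxz, mxz, mzz), 2, 2), symmetric = TRUE)$values
  list(major = 4 * sqrt(ev[1]), minor = 4 * sqrt(max(0, ev[2])))
}

# random connected pixel blob grown from a seed pixel
random_component <- function(n_px, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  px <- matrix(c(50L, 50L), 1, 2)
  while (nrow(px) < n_px) {
    base <- px[sample.int(nrow(px), 1), ]
    step <- sample(c(-1L, 0L, 1L), 2, replace = TRUE)
    cand <- base + step
    if (!any(px[, 1] == cand[1] & px[, 2] == cand[2]))
      px <- rbind(px, cand)
  }
  data.frame(depth = px[, 1], ascan = px[, 2])
}

# product-limit estimator by direct computation
brute_force_km <- function(time, event) {
  tt <- sort(unique(time[event == 1]))
  s <- 1
  out <- numeric(length(tt))
  for (k in seq_along(tt)) {
    at_risk <- sum(time >= tt[k])
    d <- sum(time == tt[k] & event == 1)
    s <- s * (1 - d / at_risk)
    out[k] <- s
  }
  data.frame(time = tt, surv = out)
}

# exhaustive scan for the consecutive-zero event definition
scan_absence_oracle <- function(weeks, counts) {
  for (i in seq_len(length(weeks) - 1)) {
    if (counts[i] == 0 && counts[i + 1] == 0) {
      if (weeks[i] <= 0) return(list(status = "excluded"))
      return(list(status = "event", time = weeks[i]))
    }
  }
  list(status = "censored", time = weeks[length(weeks)])
}

# rasterised disc: pixel centers inside a circle of radius r_um
disc_component <- function(r_um, px_um) {
  half <- ceiling(r_um / px_um) + 2
  g <- expand.grid(depth = -half:half, ascan = -half:half)
  keep <- (g$depth * px_um)^2 + (g$ascan * px_um)^2 <= r_um^2
  d <- g[keep, ]
  d$depth <- d$depth + half + 1L; d$ascan <- d$ascan + half + 1L
  d
}
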