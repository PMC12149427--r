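#' Specification of a synthetic OCT phantom
#'
#' A phantom is a volume with known ground truth: layered background
#' reflectivity, a foveal pit, planted elliptical hyperreflective objects
#' rendered at RPE-band reflectivity, optional hyporeflective (possibly
#' turbid) cysts, and additive Gaussian noise. Planted objects live on a
#' single B-scan each, matching the per-B-scan object definition used by the
#' quantification stage.
#'
#' Objects are described in physical coordinates: en-face center as an
#' offset from the fovea in millimetres, axial center in micrometres from the
#' volume top, major/minor axes in micrometres, orientation in radians
#' (in the B-scan plane, 0 = lateral). `n_hrf`, `n_oversized` and
#' `n_undersized` objects are drawn uniformly within the geometry, sized
#' inside, above and below the HRF diameter window respectively; explicit
#' objects can be given instead via `objects`.
#'
#' @param geometry A [scan_geometry].
#' @param n_hrf,n_oversized,n_undersized Counts of randomly placed objects
#'   with long axis inside `[size_window[1], size_window[2]]` um, above, and
#'   below it.
#' @param objects Optional data.frame overriding random placement, with
#'   columns `bscan`, `ascan` (0-based, fractional allowed), `z_um`,
#'   `major_um`, `minor_um`, `theta`.
#' @param size_window HRF diameter window in micrometres (default 20-50).
#' @param cysts Optional data.frame of hyporeflective cysts: columns `bscan`,
#'   `ascan`, `z_um`, `radius_ascan` (lateral semi-axis, A-scans),
#'   `radius_um` (axial semi-axis, um), `turbidity` in `[0,1]`.
#' @param noise_sd Additive Gaussian noise SD on the 0-255 intensity scale.
#' @param pit_depth_um,pit_width_mm Foveal pit depth and Gaussian half-width.
#' @param seed Integer seed; a fixed seed makes generation byte-identical.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(geometry,
                         n_hrf = 10L, n_oversized = 0L, n_undersized = 0L,
                         objects = NULL,
                         size_window = c(20, 50),
                         cysts = NULL,
                         noise_sd = 0,
                         pit_depth_um = 100, pit_width_mm = 0.75,
                         seed = 1L) {
  stopifnot(inherits(geometry, "scan_geometry"),
            size_window[1] > 0, size_window[1] < size_window[2],
            noise_sd >= 0)
  structure(list(geometry = geometry, n_hrf = as.integer(n_hrf),
                 n_oversized = as.integer(n_oversized),
                 n_undersized = as.integer(n_undersized),
                 objects = objects, size_window = size_window, cysts = cysts,
                 noise_sd = noise_sd, pit_depth_um = pit_depth_um,
                 pit_width_mm = pit_width_mm, seed = as.integer(seed)),
            class = "phantom_spec")
}

# background band levels on the 0-255 scale; RPE band is the bright
# reference against which both planted objects and the stand-in detector
# are calibrated
.phantom_levels <- list(vitreous = 30, inner = 95, outer = 80, rpe = 220,
                        choroid = 55, cyst = 35)

# analytic layer surfaces for the phantom: flat RPE, foveal pit on the ILM
phantom_surfaces <- function(spec) {
  g <- spec$geometry
  nb <- g$n_bscans; na <- g$n_ascans
  bs <- matrix(rep(seq_len(nb) - 1L, na), nb, na)
  as_ <- matrix(rep(seq_len(na) - 1L, each = nb), nb, na)
  dx <- (as_ - g$fovea_center[2]) * g$lateral_px_um / 1000
  dy <- (bs - g$fovea_center[1]) * g$bscan_spacing_um / 1000
  r2 <- dx^2 + dy^2
  depth_um <- g$depth_px * g$axial_px_um
  rpe <- matrix(0.72 * depth_um, nb, na)
  ilm_flat <- 0.28 * depth_um
  ilm <- ilm_flat + spec$pit_depth_um * exp(-r2 / (2 * spec$pit_width_mm^2))
  opl <- rpe - 0.35 * (rpe - ilm)   # OPL-HFL at 35% of retinal thickness above RPE
  layer_surfaces(ilm, opl, rpe)
}

#' Generate a synthetic OCT phantom with known HRF ground truth
#'
#' Rasterises every planted object as a filled ellipse on its B-scan (a pixel
#' belongs to the object iff its center lies inside the continuous ellipse),
#' builds the matching layered intensity volume (objects rendered at RPE-band
#' reflectivity), and returns a truth table with per-object true axes,
#' rasterised pixel area, size class, ETDRS region and retinal compartment.
#'
#' @param spec A [phantom_spec].
#' @return A list with elements `mask` (0/1 array `(bscan, depth, width)`),
#'   `intensity` (0-255 array), `surfaces` ([layer_surfaces]), `truth`
#'   (data.frame, one row per planted object) and `geometry`.
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  g <- spec$geometry
  set.seed(spec$seed)
  surf <- phantom_surfaces(spec)

  obj <- spec$objects
  if (is.null(obj)) {
    n_tot <- spec$n_hrf + spec$n_oversized + spec$n_undersized
    obj <- if (n_tot > 0) random_objects(spec, surf) else empty_objects()
  }
  obj <- as.data.frame(obj)

  mask <- array(0L, c(g$n_bscans, g$depth_px, g$n_ascans))
  truth <- empty_truth()
  if (nrow(obj) > 0) {
    for (k in seq_len(nrow(obj))) {
      px <- rasterize_ellipse(obj[k, ], g)
      if (nrow(px) == 0)
        stop(sprintf("planted object %d rasterises to zero pixels", k),
             call. = FALSE)
      if (any(px$depth < 0) || any(px$depth >= g$depth_px) ||
          any(px$ascan < 0) || any(px$ascan >= g$n_ascans))
        stop(sprintf("planted object %d collides with the volume boundary", k),
             call. = FALSE)
      mask[cbind(obj$bscan[k] + 1L, px$depth + 1L, px$ascan + 1L)] <- 1L
      truth <- rbind(truth, truth_row(k, obj[k, ], nrow(px), g, surf, spec))
    }
  }

  intensity <- render_intensity(mask, surf, spec)
  list(mask = mask, intensity = intensity, surfaces = surf,
       truth = truth, geometry = g)
}

empty_objects <- function() {
  data.frame(bscan = integer(), ascan = numeric(), z_um = numeric(),
             major_um = numeric(), minor_um = numeric(), theta = numeric())
}

empty_truth <- function() {
  data.frame(object_id = integer(), bscan = integer(), ascan = numeric(),
             z_um = numeric(), major_um = numeric(), minor_um = numeric(),
             theta = numeric(), size_class = character(),
             region = character(), compartment = character(),
             area_px = integer(), area_um2 = numeric(),
             volume_pl = numeric(), enface_dist_mm = numeric())
}

# Draw objects uniformly over the volume, spaced so that distinct objects
# cannot merge into one component. Centers are snapped to pixel centers and
# long axes are drawn with a margin away from the classification boundaries
# (HRF well inside the window, distractors well outside), so that the
# rasterised size class always matches the planted class: moment estimates
# on the anisotropic grid carry up to about one lateral pixel of
# discretisation error, which must not straddle the 20/50 um cuts.
random_objects <- function(spec, surf) {
  g <- spec$geometry
  w <- spec$size_window
  n_tot <- spec$n_hrf + spec$n_oversized + spec$n_undersized
  sizes <- c(stats::runif(spec$n_hrf, w[1] * 1.25, w[2] * 0.9),
             stats::runif(spec$n_oversized, w[2] * 1.3, w[2] * 2),
             stats::runif(spec$n_undersized, w[1] * 0.4, w[1] * 0.7))
  cls <- rep(c("hrf", "oversized", "undersized"),
             c(spec$n_hrf, spec$n_oversized, spec$n_undersized))
  out <- empty_objects()
  guard_um <- max(sizes) + 3 * max(g$lateral_px_um, g$axial_px_um)
  tries <- 0L
  while (nrow(out) < n_tot && tries < 20000L) {
    tries <- tries + 1L
    k <- nrow(out) + 1L
    major <- sizes[k]
    minor <- stats::runif(1, 0.5 * major, major)
    theta <- stats::runif(1, 0, pi)
    # vertical / lateral half-extents of the tilted ellipse
    h_z <- sqrt((major / 2 * sin(theta))^2 + (minor / 2 * cos(theta))^2)
    h_x <- sqrt((major / 2 * cos(theta))^2 + (minor / 2 * sin(theta))^2)
    b <- sample.int(g$n_bscans, 1L) - 1L
    margin_a <- ceiling(h_x / g$lateral_px_um) + 2L
    if (2L * margin_a + 2L >= g$n_ascans) next
    a <- as.numeric(sample(margin_a:(g$n_ascans - 1L - margin_a), 1L))
    s <- surfaces_at(surf, b, a)
    # whole object inside the retina
    z_lo <- s[["ilm"]] + h_z + 2
    z_hi <- s[["rpe"]] - h_z - 2
    if (!is.finite(z_lo) || !is.finite(z_hi) || z_lo >= z_hi) next
    z <- stats::runif(1, z_lo, z_hi)
    z <- round(z / g$axial_px_um) * g$axial_px_um  # snapped to a pixel center
    # compartment is assigned from the centroid, which rasterisation can
    # shift by under one pixel: keep 2 axial pixels clear of the OPL-HFL
    if (abs(z - s[["oplhfl"]]) < 2 * g$axial_px_um) next
    # likewise keep 0.02 mm clear of the 0.5 / 1.5 mm ring radii
    dxy <- sqrt((((a - g$fovea_center[2]) * g$lateral_px_um) / 1000)^2 +
                (((b - g$fovea_center[1]) * g$bscan_spacing_um) / 1000)^2)
    if (abs(dxy - 0.5) < 0.02 || abs(dxy - 1.5) < 0.02) next
    # reject placements that could touch an existing object on the same B-scan
    same <- out[out$bscan == b, , drop = FALSE]
    if (nrow(same) > 0) {
      d_lat <- abs(same$ascan - a) * g$lateral_px_um
      d_ax <- abs(same$z_um - z)
      if (any(sqrt(d_lat^2 + d_ax^2) < guard_um)) next
    }
    out <- rbind(out, data.frame(bscan = b, ascan = a, z_um = z,
                                 major_um = major, minor_um = minor,
                                 theta = theta))
  }
  if (nrow(out) < n_tot)
    stop("could not place all planted objects without collisions",
         call. = FALSE)
  out$size_class <- cls
  out
}

# pixel-center-in-ellipse rasterisation on one B-scan, physical units
rasterize_ellipse <- function(o, g) {
  lat <- g$lateral_px_um; ax <- g$axial_px_um
  a_um <- o$major_um / 2; b_um <- o$minor_um / 2
  cx <- o$ascan * lat       # pixel index i has center at i * pitch
  cz <- o$z_um
  half_w <- ceiling(a_um / lat) + 1L
  half_h <- ceiling(a_um / ax) + 1L
  ascan <- seq(floor(o$ascan) - half_w, ceiling(o$ascan) + half_w)
  depth <- seq(floor(cz / ax) - half_h, ceiling(cz / ax) + half_h)
  grid <- expand.grid(ascan = ascan, depth = depth)
  x <- grid$ascan * lat - cx
  z <- grid$depth * ax - cz
  ct <- cos(o$theta); st <- sin(o$theta)
  u <- x * ct + z * st
  v <- -x * st + z * ct
  inside <- (u / a_um)^2 + (v / b_um)^2 <= 1
  grid[inside, , drop = FALSE]
}

truth_row <- function(k, o, npx, g, surf, spec) {
  area_um2 <- npx * g$lateral_px_um * g$axial_px_um
  s <- surfaces_at(surf, o$bscan, o$ascan)
  dx <- (o$ascan - g$fovea_center[2]) * g$lateral_px_um / 1000
  dy <- (o$bscan - g$fovea_center[1]) * g$bscan_spacing_um / 1000
  d <- sqrt(dx^2 + dy^2)
  w <- spec$size_window
  cls <- if (!is.null(o$size_class)) o$size_class
         else if (o$major_um < w[1]) "undersized"
         else if (o$major_um > w[2]) "oversized" else "hrf"
  data.frame(object_id = k, bscan = o$bscan, ascan = o$ascan, z_um = o$z_um,
             major_um = o$major_um, minor_um = o$minor_um, theta = o$theta,
             size_class = cls,
             region = if (d <= 0.5) "R1" else if (d <= 1.5) "R3" else "outside",
             compartment = if (o$z_um <= s["oplhfl"]) "inner" else "outer",
             area_px = as.integer(npx), area_um2 = area_um2,
             volume_pl = area_um2 * g$bscan_spacing_um / 1000,
             enface_dist_mm = d)
}

render_intensity <- function(mask, surf, spec) {
  g <- spec$geometry
  lv <- .phantom_levels
  nb <- g$n_bscans; dp <- g$depth_px; na <- g$n_ascans
  z_um <- (seq_len(dp) - 1L) * g$axial_px_um
  intensity <- array(lv$vitreous, c(nb, dp, na))
  for (i in seq_len(nb)) {
    sl <- matrix(lv$vitreous, dp, na)
    ilm <- surf$ilm_z[i, ]; opl <- surf$oplhfl_z[i, ]; rpe <- surf$rpe_z[i, ]
    zi <- matrix(z_um, dp, na)
    ilm_m <- matrix(ilm, dp, na, byrow = TRUE)
    opl_m <- matrix(opl, dp, na, byrow = TRUE)
    rpe_m <- matrix(rpe, dp, na, byrow = TRUE)
    sl[zi >= ilm_m & zi <= opl_m] <- lv$inner
    sl[zi > opl_m & zi < rpe_m] <- lv$outer
    rpe_thick <- 5 * g$axial_px_um
    sl[zi >= rpe_m & zi <= rpe_m + rpe_thick] <- lv$rpe
    sl[zi > rpe_m + rpe_thick] <- lv$choroid
    intensity[i, , ] <- sl
  }
  # cysts: hyporeflective ellipsoids in-plane
  if (!is.null(spec$cysts) && nrow(spec$cysts) > 0) {
    for (k in seq_len(nrow(spec$cysts))) {
      cy <- spec$cysts[k, ]
      idx <- cyst_pixels(cy, g)
      if (nrow(idx) > 0)
        intensity[cbind(cy$bscan + 1L, idx$depth + 1L, idx$ascan + 1L)] <-
          lv$cyst
    }
  }
  intensity[mask == 1L] <- lv$rpe
  if (spec$noise_sd > 0) {
    intensity <- intensity +
      stats::rnorm(length(intensity), 0, spec$noise_sd)
    intensity[intensity < 0] <- 0
    intensity[intensity > 255] <- 255
  }
  intensity
}

cyst_pixels <- function(cy, g) {
  dp <- g$depth_px; na <- g$n_ascans
  depth <- 0:(dp - 1L); ascan <- 0:(na - 1L)
  grid <- expand.grid(ascan = ascan, depth = depth)
  dx <- (grid$ascan - cy$ascan) / cy$radius_ascan
  dz <- (grid$depth * g$axial_px_um - cy$z_um) / cy$radius_um
  grid[dx^2 + dz^2 <= 1, , drop = FALSE]
}

#' Remove mask voxels inside turbid cysts
#'
#' Emulates the masking of hyperreflective material by turbid or hazy
#' intraretinal fluid: every mask voxel lying inside a cyst is removed
#' independently with the cyst's `turbidity` probability. This is an explicit
#' degradation step, never applied silently by [generate_phantom()].
#'
#' @param mask 0/1 array `(bscan, depth, width)`.
#' @param cysts Data.frame as in [phantom_spec()] (columns `bscan`, `ascan`,
#'   `z_um`, `radius_ascan`, `radius_um`, `turbidity`).
#' @param geometry A [scan_geometry].
#' @param seed Optional integer seed for the removal draws.
#' @return The degraded mask.
#' @export
degrade_with_turbidity <- function(mask, cysts, geometry, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(cysts) || nrow(cysts) == 0) return(mask)
  for (k in seq_len(nrow(cysts))) {
    cy <- cysts[k, ]
    idx <- cyst_pixels(cy, geometry)
    if (nrow(idx) == 0) next
    flat <- cbind(cy$bscan + 1L, idx$depth + 1L, idx$ascan + 1L)
    on <- which(mask[flat] == 1L)
    if (length(on) == 0) next
    drop <- on[stats::runif(length(on)) < cy$turbidity]
    if (length(drop) > 0) mask[flat[drop, , drop = FALSE]] <- 0L
  }
  mask
}
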