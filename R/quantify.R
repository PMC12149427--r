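#' Quantification configuration
#'
#' @param min_diameter_um,max_diameter_um HRF long-axis diameter window in
#'   micrometres; the window is inclusive at both ends (an object measuring
#'   exactly 50 um is an HRF, one above 50 um is discarded as oversized).
#' @param connectivity Pixel connectivity for per-B-scan component labelling,
#'   4 or 8 (default 8).
#' @param r1_radius_mm,r3_radius_mm ETDRS ring radii: the central 1-mm
#'   subfield (radius 0.5 mm) and the 3-mm ring (radius 1.5 mm).
#' @param ring_mode `"cumulative"` (default): R3 summaries cover the whole
#'   3-mm disc, so R1 is a subset of R3; `"annulus"`: R3 covers only the
#'   1-3 mm annulus.
#' @return An object of class `quant_config`.
#' @export
quant_config <- function(min_diameter_um = 20, max_diameter_um = 50,
                         connectivity = 8L,
                         r1_radius_mm = 0.5, r3_radius_mm = 1.5,
                         ring_mode = c("cumulative", "annulus")) {
  if (!(min_diameter_um > 0 && min_diameter_um < max_diameter_um))
    stop("need 0 < min_diameter_um < max_diameter_um", call. = FALSE)
  if (!connectivity %in% c(4L, 8L))
    stop("connectivity must be 4 or 8", call. = FALSE)
  if (!(r1_radius_mm > 0 && r1_radius_mm < r3_radius_mm))
    stop("ring radii must be increasing", call. = FALSE)
  structure(list(min_diameter_um = min_diameter_um,
                 max_diameter_um = max_diameter_um,
                 connectivity = as.integer(connectivity),
                 r1_radius_mm = r1_radius_mm, r3_radius_mm = r3_radius_mm,
                 ring_mode = match.arg(ring_mode)),
            class = "quant_config")
}

#' Connected components of one B-scan
#'
#' Objects are defined strictly per B-scan (2-D components); they are never
#' merged across B-scans. Labelling is breadth-first under the configured
#' connectivity.
#'
#' @param mask 0/1 array `(bscan, depth, width)`.
#' @param bscan 0-based B-scan index.
#' @param config A [quant_config] (the connectivity is used).
#' @return List of pixel sets; each a data.frame with 0-based `depth`,
#'   `ascan` columns. Empty list for an empty B-scan.
#' @export
extract_components <- function(mask, bscan, config = quant_config()) {
  if (bscan < 0 || bscan >= dim(mask)[1])
    stop("bscan index out of range", call. = FALSE)
  sl <- mask[bscan + 1L, , , drop = TRUE]
  if (is.null(dim(sl))) sl <- matrix(sl, dim(mask)[2], dim(mask)[3])
  label_components(sl, config$connectivity)
}

# BFS labelling of a binary matrix (rows = depth, cols = ascan).
# Returns list of data.frames with 0-based depth/ascan.
label_components <- function(m, connectivity = 8L) {
  nr <- nrow(m); nc <- ncol(m)
  on <- which(m != 0)
  if (length(on) == 0) return(list())
  lab <- integer(nr * nc)
  if (connectivity == 4L) {
    dr <- c(-1L, 1L, 0L, 0L); dc <- c(0L, 0L, -1L, 1L)
  } else {
    dr <- c(-1L, 1L, 0L, 0L, -1L, -1L, 1L, 1L)
    dc <- c(0L, 0L, -1L, 1L, -1L, 1L, -1L, 1L)
  }
  comps <- list(); ncomp <- 0L
  for (s in on) {
    if (lab[s] != 0L) next
    ncomp <- ncomp + 1L
    queue <- s; lab[s] <- ncomp
    members <- integer(0)
    while (length(queue) > 0) {
      cur <- queue[1]; queue <- queue[-1]
      members <- c(members, cur)
      r0 <- ((cur - 1L) %% nr) + 1L
      c0 <- ((cur - 1L) %/% nr) + 1L
      for (k in seq_along(dr)) {
        r <- r0 + dr[k]; cc <- c0 + dc[k]
        if (r < 1L || r > nr || cc < 1L || cc > nc) next
        idx <- (cc - 1L) * nr + r
        if (m[idx] != 0 && lab[idx] == 0L) {
          lab[idx] <- ncomp
          queue <- c(queue, idx)
        }
      }
    }
    comps[[ncomp]] <- data.frame(
      depth = ((members - 1L) %% nr),
      ascan = ((members - 1L) %/% nr))
  }
  comps
}

#' Equivalent-ellipse fit from second central moments
#'
#' Sizes a pixel component by the ellipse with the same second central
#' moments, computed in physical units on the anisotropic grid
#' (`lateral_px_um` x `axial_px_um`). A per-pixel self-moment of a^2/12 is
#' added on each axis (the variance of a uniform distribution over one pixel
#' side), so a single pixel has finite extent. Axis lengths are
#' `4 * sqrt(eigenvalue)` of the 2x2 moment matrix — for a continuous
#' ellipse these recover the true axis diameters exactly (a disc of radius r
#' has second moment r^2/4, hence major axis 2r).
#'
#' @param component Pixel set (data.frame with 0-based `depth`, `ascan`).
#' @param geometry A [scan_geometry].
#' @return List with `major_axis_um`, `minor_axis_um`, `orientation` (radians
#'   from the lateral axis), `centroid_ascan`, `centroid_z_um`, `n_px`,
#'   `area_um2`.
#' @export
fit_ellipse <- function(component, geometry) {
  n <- nrow(component)
  if (n == 0) stop("empty component", call. = FALSE)
  lat <- geometry$lateral_px_um
  ax <- geometry$axial_px_um
  x <- component$ascan * lat
  z <- component$depth * ax
  mx <- mean(x); mz <- mean(z)
  mxx <- sum((x - mx)^2) / n + lat^2 / 12
  mzz <- sum((z - mz)^2) / n + ax^2 / 12
  mxz <- sum((x - mx) * (z - mz)) / n
  tr <- mxx + mzz
  det_ <- mxx * mzz - mxz^2
  disc <- sqrt(max(0, (tr / 2)^2 - det_))
  l1 <- tr / 2 + disc
  l2 <- tr / 2 - disc
  theta <- if (abs(mxz) < .Machine$double.eps && mxx >= mzz) 0
           else atan2(l1 - mxx, mxz)
  list(major_axis_um = 4 * sqrt(l1),
       minor_axis_um = 4 * sqrt(max(0, l2)),
       orientation = theta,
       centroid_ascan = mx / lat,
       centroid_z_um = mz,
       n_px = n,
       area_um2 = n * lat * ax)
}

#' Classify an object by its long-axis diameter
#'
#' @param major_axis_um Long axis of the fitted ellipse, micrometres.
#' @param config A [quant_config].
#' @return `"hrf"` when `min <= major <= max` (boundaries inclusive),
#'   `"undersized"` below, `"oversized"` above.
#' @export
classify_object <- function(major_axis_um, config = quant_config()) {
  stopifnot(all(major_axis_um >= 0))
  ifelse(major_axis_um < config$min_diameter_um, "undersized",
         ifelse(major_axis_um > config$max_diameter_um, "oversized", "hrf"))
}

#' Assign an object to an ETDRS ring by its en-face centroid
#'
#' Membership by Euclidean en-face distance `d` of the object centroid from
#' the fovea: `R1` when `d <= 0.5` mm, else `R3` when `d <= 1.5` mm, else
#' `outside`; ring boundaries are inclusive. Rings are cumulative discs, so
#' every R1 object is also inside the 3-mm disc; summaries resolve this per
#' the configured `ring_mode`.
#'
#' @param dist_mm En-face distance from the fovea center in millimetres (or a
#'   vector of distances).
#' @param config A [quant_config].
#' @return `"R1"`, `"R3"` or `"outside"`.
#' @export
assign_region <- function(dist_mm, config = quant_config()) {
  ifelse(dist_mm <= config$r1_radius_mm, "R1",
         ifelse(dist_mm <= config$r3_radius_mm, "R3", "outside"))
}

#' Assign an object to the inner or outer retinal compartment
#'
#' The inner retina runs from the ILM to, and including, the OPL-HFL
#' boundary; the outer retina from just below the OPL-HFL to the RPE. An
#' object centroid exactly on the OPL-HFL is therefore inner. Centroids
#' above the ILM or below the RPE are outside the retina (`NA`, excluded and
#' QC-counted by [quantify_volume()]), as are locations where the surfaces
#' are undefined.
#'
#' @param centroid_z_um Axial centroid position, micrometres from volume top.
#' @param surf_at Named vector `c(ilm, oplhfl, rpe)` from [surfaces_at()].
#' @return `"inner"`, `"outer"`, or `NA_character_` when outside the retina
#'   or the surfaces are undefined.
#' @export
assign_compartment <- function(centroid_z_um, surf_at) {
  if (anyNA(surf_at)) return(NA_character_)
  if (centroid_z_um < surf_at[["ilm"]] || centroid_z_um > surf_at[["rpe"]])
    return(NA_character_)
  if (centroid_z_um <= surf_at[["oplhfl"]]) "inner" else "outer"
}

#' Quantify HRF objects in a segmentation mask
#'
#' Runs the full per-eye quantification: per-B-scan connected components,
#' equivalent-ellipse sizing in physical units, size classification against
#' the HRF diameter window, ETDRS ring and retinal-compartment assignment,
#' and per-object volume as area x B-scan spacing (reported in picoliters;
#' 1 pL = 1000 um^3).
#'
#' @param mask 0/1 array `(bscan, depth, width)`.
#' @param surfaces A [layer_surfaces].
#' @param geometry A [scan_geometry].
#' @param config A [quant_config].
#' @param eye,visit_week Identifiers carried into the summary.
#' @return A list of class `hrf_quant`: `objects` (data.frame of retained HRF
#'   objects), `summary` (the [summarize_objects()] table), `qc` (tallies of
#'   excluded objects by reason: `undersized`, `oversized`,
#'   `outside_retina`, `outside_rings`, `no_surface`).
#' @export
quantify_volume <- function(mask, surfaces, geometry,
                            config = quant_config(),
                            eye = "eye", visit_week = 0) {
  check_mask_geometry(mask, geometry)
  qc <- c(undersized = 0L, oversized = 0L, outside_retina = 0L,
          outside_rings = 0L, no_surface = 0L)
  rows <- list()
  for (b in seq_len(geometry$n_bscans) - 1L) {
    comps <- extract_components(mask, b, config)
    for (comp in comps) {
      e <- fit_ellipse(comp, geometry)
      cls <- classify_object(e$major_axis_um, config)
      if (cls != "hrf") {
        qc[cls] <- qc[cls] + 1L
        next
      }
      s <- surfaces_at(surfaces, b, e$centroid_ascan)
      if (anyNA(s)) { qc["no_surface"] <- qc["no_surface"] + 1L; next }
      compartment <- assign_compartment(e$centroid_z_um, s)
      if (is.na(compartment)) {
        qc["outside_retina"] <- qc["outside_retina"] + 1L
        warning(sprintf("object at bscan %d, ascan %.1f lies outside ILM-RPE; excluded",
                        b, e$centroid_ascan), call. = FALSE)
        next
      }
      dx <- (e$centroid_ascan - geometry$fovea_center[2]) *
        geometry$lateral_px_um / 1000
      dy <- (b - geometry$fovea_center[1]) * geometry$bscan_spacing_um / 1000
      d <- sqrt(dx^2 + dy^2)
      region <- assign_region(d, config)
      if (region == "outside") {
        qc["outside_rings"] <- qc["outside_rings"] + 1L
        next
      }
      rows[[length(rows) + 1L]] <- data.frame(
        bscan = b, centroid_ascan = e$centroid_ascan,
        centroid_z_um = e$centroid_z_um,
        enface_dist_mm = d,
        major_axis_um = e$major_axis_um, minor_axis_um = e$minor_axis_um,
        orientation = e$orientation, n_px = e$n_px, area_um2 = e$area_um2,
        volume_pl = e$area_um2 * geometry$bscan_spacing_um / 1000,
        region = region, compartment = compartment)
    }
  }
  objects <- if (length(rows) > 0) do.call(rbind, rows) else
    data.frame(bscan = integer(), centroid_ascan = numeric(),
               centroid_z_um = numeric(), enface_dist_mm = numeric(),
               major_axis_um = numeric(), minor_axis_um = numeric(),
               orientation = numeric(), n_px = integer(),
               area_um2 = numeric(), volume_pl = numeric(),
               region = character(), compartment = character())
  structure(list(objects = objects,
                 summary = summarize_objects(objects, config, eye, visit_week),
                 qc = as.list(qc)),
            class = "hrf_quant")
}

#' Summarise HRF objects by ETDRS ring and compartment
#'
#' Counts and summed volumes per (ring, compartment) cell, with the `total`
#' compartment defined exactly as inner + outer. Under the default cumulative
#' ring mode, R3 rows cover the whole 3-mm disc (R1 included), so R3 values
#' are always >= R1 values; under `annulus` mode R3 rows cover only the
#' 1-3 mm annulus.
#'
#' @param objects Data.frame of retained HRF objects from [quantify_volume()].
#' @param config A [quant_config].
#' @param eye,visit_week Identifiers.
#' @return Data.frame of class `hrf_summary` with columns `eye`,
#'   `visit_week`, `region`, `compartment`, `hrf_count`, `hrf_volume_pl`.
#' @export
summarize_objects <- function(objects, config = quant_config(),
                              eye = "eye", visit_week = 0) {
  cells <- expand.grid(region = c("R1", "R3"),
                       compartment = c("inner", "outer", "total"),
                       stringsAsFactors = FALSE)
  out <- do.call(rbind, lapply(seq_len(nrow(cells)), function(i) {
    ring <- cells$region[i]; comp <- cells$compartment[i]
    if (config$ring_mode == "cumulative" && ring == "R3") {
      in_ring <- objects$region %in% c("R1", "R3")
    } else {
      in_ring <- objects$region == ring
    }
    in_comp <- if (comp == "total") rep(TRUE, nrow(objects))
               else objects$compartment == comp
    sel <- in_ring & in_comp
    data.frame(eye = eye, visit_week = visit_week,
               region = ring, compartment = comp,
               hrf_count = sum(sel),
               hrf_volume_pl = sum(objects$volume_pl[sel]))
  }))
  class(out) <- c("hrf_summary", "data.frame")
  out
}

#' Intensity-threshold candidate detector
#'
#' A transparent stand-in segmentation for intensity volumes: a voxel is
#' marked as hyperreflective-material candidate iff it lies strictly between
#' the ILM and the RPE and its intensity is at least `f` times the median
#' reflectivity of the local RPE band (HRF being bright dots of similar
#' reflectivity to the RPE). Isolated single-pixel candidates are removed
#' as speckle. This is a simple detector for synthetic and exploratory use,
#' not a model of any trained segmentation network.
#'
#' @param intensity 0-255 array `(bscan, depth, width)`.
#' @param surfaces A [layer_surfaces].
#' @param geometry A [scan_geometry].
#' @param f Fraction of the RPE-band median used as threshold (default 0.9).
#' @param rpe_band_um Thickness of the band below the RPE surface used to
#'   estimate reference reflectivity (default 20 um).
#' @param min_component_px Candidate components smaller than this many
#'   pixels are removed as speckle (default 2, i.e. isolated single pixels
#'   are dropped; a genuine 20 um focus spans several pixels at typical OCT
#'   pitches).
#' @return A 0/1 mask array.
#' @export
detect_candidates <- function(intensity, surfaces, geometry, f = 0.9,
                              rpe_band_um = 20, min_component_px = 2L) {
  check_mask_geometry(intensity, geometry)
  mask <- array(0L, dim(intensity))
  z_um <- (seq_len(geometry$depth_px) - 1L) * geometry$axial_px_um
  for (b in seq_len(geometry$n_bscans)) {
    sl <- intensity[b, , , drop = TRUE]
    ilm <- matrix(surfaces$ilm_z[b, ], geometry$depth_px,
                  geometry$n_ascans, byrow = TRUE)
    rpe <- matrix(surfaces$rpe_z[b, ], geometry$depth_px,
                  geometry$n_ascans, byrow = TRUE)
    zi <- matrix(z_um, geometry$depth_px, geometry$n_ascans)
    band <- zi >= rpe & zi <= rpe + rpe_band_um
    if (!any(band)) {
      warning(sprintf("B-scan %d: empty RPE band; skipped", b - 1L),
              call. = FALSE)
      next
    }
    thr <- f * stats::median(sl[band])
    cand <- (zi > ilm) & (zi < rpe) & (sl >= thr)
    mask[b, , ] <- remove_speckle(cand * 1L, min_component_px)
  }
  mask
}

# drop connected components below the size floor (isolated speckle)
remove_speckle <- function(m, min_px) {
  if (min_px <= 1L || sum(m) == 0) return(m)
  for (comp in label_components(m, 8L)) {
    if (nrow(comp) < min_px)
      m[cbind(comp$depth + 1L, comp$ascan + 1L)] <- 0L
  }
  m
}
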