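#' Scan geometry of an SD-OCT volume
#'
#' Describes the physical voxel grid of a volume scan: a stack of `n_bscans`
#' cross-sectional B-scans, each a `depth_px` x `n_ascans` image with axial
#' pixel pitch `axial_px_um` (depth, increasing downward from the top of the
#' volume) and lateral pitch `lateral_px_um` along the B-scan. Adjacent
#' B-scan centers are `bscan_spacing_um` apart; this slice thickness is the
#' depth term used when per-B-scan object areas are converted to volumes.
#'
#' Coordinate conventions used throughout the package: indices are 0-based;
#' axial positions are micrometres from the top of the volume, increasing
#' downward; en-face positions are millimetres relative to the fovea center.
#'
#' @param n_bscans Number of B-scans (a typical Spectralis DME protocol
#'   acquires 97).
#' @param depth_px Axial size of each B-scan in pixels.
#' @param n_ascans Number of A-scans (lateral pixels) per B-scan.
#' @param axial_px_um Axial pixel size in micrometres.
#' @param lateral_px_um Lateral pixel size in micrometres. Not recorded in
#'   every export, hence a default of 11.5 um (about 6 mm over 512 A-scans, a
#'   common Spectralis setting); always override when the true value is known.
#' @param bscan_spacing_um Distance between the centers of adjacent B-scans in
#'   micrometres (about 62 um for the 97-B-scan protocol).
#' @param fovea_center Length-2 numeric, `(bscan index, A-scan position)` of
#'   the fovea in 0-based en-face pixel coordinates. Fractional values are
#'   allowed.
#' @return An object of class `scan_geometry`.
#' @examples
#' g <- scan_geometry(n_bscans = 97, depth_px = 496, n_ascans = 512,
#'                    axial_px_um = 3.87, bscan_spacing_um = 62)
#' g$scan_area_mm2
#' @export
scan_geometry <- function(n_bscans, depth_px, n_ascans,
                          axial_px_um, lateral_px_um = 11.5,
                          bscan_spacing_um,
                          fovea_center = c((n_bscans - 1) / 2,
                                           (n_ascans - 1) / 2)) {
  stopifnot(length(n_bscans) == 1L, n_bscans >= 1,
            length(depth_px) == 1L, depth_px >= 1,
            length(n_ascans) == 1L, n_ascans >= 1)
  if (axial_px_um <= 0 || lateral_px_um <= 0 || bscan_spacing_um <= 0)
    stop("all pixel spacings must be strictly positive", call. = FALSE)
  fovea_center <- as.numeric(fovea_center)
  if (length(fovea_center) != 2L || anyNA(fovea_center))
    stop("fovea_center must be (bscan index, ascan position)", call. = FALSE)
  if (fovea_center[1] < 0 || fovea_center[1] > n_bscans - 1 ||
      fovea_center[2] < 0 || fovea_center[2] > n_ascans - 1)
    stop("fovea_center lies outside the en-face footprint", call. = FALSE)
  g <- list(n_bscans = as.integer(n_bscans),
            depth_px = as.integer(depth_px),
            n_ascans = as.integer(n_ascans),
            axial_px_um = axial_px_um,
            lateral_px_um = lateral_px_um,
            bscan_spacing_um = bscan_spacing_um,
            fovea_center = fovea_center,
            scan_area_mm2 = n_ascans * lateral_px_um *
              n_bscans * bscan_spacing_um / 1e6)
  class(g) <- "scan_geometry"
  g
}

#' @export
print.scan_geometry <- function(x, ...) {
  cat("SD-OCT scan geometry\n")
  cat(sprintf("  %d B-scans x %d px depth x %d A-scans\n",
              x$n_bscans, x$depth_px, x$n_ascans))
  cat(sprintf("  pixel pitch: %.3g um axial, %.3g um lateral, %.3g um between B-scans\n",
              x$axial_px_um, x$lateral_px_um, x$bscan_spacing_um))
  cat(sprintf("  fovea center (bscan, ascan): (%.1f, %.1f); en-face area %.1f mm^2\n",
              x$fovea_center[1], x$fovea_center[2], x$scan_area_mm2))
  invisible(x)
}

#' Retinal layer surfaces
#'
#' Bundles the three axial surfaces bounding the retinal compartments: the
#' internal limiting membrane (ILM), the outer plexiform layer-Henle fiber
#' layer boundary (OPL-HFL) and the retinal pigment epithelium (RPE). The
#' inner retina runs from the ILM to, and including, the OPL-HFL; the outer
#' retina from the OPL-HFL to the RPE; the total retina from ILM to RPE.
#'
#' Each surface is an `n_bscans x n_ascans` matrix of axial positions in
#' micrometres from the top of the volume. Missing values (e.g. segmentation
#' failure under large cysts) are filled by linear interpolation along the
#' A-scan direction when the gap spans at most `max_gap` A-scans; larger gaps
#' are an error so that silent extrapolation over wide defects cannot occur.
#'
#' @param ilm_z,oplhfl_z,rpe_z Numeric matrices of identical dimension, axial
#'   positions in micrometres.
#' @param max_gap Largest run of consecutive missing A-scans that will be
#'   interpolated (default 10).
#' @return An object of class `layer_surfaces` with elements `ilm_z`,
#'   `oplhfl_z`, `rpe_z`.
#' @export
layer_surfaces <- function(ilm_z, oplhfl_z, rpe_z, max_gap = 10L) {
  ilm_z <- as.matrix(ilm_z); oplhfl_z <- as.matrix(oplhfl_z)
  rpe_z <- as.matrix(rpe_z)
  if (!identical(dim(ilm_z), dim(oplhfl_z)) ||
      !identical(dim(ilm_z), dim(rpe_z)))
    stop("surface matrices must share dimensions", call. = FALSE)
  ilm_z <- interp_surface_gaps(ilm_z, max_gap, "ilm")
  oplhfl_z <- interp_surface_gaps(oplhfl_z, max_gap, "oplhfl")
  rpe_z <- interp_surface_gaps(rpe_z, max_gap, "rpe")
  bad <- which((ilm_z > oplhfl_z | oplhfl_z > rpe_z) &
                 !is.na(ilm_z) & !is.na(oplhfl_z) & !is.na(rpe_z),
               arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop(sprintf(
      "crossing surfaces: ilm <= oplhfl <= rpe violated first at bscan %d, ascan %d (0-based)",
      bad[1, 1] - 1L, bad[1, 2] - 1L), call. = FALSE)
  }
  structure(list(ilm_z = ilm_z, oplhfl_z = oplhfl_z, rpe_z = rpe_z),
            class = "layer_surfaces")
}

# Linear interpolation of NA runs of length <= max_gap along each B-scan row.
# Runs touching the row edge, or longer than max_gap, are an error: the caller
# must supply surfaces wherever objects may occur.
interp_surface_gaps <- function(m, max_gap, name) {
  if (!anyNA(m)) return(m)
  for (i in seq_len(nrow(m))) {
    row <- m[i, ]
    if (!anyNA(row)) next
    r <- rle(is.na(row))
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (k in which(r$values)) {
      if (r$lengths[k] > max_gap)
        stop(sprintf("surface '%s': %d consecutive missing A-scans at bscan %d, ascan %d (0-based); gap exceeds %d",
                     name, r$lengths[k], i - 1L, starts[k] - 1L, max_gap),
             call. = FALSE)
      if (starts[k] == 1L || ends[k] == length(row))
        stop(sprintf("surface '%s': missing values touch the edge of bscan %d; cannot interpolate",
                     name, i - 1L), call. = FALSE)
    }
    known <- which(!is.na(row))
    m[i, ] <- stats::approx(known, row[known], xout = seq_along(row))$y
  }
  m
}

#' Evaluate layer surfaces at an A-scan position
#'
#' @param surfaces A [layer_surfaces] object.
#' @param bscan,ascan 0-based indices (scalar); `ascan` may be fractional and
#'   is rounded to the nearest A-scan column.
#' @return Named numeric vector `c(ilm, oplhfl, rpe)` in micrometres, `NA`
#'   where undefined.
#' @export
surfaces_at <- function(surfaces, bscan, ascan) {
  i <- as.integer(bscan) + 1L
  j <- as.integer(round(ascan)) + 1L
  if (i < 1L || i > nrow(surfaces$ilm_z) || j < 1L || j > ncol(surfaces$ilm_z))
    return(c(ilm = NA_real_, oplhfl = NA_real_, rpe = NA_real_))
  c(ilm = surfaces$ilm_z[i, j],
    oplhfl = surfaces$oplhfl_z[i, j],
    rpe = surfaces$rpe_z[i, j])
}

# shape check shared by readers and quantification
check_mask_geometry <- function(mask, geometry) {
  d <- dim(mask)
  expect <- c(geometry$n_bscans, geometry$depth_px, geometry$n_ascans)
  names(expect) <- c("n_bscans", "depth_px", "n_ascans")
  if (length(d) != 3L)
    stop("mask must be a 3-D array (bscan, depth, width)", call. = FALSE)
  for (k in 1:3) {
    if (d[k] != expect[k])
      stop(sprintf("mask dimension %d (%s) is %d but geometry declares %d",
                   k, names(expect)[k], d[k], expect[k]), call. = FALSE)
  }
  invisible(TRUE)
}
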