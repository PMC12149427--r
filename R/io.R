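#' Read a volume (mask or intensity) from multi-page TIFF or NIfTI
#'
#' Volumes are stored with one page/slab per B-scan. The returned array has
#' axis order `(bscan, depth, width)`. Masks are binarised: any nonzero voxel
#' counts as hyperreflective material, tolerant of upstream binarisation
#' dialects (0/1, 0/255, ...).
#'
#' @param path Path to a `.tif`/`.tiff` multi-page TIFF or `.nii`/`.nii.gz`
#'   NIfTI file.
#' @param kind `"mask"` (binarise at > 0, integer 0/1) or `"intensity"`
#'   (values returned as stored, TIFF rescaled to 0..255).
#' @param geometry Optional [scan_geometry]; when given, array dimensions are
#'   checked against it and a format error names any offending dimension.
#' @return A 3-D array `(bscan, depth, width)`.
#' @export
read_volume <- function(path, kind = c("mask", "intensity"), geometry = NULL) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    pages <- tiff::readTIFF(path, all = TRUE, as.is = FALSE)
    if (!is.list(pages)) pages <- list(pages)
    d <- dim(pages[[1]])
    vol <- array(0, c(length(pages), d[1], d[2]))
    for (i in seq_along(pages)) {
      p <- pages[[i]]
      if (length(dim(p)) == 3L) p <- p[, , 1]  # tolerate grey stored as RGB
      vol[i, , ] <- p
    }
    if (kind == "intensity") vol <- round(vol * 255)
  } else if (grepl("\\.nii(\\.gz)?$", path, ignore.case = TRUE)) {
    img <- RNifti::readNifti(path)
    vol <- array(as.numeric(img), dim(img))
    if (length(dim(vol)) != 3L)
      stop("NIfTI volume must be 3-D, got ", length(dim(vol)), " dimensions",
           call. = FALSE)
  } else {
    stop("unrecognised volume format (expect .tif/.tiff or .nii/.nii.gz): ",
         path, call. = FALSE)
  }
  if (kind == "mask") {
    vol <- array(as.integer(vol > 0), dim(vol))
  }
  if (!is.null(geometry)) check_mask_geometry(vol, geometry)
  vol
}

#' Write a volume to multi-page TIFF or NIfTI
#'
#' @param vol 3-D array `(bscan, depth, width)`. Masks should be 0/1;
#'   intensity volumes 0..255 (8-bit) or 0..65535 (16-bit).
#' @param path Destination; format chosen from the extension.
#' @param bits TIFF bit depth (8 or 16); ignored for NIfTI.
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path, bits = 8L) {
  stopifnot(length(dim(vol)) == 3L)
  if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    top <- 2^bits - 1
    if (max(vol) > top) stop("values exceed TIFF bit depth", call. = FALSE)
    pages <- lapply(seq_len(dim(vol)[1]),
                    function(i) vol[i, , , drop = TRUE] / top)
    tiff::writeTIFF(pages, path, bits.per.sample = as.integer(bits))
  } else if (grepl("\\.nii(\\.gz)?$", path, ignore.case = TRUE)) {
    RNifti::writeNifti(vol, path)
  } else {
    stop("unrecognised volume format: ", path, call. = FALSE)
  }
  invisible(path)
}

#' Read and write layer surfaces as CSV
#'
#' CSV columns: `bscan`, `ascan` (0-based indices), `ilm_um`, `oplhfl_um`,
#' `rpe_um` (micrometres from the top of the volume). Missing interior values
#' may be encoded as empty fields/NA; gaps of at most `max_gap` A-scans are
#' interpolated by [layer_surfaces()].
#'
#' @param path CSV file path.
#' @param max_gap Passed to [layer_surfaces()].
#' @return [read_surfaces()]: a [layer_surfaces] object.
#' @export
read_surfaces <- function(path, max_gap = 10L) {
  df <- utils::read.csv(path)
  need <- c("bscan", "ascan", "ilm_um", "oplhfl_um", "rpe_um")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0)
    stop("surfaces CSV missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  nb <- max(df$bscan) + 1L
  na <- max(df$ascan) + 1L
  if (nrow(df) != nb * na)
    stop(sprintf("surfaces CSV has %d rows; expected full %d x %d grid",
                 nrow(df), nb, na), call. = FALSE)
  grid <- function(v) {
    m <- matrix(NA_real_, nb, na)
    m[cbind(df$bscan + 1L, df$ascan + 1L)] <- v
    m
  }
  layer_surfaces(grid(df$ilm_um), grid(df$oplhfl_um), grid(df$rpe_um),
                 max_gap = max_gap)
}

#' @rdname read_surfaces
#' @param surfaces A [layer_surfaces] object.
#' @return [write_surfaces()]: `path`, invisibly.
#' @export
write_surfaces <- function(surfaces, path) {
  nb <- nrow(surfaces$ilm_z); na <- ncol(surfaces$ilm_z)
  df <- data.frame(
    bscan = rep(seq_len(nb) - 1L, each = na),
    ascan = rep(seq_len(na) - 1L, times = nb),
    ilm_um = as.vector(t(surfaces$ilm_z)),
    oplhfl_um = as.vector(t(surfaces$oplhfl_z)),
    rpe_um = as.vector(t(surfaces$rpe_z)))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read and write scan geometry as JSON
#' @param path JSON file path.
#' @return [read_geometry()]: a [scan_geometry] object.
#' @export
read_geometry <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  scan_geometry(n_bscans = j$n_bscans, depth_px = j$depth_px,
                n_ascans = j$n_ascans, axial_px_um = j$axial_px_um,
                lateral_px_um = j$lateral_px_um,
                bscan_spacing_um = j$bscan_spacing_um,
                fovea_center = j$fovea_center)
}

#' @rdname read_geometry
#' @param geometry A [scan_geometry] object.
#' @export
write_geometry <- function(geometry, path) {
  jsonlite::write_json(unclass(geometry)[c("n_bscans", "depth_px", "n_ascans",
                                           "axial_px_um", "lateral_px_um",
                                           "bscan_spacing_um", "fovea_center")],
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

# ---- longitudinal trial tables -------------------------------------------

trial_arms <- c("faricimab_q8w", "faricimab_te", "aflibercept_q8w")
trial_regions <- c("us_canada", "asia", "rest_of_world")
trial_endpoint_cols <- c(
  "vol_inner_r1_pl", "vol_outer_r1_pl", "vol_inner_r3_pl", "vol_outer_r3_pl",
  "count_inner_r1", "count_outer_r1", "count_inner_r3", "count_outer_r3",
  "irf_vol_pl")

#' Read a longitudinal trial endpoint table
#'
#' One row per patient-visit. Required columns: `patient_id`, `arm` (one of
#' `faricimab_q8w`, `faricimab_te`, `aflibercept_q8w`), `visit_week`,
#' `bcva_baseline` (letters), `bcva_stratum` (`"<64"`/`">=64"`),
#' `prior_anti_vegf` (`"yes"`/`"no"`), `region_stratum` (`us_canada`, `asia`,
#' `rest_of_world`), `last_week`, plus the endpoint columns
#' `vol_<compartment>_<ring>_pl`, `count_<compartment>_<ring>` and
#' `irf_vol_pl`.
#'
#' Patients without a week-0 row are flagged with a warning and marked
#' `has_baseline = FALSE`; baseline-adjusted analyses exclude them.
#'
#' @param path CSV file path.
#' @return A `data.frame` of class `trial_dataset`, sorted by patient and
#'   week, with attribute `no_baseline` listing patients lacking a week-0 row.
#' @export
read_trial_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_trial_table(df)
}

#' Validate an in-memory trial table
#' @param df A data.frame with the [read_trial_table()] schema.
#' @return The validated, typed `trial_dataset`.
#' @export
validate_trial_table <- function(df) {
  need <- c("patient_id", "arm", "visit_week", "bcva_baseline",
            "bcva_stratum", "prior_anti_vegf", "region_stratum", "last_week")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0)
    stop("trial table missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  bad_arm <- setdiff(unique(df$arm), trial_arms)
  if (length(bad_arm) > 0)
    stop("unknown arm label(s): ", paste(bad_arm, collapse = ", "),
         call. = FALSE)
  bad_reg <- setdiff(unique(df$region_stratum), trial_regions)
  if (length(bad_reg) > 0)
    stop("unknown region stratum: ", paste(bad_reg, collapse = ", "),
         call. = FALSE)
  bad_bcva <- setdiff(unique(df$bcva_stratum), c("<64", ">=64"))
  if (length(bad_bcva) > 0)
    stop("unknown BCVA stratum: ", paste(bad_bcva, collapse = ", "),
         call. = FALSE)
  bad_pav <- setdiff(unique(df$prior_anti_vegf), c("yes", "no"))
  if (length(bad_pav) > 0)
    stop("prior_anti_vegf must be yes/no, got: ",
         paste(bad_pav, collapse = ", "), call. = FALSE)
  key <- paste(df$patient_id, df$visit_week)
  if (anyDuplicated(key))
    stop("duplicated patient-visit row(s), e.g. ", key[anyDuplicated(key)],
         call. = FALSE)
  df$arm <- factor(df$arm, levels = trial_arms)
  df <- df[order(df$patient_id, df$visit_week), , drop = FALSE]
  with_base <- unique(df$patient_id[df$visit_week == 0])
  no_base <- setdiff(unique(df$patient_id), with_base)
  if (length(no_base) > 0)
    warning(length(no_base),
            " patient(s) lack a week-0 row and are excluded from ",
            "baseline-adjusted analyses: ",
            paste(utils::head(no_base, 5), collapse = ", "), call. = FALSE)
  attr(df, "no_baseline") <- no_base
  class(df) <- c("trial_dataset", "data.frame")
  df
}

#' Write a per-eye HRF summary table to CSV
#'
#' Long format with columns `eye`, `visit_week`, `region` (`R1`/`R3`),
#' `compartment` (`inner`/`outer`/`total`), `hrf_count`, `hrf_volume_pl`.
#'
#' @param summaries An `hrf_summary` object or data.frame of such rows.
#' @param path Destination CSV.
#' @export
write_summary <- function(summaries, path) {
  df <- as.data.frame(summaries)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname read_trial_table
#' @param dataset A `trial_dataset`.
#' @export
write_trial_table <- function(dataset, path) {
  df <- as.data.frame(dataset)
  df$arm <- as.character(df$arm)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
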