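#' Region of interest
#'
#' A box in voxel coordinates (1-based, inclusive bounds) restricting where
#' thresholding is applied — the manual part of the semi-automatic
#' segmentation. An optional coarse binary include-mask further restricts
#' the box.
#'
#' @param z,y,x integer vectors `c(lo, hi)`; `NULL` means the full extent.
#' @param include optional logical 3D array (full volume shape); only `TRUE`
#'   voxels are eligible.
#' @return A `region_of_interest` object.
#' @export
region_of_interest <- function(z = NULL, y = NULL, x = NULL, include = NULL) {
  chk <- function(v, nm) {
    if (is.null(v)) return(NULL)
    if (length(v) != 2 || any(v < 1) || v[1] > v[2])
      stopf("`%s` must be c(lo, hi) with 1 <= lo <= hi", nm)
    as.integer(v)
  }
  structure(list(z = chk(z, "z"), y = chk(y, "y"), x = chk(x, "x"),
                 include = include),
            class = "region_of_interest")
}

roi_selector <- function(roi, dims) {
  if (is.null(roi)) roi <- region_of_interest()
  lim <- function(v, n, nm) {
    if (is.null(v)) return(c(1L, n))
    if (v[2] > n) stopf("ROI %s bound %d exceeds volume extent %d", nm, v[2], n)
    v
  }
  z <- lim(roi$z, dims[1], "z"); y <- lim(roi$y, dims[2], "y")
  x <- lim(roi$x, dims[3], "x")
  sel <- array(FALSE, dims)
  sel[z[1]:z[2], y[1]:y[2], x[1]:x[2]] <- TRUE
  if (!is.null(roi$include)) {
    if (!identical(dim(roi$include), dims))
      stopf("ROI include-mask shape differs from volume shape")
    sel <- sel & roi$include
  }
  sel
}

# Default voxel-pitch uncertainty (um): half the 1-um focal spot of the
# scanner, applied symmetrically to the reconstructed pitch.
PITCH_UNCERTAINTY_UM <- 0.5

# Default normalized segmentation threshold: the value at which stained soft
# tissue separates cleanly from the background liquid in well-stained scans.
DEFAULT_THRESHOLD <- 0.4

#' Threshold segmentation within a region of interest
#'
#' Semi-automatic segmentation: voxels inside the ROI with normalized
#' greyvalue `>=` the threshold form the mask; connected components are
#' labelled with the full 26-neighbourhood (6-connectivity fragments thin
#' cuticle sheets) and optionally only the largest is kept. Integer volumes
#' are normalized internally. The segmented volume is reported in mm^3 with
#' lower/upper bounds from the voxel-pitch uncertainty.
#'
#' @param volume a [voxel_volume()] (integer or normalized).
#' @param roi a [region_of_interest()]; `NULL` = whole volume.
#' @param threshold normalized threshold in (0, 1); default 0.4.
#' @param keep `"largest_component"` (default) or `"all_components"`.
#' @param pitch_uncertainty_um symmetric voxel-pitch uncertainty in um
#'   (default 0.5) used for the volume bounds.
#' @return A `segmentation_result`: `mask` (logical 3D array), `threshold`,
#'   `component_count`, `voxel_count`, `volume_mm3`, `volume_lower_mm3`,
#'   `volume_upper_mm3`, `voxel_size_um`.
#' @export
threshold_segment <- function(volume, roi = NULL, threshold = DEFAULT_THRESHOLD,
                              keep = c("largest_component", "all_components"),
                              pitch_uncertainty_um = PITCH_UNCERTAINTY_UM) {
  stopifnot(inherits(volume, "voxel_volume"))
  keep <- match.arg(keep)
  if (!is_scalar_number(threshold) || threshold <= 0 || threshold >= 1)
    stopf("`threshold` must lie strictly between 0 and 1")
  if (!is_normalized(volume))
    volume <- suppressMessages(normalize_volume(volume))
  sel <- roi_selector(roi, dim(volume$data))
  mask <- (volume$data >= threshold) & sel

  if (!any(mask)) {
    warnf("empty segmentation: no voxel in the ROI reaches threshold %g", threshold)
    comp_count <- 0L
  } else {
    labels <- .label_components_3d(mask)
    comp_count <- attr(labels, "n_components")
    if (keep == "largest_component") {
      mask <- labels == 1L  # components are numbered largest-first
      dim(mask) <- dim(volume$data)
    }
  }
  vb <- volume_from_voxels(sum(mask), volume$voxel_size_um, pitch_uncertainty_um)
  structure(list(mask = mask, threshold = threshold,
                 component_count = comp_count, voxel_count = vb$voxel_count,
                 volume_mm3 = vb$volume_mm3,
                 volume_lower_mm3 = vb$lower_mm3, volume_upper_mm3 = vb$upper_mm3,
                 voxel_size_um = volume$voxel_size_um,
                 pitch_uncertainty_um = pitch_uncertainty_um, keep = keep),
            class = "segmentation_result")
}

#' @export
print.segmentation_result <- function(x, ...) {
  cat(sprintf("<segmentation_result> threshold %.3g, %d component(s), %d voxel(s)\n",
              x$threshold, x$component_count, x$voxel_count))
  cat(sprintf("  volume %.6g mm^3 [%.6g, %.6g] at %.3g +/- %.2g um pitch\n",
              x$volume_mm3, x$volume_lower_mm3, x$volume_upper_mm3,
              x$voxel_size_um, x$pitch_uncertainty_um))
  invisible(x)
}

#' Volume from a voxel count, with pitch-uncertainty bounds
#'
#' `volume = voxel_count * (pitch mm)^3` exactly; the bounds substitute
#' `pitch +/- delta`, so pitch uncertainty propagates cubically. At
#' `delta = 0` the bounds collapse onto the volume.
#'
#' @param voxel_count non-negative integer.
#' @param voxel_size_um voxel pitch in um.
#' @param pitch_uncertainty_um symmetric pitch uncertainty delta in um.
#' @return List with `voxel_count`, `volume_mm3`, `lower_mm3`, `upper_mm3`.
#' @export
volume_from_voxels <- function(voxel_count, voxel_size_um,
                               pitch_uncertainty_um = PITCH_UNCERTAINTY_UM) {
  if (pitch_uncertainty_um < 0) stopf("pitch uncertainty must be >= 0")
  mm <- function(p) voxel_count * (p * 1e-3)^3
  list(voxel_count = as.integer(voxel_count),
       volume_mm3 = mm(voxel_size_um),
       lower_mm3 = mm(max(voxel_size_um - pitch_uncertainty_um, 0)),
       upper_mm3 = mm(voxel_size_um + pitch_uncertainty_um))
}

#' Measure a segmented structure's volume
#'
#' Accessor recomputing the mm^3 volume and its pitch-uncertainty bounds
#' from a [threshold_segment()] result.
#'
#' @param result a `segmentation_result`.
#' @param pitch_uncertainty_um override of the pitch uncertainty.
#' @return As [volume_from_voxels()].
#' @export
measure_volume <- function(result, pitch_uncertainty_um = result$pitch_uncertainty_um) {
  stopifnot(inherits(result, "segmentation_result"))
  volume_from_voxels(result$voxel_count, result$voxel_size_um, pitch_uncertainty_um)
}
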