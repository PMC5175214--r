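#' Contrast measurement for one tissue on one staining day
#'
#' Holds the per-patch mean greyvalues of a tissue and the mean greyvalue of
#' the surrounding liquid background, from which the simple contrast ratio
#' is computed.
#'
#' @param region_means mean greyvalue of each measured tissue patch
#'   (6-8 patches in routine use).
#' @param background_mean mean greyvalue of the background region; must be
#'   positive (the background liquid always attenuates).
#' @param tissue_label tissue name.
#' @param day integer staining day.
#' @return A `contrast_measurement` object.
#' @export
contrast_measurement <- function(region_means, background_mean,
                                 tissue_label = "tissue", day = NA_integer_) {
  if (!length(region_means)) stopf("`region_means` must be non-empty")
  if (!is_scalar_number(background_mean) || background_mean <= 0)
    stopf("invalid background: `background_mean` must be positive")
  structure(list(region_means = as.numeric(region_means),
                 background_mean = as.numeric(background_mean),
                 tissue_label = as.character(tissue_label),
                 day = as.integer(day)),
            class = "contrast_measurement")
}

#' Simple contrast ratio
#'
#' `(mean tissue greyvalue - mean background greyvalue) / mean background
#' greyvalue`, with the mean tissue greyvalue taken as the mean of the patch
#' means (equal patch weighting). Scale-free: multiplying all greyvalues by
#' a positive constant leaves it unchanged, so it can track stain
#' progression across days and scans. The spread is the n-1 standard
#' deviation of the per-patch ratios (0 for a single patch).
#'
#' @param measurement a [contrast_measurement()].
#' @return List with `ratio`, `sd`, `n_patches`, `tissue_label`, `day`.
#' @export
contrast_ratio <- function(measurement) {
  stopifnot(inherits(measurement, "contrast_measurement"))
  b <- measurement$background_mean
  per_patch <- (measurement$region_means - b) / b
  list(ratio = mean(per_patch),
       sd = if (length(per_patch) > 1) stats::sd(per_patch) else 0,
       n_patches = length(per_patch),
       tissue_label = measurement$tissue_label,
       day = measurement$day)
}

#' Sample patch means of a tissue from a volume + mask
#'
#' Emulates manual contrast measurement: `n_patches` disjoint cubic patches
#' are placed at seeded random positions fully inside the tissue's labelled
#' region and each patch's mean greyvalue recorded; the background mean is
#' taken over the entire background-labelled region ("a large area"). When
#' the tissue is too small to host even one full patch, the whole region
#' becomes a single patch, with a warning.
#'
#' @param volume a [voxel_volume()].
#' @param mask a [label_mask()] containing `tissue_label` and
#'   `background_label`.
#' @param tissue_label tissue to measure.
#' @param n_patches number of patches (default 8).
#' @param patch_edge cubic patch edge length in voxels (default 5).
#' @param background_label name of the background region.
#' @param day staining day recorded in the result.
#' @param seed RNG seed for patch placement.
#' @return A [contrast_measurement()].
#' @export
measure_regions <- function(volume, mask, tissue_label, n_patches = 8,
                            patch_edge = 5, background_label = "background",
                            day = NA_integer_, seed = 1L) {
  stopifnot(inherits(volume, "voxel_volume"), inherits(mask, "label_mask"))
  if (!identical(dim(volume$data), dim(mask$data)))
    stopf("volume and mask shapes differ")
  tid <- label_id(mask, tissue_label)
  bid <- label_id(mask, background_label)
  inside <- mask$data == tid
  background_mean <- mean(volume$data[mask$data == bid])
  e <- as.integer(patch_edge)

  # candidate anchors: voxels whose full e-cube lies inside the tissue
  set.seed(as.integer(seed))
  anchors <- which(inside, arr.ind = TRUE)
  d <- dim(inside)
  fits <- anchors[, 1] + e - 1 <= d[1] & anchors[, 2] + e - 1 <= d[2] &
    anchors[, 3] + e - 1 <= d[3]
  anchors <- anchors[fits, , drop = FALSE]
  patch_means <- numeric(0)
  used <- matrix(numeric(0), ncol = 3)  # accepted anchor corners
  if (nrow(anchors)) {
    tries <- sample.int(nrow(anchors))
    for (t in tries) {
      a <- anchors[t, ]
      if (nrow(used) &&
          any(abs(used[, 1] - a[1]) < e & abs(used[, 2] - a[2]) < e &
              abs(used[, 3] - a[3]) < e)) next  # would overlap an accepted patch
      cube <- inside[a[1]:(a[1] + e - 1), a[2]:(a[2] + e - 1), a[3]:(a[3] + e - 1)]
      if (!all(cube)) next
      patch_means <- c(patch_means,
                       mean(volume$data[a[1]:(a[1] + e - 1),
                                        a[2]:(a[2] + e - 1),
                                        a[3]:(a[3] + e - 1)]))
      used <- rbind(used, a)
      if (length(patch_means) >= n_patches) break
    }
  }
  if (length(patch_means) < n_patches) {
    if (!length(patch_means)) {
      warnf("tissue \"%s\" cannot host a %d-voxel cube; using the whole region as one patch",
            tissue_label, e)
      patch_means <- mean(volume$data[inside])
    } else {
      warnf("tissue \"%s\": only %d disjoint %d-voxel patches fit (requested %d)",
            tissue_label, length(patch_means), e, n_patches)
    }
  }
  contrast_measurement(patch_means, background_mean, tissue_label, day)
}

#' Stain-progression series for one tissue
#'
#' Orders per-day contrast measurements into a series of (day, ratio, sd).
#' Days need not be contiguous — scans lost to movement artefacts simply
#' leave gaps, which are never interpolated.
#'
#' @param measurements list of [contrast_measurement()]s for one tissue,
#'   each with a distinct day.
#' @return A `contrast_series`: data frame with columns `day`, `ratio`,
#'   `sd`, `n_patches`, plus a `tissue_label` attribute.
#' @export
progression_series <- function(measurements) {
  if (inherits(measurements, "contrast_measurement"))
    measurements <- list(measurements)
  if (!length(measurements)) stopf("need at least one measurement")
  labels <- unique(vapply(measurements, function(m) m$tissue_label, ""))
  if (length(labels) > 1)
    stopf("measurements mix tissues: %s", paste(labels, collapse = ", "))
  days <- vapply(measurements, function(m) m$day, 0L)
  if (anyNA(days)) stopf("every measurement needs a staining day")
  if (anyDuplicated(days))
    stopf("duplicate day(s) for tissue \"%s\": %s", labels,
          paste(unique(days[duplicated(days)]), collapse = ", "))
  ord <- order(days)
  rows <- lapply(measurements[ord], contrast_ratio)
  df <- data.frame(day = vapply(rows, function(r) r$day, 0L),
                   ratio = vapply(rows, function(r) r$ratio, 0),
                   sd = vapply(rows, function(r) r$sd, 0),
                   n_patches = vapply(rows, function(r) r$n_patches, 0L))
  structure(df, tissue_label = labels, class = c("contrast_series", "data.frame"))
}

#' @export
print.contrast_series <- function(x, ...) {
  cat(sprintf("<contrast_series> %s, %d day(s)\n", attr(x, "tissue_label"), nrow(x)))
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}
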