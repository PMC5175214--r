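# Stain-uptake quantification: the staining front advances from the
# incision through the specimen as the contrast agent diffuses; its
# position over days gives the uptake rate (mm/day), and the stained volume
# of a large tissue over days gives a volumetric trajectory.

axis_index <- function(axis) match(match.arg(axis, c("z", "y", "x")), c("z", "y", "x"))

#' Staining-front position along an axis
#'
#' For every one-voxel slab along the chosen axis (moving away from the
#' incision in increasing index), the fraction of that slab's tissue voxels
#' whose normalized greyvalue reaches `stained_threshold` is computed; the
#' front is the farthest slab at which this fraction is at least 0.5 (a
#' half-maximum convention, robust to speckle). Position is the slab's
#' distance from the incision in mm; 0 when no slab qualifies.
#'
#' @param volume a [voxel_volume()] (normalized internally if integer).
#' @param mask a [label_mask()] containing `tissue_label`.
#' @param tissue_label tissue whose staining is tracked.
#' @param axis `"z"`, `"y"` or `"x"`.
#' @param incision_index slab index (1-based) of the incision plane.
#' @param stained_threshold normalized greyvalue above which a voxel counts
#'   as stained (default 0.4, the segmentation convention).
#' @return List with `position_mm`, `front_slab` (index, NA when unstained)
#'   and `profile` (data frame of slab distance_mm and stained fraction).
#' @export
front_position <- function(volume, mask, tissue_label, axis = "z",
                           incision_index = 1L,
                           stained_threshold = DEFAULT_THRESHOLD) {
  stopifnot(inherits(volume, "voxel_volume"), inherits(mask, "label_mask"))
  if (!identical(dim(volume$data), dim(mask$data)))
    stopf("volume and mask shapes differ")
  if (!is_normalized(volume)) volume <- suppressMessages(normalize_volume(volume))
  ax <- axis_index(axis)
  n <- dim(volume$data)[ax]
  if (incision_index < 1 || incision_index > n)
    stopf("incision slab %d outside axis extent 1..%d", incision_index, n)
  tid <- label_id(mask, tissue_label)
  tissue <- mask$data == tid
  if (!any(tissue)) stopf("label \"%s\" has no voxels", tissue_label)
  stained <- tissue & (volume$data >= stained_threshold)
  n_tissue <- apply(tissue, ax, sum)
  n_stained <- apply(stained, ax, sum)
  slabs <- which(n_tissue > 0 & seq_len(n) >= incision_index)
  if (!length(slabs))
    stopf("tissue \"%s\" absent along %s beyond the incision", tissue_label, axis)
  frac <- n_stained[slabs] / n_tissue[slabs]
  pitch_mm <- volume$voxel_size_um * 1e-3
  qual <- slabs[frac >= 0.5]
  front <- if (length(qual)) max(qual) else NA_integer_
  list(position_mm = if (is.na(front)) 0 else (front - incision_index) * pitch_mm,
       front_slab = front,
       profile = data.frame(distance_mm = (slabs - incision_index) * pitch_mm,
                            fraction = frac))
}

#' Per-day uptake series
#'
#' Front positions (mm) or stained volumes (mm^3) over staining days.
#'
#' @param days strictly increasing integer staining days.
#' @param values front position (mm) or stained volume (mm^3) per day.
#' @param kind `"front_position_mm"` or `"stained_volume_mm3"`.
#' @param reference_total_mm3 fully stained tissue volume, when known.
#' @param lower,upper optional per-day bounds (pitch uncertainty).
#' @return An `uptake_series` data frame with attributes `kind` and
#'   `reference_total_mm3`.
#' @export
uptake_series <- function(days, values, kind = c("front_position_mm",
                                                 "stained_volume_mm3"),
                          reference_total_mm3 = NA_real_,
                          lower = NULL, upper = NULL) {
  kind <- match.arg(kind)
  if (length(days) != length(values)) stopf("days and values lengths differ")
  if (any(diff(days) <= 0)) stopf("days must be strictly increasing")
  df <- data.frame(day = as.numeric(days), value = as.numeric(values))
  if (!is.null(lower)) df$lower <- lower
  if (!is.null(upper)) df$upper <- upper
  if (kind == "stained_volume_mm3" && !is.na(reference_total_mm3)) {
    df$fraction <- df$value / reference_total_mm3
    tol <- if (!is.null(upper)) max(upper - values, 0) else 1e-9
    if (any(df$value > reference_total_mm3 + tol))
      stopf("stained volume exceeds the reference total")
  }
  structure(df, kind = kind, reference_total_mm3 = reference_total_mm3,
            class = c("uptake_series", "data.frame"))
}

#' Uptake rate from an uptake series
#'
#' Ordinary least-squares slope of position (or stained volume) against
#' staining day, with its standard error. Gaps between days are allowed and
#' never interpolated. With exactly two days the slope is the difference
#' quotient and no standard error is available.
#'
#' @param series an [uptake_series()], or a data frame with columns `day`
#'   and `value`.
#' @return List with `rate` (mm/day or mm^3/day), `se`, `intercept`, `n`,
#'   and `fit` (the `lm` object, or NULL for two days).
#' @export
uptake_rate <- function(series) {
  if (!is.data.frame(series)) stopf("`series` must be an uptake series")
  if (nrow(series) < 2) stopf("insufficient data: need at least 2 days")
  if (nrow(series) == 2) {
    rate <- diff(series$value) / diff(series$day)
    return(list(rate = rate, se = NA_real_,
                intercept = series$value[1] - rate * series$day[1],
                n = 2L, fit = NULL))
  }
  fit <- stats::lm(value ~ day, data = series)
  # noiseless phantoms fit exactly; the perfect-fit warning is expected there
  sm <- suppressWarnings(summary(fit))$coefficients
  list(rate = unname(sm["day", "Estimate"]), se = unname(sm["day", "Std. Error"]),
       intercept = unname(sm["(Intercept)", "Estimate"]), n = nrow(series),
       fit = fit)
}

#' Stained-volume trajectory of one tissue across days
#'
#' Per day, the stained volume is the count of tissue voxels at or above
#' the stained threshold times the voxel volume, with pitch-uncertainty
#' bounds; the reference total is the whole tissue's voxel volume; the
#' stained fraction is their ratio. Volumes must share shape and pitch with
#' the mask — no registration is attempted.
#'
#' @param volumes named or unnamed list of per-day [voxel_volume()]s.
#' @param days staining day of each volume.
#' @param mask a [label_mask()] shared by all days.
#' @param tissue_label tissue to measure.
#' @param stained_threshold normalized stained-voxel threshold (default 0.4).
#' @param pitch_uncertainty_um voxel-pitch uncertainty for the bounds.
#' @return An [uptake_series()] of kind `stained_volume_mm3` with `fraction`
#'   and bound columns.
#' @export
stained_volume_trajectory <- function(volumes, days, mask, tissue_label,
                                      stained_threshold = DEFAULT_THRESHOLD,
                                      pitch_uncertainty_um = PITCH_UNCERTAINTY_UM) {
  stopifnot(inherits(mask, "label_mask"))
  if (length(volumes) != length(days)) stopf("one volume per day required")
  tid <- label_id(mask, tissue_label)
  tissue <- mask$data == tid
  n_total <- sum(tissue)
  pitch <- volumes[[1]]$voxel_size_um
  vals <- lower <- upper <- numeric(length(volumes))
  for (i in seq_along(volumes)) {
    v <- volumes[[i]]
    stopifnot(inherits(v, "voxel_volume"))
    if (!identical(dim(v$data), dim(mask$data)))
      stopf("alignment error: day %s volume shape differs from mask", days[i])
    if (abs(v$voxel_size_um - pitch) > 1e-9)
      stopf("alignment error: voxel pitch differs across days")
    if (!is_normalized(v)) v <- suppressMessages(normalize_volume(v))
    n_stained <- sum(v$data[tissue] >= stained_threshold)
    vb <- volume_from_voxels(n_stained, pitch, pitch_uncertainty_um)
    vals[i] <- vb$volume_mm3; lower[i] <- vb$lower_mm3; upper[i] <- vb$upper_mm3
  }
  ref <- volume_from_voxels(n_total, pitch, pitch_uncertainty_um)$volume_mm3
  uptake_series(days, vals, "stained_volume_mm3", reference_total_mm3 = ref,
                lower = lower, upper = upper)
}

#' Fit an error-function staining-front model
#'
#' The 1-D diffusion picture gives a stained fraction that falls off as an
#' error function of distance ahead of a front advancing at constant
#' velocity: `fraction(x, t) = plateau / 2 * erfc((x - v (t - onset)) / w)`.
#' Fitted by Levenberg-Marquardt least squares to per-slab stained-fraction
#' profiles pooled over days. Non-convergence is reported in the result,
#' never silently.
#'
#' @param profiles data frame with columns `distance_mm`, `day`, `fraction`
#'   (e.g. pooled [front_position()] profiles over days).
#' @param start optional named list overriding the starting values for `v`
#'   (mm/day), `onset` (day), `width` (mm), `plateau`.
#' @param fit_plateau fit the plateau level too, or fix it at 1.
#' @return A `front_model`: `velocity_mm_per_day`, `onset_day`, `width_mm`,
#'   `plateau`, `converged`, `residual_norm`, `message`, `fit`.
#' @export
fit_front_model <- function(profiles, start = NULL, fit_plateau = FALSE) {
  need <- c("distance_mm", "day", "fraction")
  if (!all(need %in% names(profiles)))
    stopf("`profiles` needs columns %s", paste(need, collapse = ", "))
  if (nrow(profiles) < 3) stopf("insufficient data: need at least 3 observations")
  df <- profiles

  # heuristics: per-day half-crossing distances give a slope for v
  cross <- vapply(split(df, df$day), function(d) {
    d <- d[order(d$distance_mm), ]
    i <- which(d$fraction < 0.5)[1]
    if (is.na(i) || i == 1) return(NA_real_)
    d$distance_mm[i - 1]
  }, 0)
  days_u <- as.numeric(names(cross))
  ok <- !is.na(cross)
  v0 <- if (sum(ok) >= 2) max(stats::cov(days_u[ok], cross[ok]) /
                                stats::var(days_u[ok]), 1e-3) else 0.1
  b0 <- if (sum(ok) >= 2) mean(cross[ok]) - v0 * mean(days_u[ok]) else 0
  width0 <- max(diff(range(df$distance_mm)) / 20, 1e-3)
  # fitted front centre is v * day + b; the onset/velocity form v*(day-onset)
  # is recovered as onset = -b / v (it is ill-conditioned to fit directly)
  st <- list(v = v0, b = b0, width = width0, plateau = 1)
  if (!is.null(start)) {
    start <- as.list(start)
    if (!is.null(start$onset)) {
      start$b <- -start$onset * (start$v %||% v0)
      start$onset <- NULL
    }
    st <- utils::modifyList(st, start)
  }

  form <- if (fit_plateau)
    fraction ~ plateau / 2 * erfc((distance_mm - v * day - b) / width)
  else
    fraction ~ 0.5 * erfc((distance_mm - v * day - b) / width)
  if (!fit_plateau) st$plateau <- NULL
  fit <- tryCatch(
    minpack.lm::nlsLM(form, data = df, start = st,
                      lower = c(v = 0, b = -Inf, width = 1e-6,
                                plateau = 0)[names(st)],
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) e)
  if (inherits(fit, "error")) {
    return(structure(list(velocity_mm_per_day = NA_real_, onset_day = NA_real_,
                          width_mm = NA_real_, plateau = NA_real_,
                          converged = FALSE, residual_norm = NA_real_,
                          message = conditionMessage(fit), fit = NULL),
                     class = "front_model"))
  }
  cf <- stats::coef(fit)
  structure(list(velocity_mm_per_day = unname(cf["v"]),
                 onset_day = if (cf["v"] > 0) unname(-cf["b"] / cf["v"]) else NA_real_,
                 width_mm = unname(cf["width"]),
                 plateau = if (fit_plateau) unname(cf["plateau"]) else 1,
                 converged = fit$convInfo$isConv %||% TRUE,
                 residual_norm = sqrt(sum(stats::resid(fit)^2)),
                 message = if (isTRUE(fit$convInfo$isConv)) "converged"
                           else fit$convInfo$stopMessage %||% "not converged",
                 fit = fit),
            class = "front_model")
}

#' @export
print.front_model <- function(x, ...) {
  if (!x$converged) {
    cat("<front_model> fit failed:", x$message, "\n")
  } else {
    cat(sprintf("<front_model> v = %.4g mm/day, onset day %.3g, width %.4g mm, plateau %.3g\n",
                x$velocity_mm_per_day, x$onset_day, x$width_mm, x$plateau))
  }
  invisible(x)
}
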