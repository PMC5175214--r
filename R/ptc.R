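#' Labelled greyvalue population
#'
#' The greyvalues sampled from one tissue (or from the background), with
#' provenance. This is the unit the Gaussian contrast model is fitted to.
#'
#' @param values numeric vector of greyvalues.
#' @param label tissue name.
#' @param source free-text provenance (e.g. "mask" or a file name).
#' @return A `labelled_population` object.
#' @export
labelled_population <- function(values, label, source = "unspecified") {
  if (!is.numeric(values)) stopf("greyvalues must be numeric")
  structure(list(values = as.numeric(values), label = as.character(label),
                 source = source),
            class = "labelled_population")
}

#' Extract labelled populations from a volume + mask pair
#'
#' One population per nonzero label in the mask (or per requested label),
#' holding that label's voxel greyvalues.
#'
#' @param volume a [voxel_volume()].
#' @param mask a [label_mask()] of the same shape.
#' @param labels tissue names to extract; default all named labels.
#' @return Named list of [labelled_population()]s.
#' @export
populations_from_mask <- function(volume, mask, labels = NULL) {
  stopifnot(inherits(volume, "voxel_volume"), inherits(mask, "label_mask"))
  if (!identical(dim(volume$data), dim(mask$data)))
    stopf("volume and mask shapes differ")
  if (is.null(labels)) labels <- unname(mask$label_names)
  out <- lapply(labels, function(lb) {
    id <- label_id(mask, lb)
    labelled_population(volume$data[mask$data == id], lb, source = "mask")
  })
  stats::setNames(out, labels)
}

#' Population from a two-column delimited text file
#'
#' Reads `label, greyvalue` rows (header optional) and returns the
#' populations found, one per distinct label.
#'
#' @param path delimited text file with columns label and greyvalue.
#' @param sep field separator.
#' @return Named list of [labelled_population()]s.
#' @export
read_populations <- function(path, sep = ",") {
  df <- utils::read.table(path, sep = sep, stringsAsFactors = FALSE)
  if (ncol(df) < 2) stopf("expected two columns (label, greyvalue) in %s", path)
  if (is.na(suppressWarnings(as.numeric(df[1, 2])))) df <- df[-1, , drop = FALSE]
  vals <- as.numeric(df[[2]])
  labs <- as.character(df[[1]])
  out <- lapply(unique(labs), function(lb)
    labelled_population(vals[labs == lb], lb, source = path))
  stats::setNames(out, unique(labs))
}

# Threshold below which a fitted model carries a small-sample warning: a
# misclassification probability of 1e-3 cannot be supported by fewer than
# 1000 voxels.
SMALL_SAMPLE_N <- 1000L

#' Fit a Gaussian greyvalue model to a population
#'
#' Moment fit: arithmetic mean and n-1 sample standard deviation, the
#' maximum-likelihood mean with the conventional sd under the Gaussian
#' assumption. Populations smaller than 1000 voxels are flagged, since small
#' contrast probabilities cannot be asserted from small samples.
#'
#' @param population a [labelled_population()] or a numeric vector.
#' @param label tissue name when a bare numeric vector is given.
#' @return A `gaussian_model` with fields `mean`, `sd`, `n`, `label`,
#'   `warnings`.
#' @export
fit_gaussian <- function(population, label = NULL) {
  if (is.numeric(population))
    population <- labelled_population(population, label %||% "population")
  stopifnot(inherits(population, "labelled_population"))
  v <- population$values
  if (!length(v)) stopf("empty population \"%s\"", population$label)
  if (length(v) < 2) stopf("population \"%s\" has fewer than 2 values", population$label)
  s <- stats::sd(v)
  if (s == 0)
    stopf("degenerate distribution: population \"%s\" is constant (sd = 0)",
          population$label)
  warnings <- character()
  if (length(v) < SMALL_SAMPLE_N)
    warnings <- sprintf("small sample: n = %d < %d; contrast probabilities below 1/n are not supported by the data",
                        length(v), SMALL_SAMPLE_N)
  gaussian_model(mean(v), s, length(v), population$label, warnings)
}

#' @rdname fit_gaussian
#' @param mean,sd,n,warnings model fields, for direct construction from known
#'   parameters.
#' @export
gaussian_model <- function(mean, sd, n = SMALL_SAMPLE_N, label = "model",
                           warnings = character()) {
  if (!is_scalar_number(sd) || sd <= 0) stopf("`sd` must be a positive number")
  if (n < 2) stopf("`n` must be at least 2")
  structure(list(mean = as.numeric(mean), sd = as.numeric(sd),
                 n = as.integer(n), label = as.character(label),
                 warnings = warnings),
            class = "gaussian_model")
}

#' @export
print.gaussian_model <- function(x, ...) {
  cat(sprintf("<gaussian_model> %s: mean %.5g, sd %.5g (n = %d)\n",
              x$label, x$mean, x$sd, x$n))
  for (w in x$warnings) cat("  warning:", w, "\n")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Relative sd tolerance under which the two-Gaussian intersection quadratic
# is treated as the degenerate equal-variance case (it becomes numerically
# singular as the variances coincide).
EQUAL_SIGMA_RTOL <- 1e-9

#' Intersection points of two Gaussian densities
#'
#' Equates the two density formulae and solves the resulting quadratic in x.
#' Unequal variances give two real roots; equal variances (within a relative
#' tolerance of 1e-9, where the quadratic degenerates) with distinct means
#' give the single midpoint `(mean1 + mean2) / 2`.
#'
#' @param g1,g2 [gaussian_model()]s.
#' @return Numeric vector of one or two intersection abscissae (sorted).
#'   Identical distributions have no isolated intersection and are an error;
#'   [ptc_pair()] handles that case upstream.
#' @export
intersection_points <- function(g1, g2) {
  stopifnot(inherits(g1, "gaussian_model"), inherits(g2, "gaussian_model"))
  m1 <- g1$mean; s1 <- g1$sd; m2 <- g2$mean; s2 <- g2$sd
  if (abs(s1 - s2) <= EQUAL_SIGMA_RTOL * max(s1, s2)) {
    if (m1 == m2)
      stopf("identical distributions: densities coincide everywhere, no isolated intersection")
    return((m1 + m2) / 2)
  }
  # log f1(x) = log f2(x)  =>  a x^2 + b x + c = 0
  a <- 1 / (2 * s2^2) - 1 / (2 * s1^2)
  b <- m1 / s1^2 - m2 / s2^2
  c <- m2^2 / (2 * s2^2) - m1^2 / (2 * s1^2) + log(s2 / s1)
  disc <- b^2 - 4 * a * c
  # the parabola is negative at the narrow Gaussian's mean, so disc > 0 always
  sq <- sqrt(max(disc, 0))
  sort(c((-b - sq) / (2 * a), (-b + sq) / (2 * a)))
}

#' Probabilistic tissue contrast between two Gaussian models
#'
#' The PTC is the overlap of the two fitted greyvalue densities,
#' `integral of min(f1(x), f2(x)) dx`: the sum of the two conditional
#' misclassification probabilities when voxels are assigned to tissues by
#' thresholding at the density intersection point(s). It lies in `[0, 1]`:
#' 1 for indistinguishable tissues, near 0 for well-separated ones. A PTC of
#' about 1e-3 (one misassigned voxel per thousand) marks the level at which
#' automatic thresholding becomes practical.
#'
#' Evaluated in closed form via Gaussian CDFs at the intersection points:
#' with the narrower distribution second, the overlap is
#' `F2(xA) + [F1(xB) - F1(xA)] + [1 - F2(xB)]`; with equal sds it reduces to
#' `2 * Phi(-|mean1 - mean2| / (2 sd))`; identical distributions give exactly 1.
#'
#' @param g1,g2 [gaussian_model()]s (or [labelled_population()]s, which are
#'   fitted first).
#' @return A `ptc_result` with fields `ptc`, `x_A`, `x_B`, `method`
#'   (`"two_intersection"`, `"equal_sigma"` or `"identical"`), `labels`,
#'   `components` (for one-vs-rest results) and `warnings`.
#' @export
ptc_pair <- function(g1, g2) {
  if (inherits(g1, "labelled_population")) g1 <- fit_gaussian(g1)
  if (inherits(g2, "labelled_population")) g2 <- fit_gaussian(g2)
  stopifnot(inherits(g1, "gaussian_model"), inherits(g2, "gaussian_model"))
  labels <- c(g1$label, g2$label)
  warnings <- unique(c(g1$warnings, g2$warnings))

  equal_sd <- abs(g1$sd - g2$sd) <= EQUAL_SIGMA_RTOL * max(g1$sd, g2$sd)
  if (equal_sd && g1$mean == g2$mean) {
    return(ptc_result(1, NA_real_, NA_real_, "identical", labels, warnings))
  }
  if (equal_sd) {
    x <- (g1$mean + g2$mean) / 2
    ptc <- 2 * stats::pnorm(-abs(g1$mean - g2$mean) / (2 * max(g1$sd, g2$sd)))
    return(ptc_result(ptc, x, NA_real_, "equal_sigma", labels, warnings))
  }
  # order so that `narrow` has the smaller sd; the overlap density is the
  # wide Gaussian between the intersections and the narrow one outside
  if (g1$sd > g2$sd) { wide <- g1; narrow <- g2 } else { wide <- g2; narrow <- g1 }
  x <- intersection_points(wide, narrow)
  ptc <- stats::pnorm(x[1], narrow$mean, narrow$sd) +
    (stats::pnorm(x[2], wide$mean, wide$sd) -
       stats::pnorm(x[1], wide$mean, wide$sd)) +
    stats::pnorm(x[2], narrow$mean, narrow$sd, lower.tail = FALSE)
  ptc_result(min(max(ptc, 0), 1), x[1], x[2], "two_intersection", labels, warnings)
}

ptc_result <- function(ptc, x_A, x_B, method, labels,
                       warnings = character(), components = NULL, mode = NULL) {
  structure(list(ptc = ptc, x_A = x_A, x_B = x_B, method = method,
                 labels = labels, components = components, mode = mode,
                 warnings = warnings),
            class = "ptc_result")
}

#' @export
print.ptc_result <- function(x, ...) {
  cat(sprintf("<ptc_result> %s vs %s: PTC = %.4g (%s)\n",
              x$labels[1], paste(x$labels[-1], collapse = " + "),
              x$ptc, x$method))
  if (!is.na(x$x_A)) {
    if (is.na(x$x_B)) cat(sprintf("  intersection at x = %.6g\n", x$x_A))
    else cat(sprintf("  intersections at x_A = %.6g, x_B = %.6g\n", x$x_A, x$x_B))
  }
  if (!is.null(x$components))
    cat(sprintf("  pairwise components (%s): %s\n", x$mode,
                paste(signif(x$components, 4), collapse = ", ")))
  for (w in x$warnings) cat("  warning:", w, "\n")
  invisible(x)
}

#' Tissue-vs-background PTC
#'
#' Fits Gaussian models to both populations and returns their pairwise PTC;
#' the comparison used to judge whether a tissue can be thresholded out of
#' the surrounding liquid automatically.
#'
#' @param tissue,background [labelled_population()]s.
#' @return A `ptc_result`; see [ptc_pair()].
#' @export
ptc_vs_background <- function(tissue, background) {
  ptc_pair(fit_gaussian(tissue), fit_gaussian(background))
}

#' One-vs-rest PTC (overall discriminability)
#'
#' Contrasts one tissue against all others. `sum_pairwise` (default) adds
#' the pairwise overlaps and clips at 1, the cumulative-overlap reading of a
#' tissue's overall discriminability; `pooled_mixture` integrates
#' `min(f_target, g)` where `g` is the equal-weight mixture of the other
#' tissues' fitted densities, by trapezoidal quadrature.
#'
#' @param target a [labelled_population()] or [gaussian_model()].
#' @param others list of populations or models to contrast against.
#' @param mode `"sum_pairwise"` or `"pooled_mixture"`.
#' @return A `ptc_result` recording the mode and the pairwise components.
#' @export
ptc_one_vs_rest <- function(target, others, mode = c("sum_pairwise", "pooled_mixture")) {
  mode <- match.arg(mode)
  if (!is.list(others) || inherits(others, c("labelled_population", "gaussian_model")))
    others <- list(others)
  if (!length(others)) stopf("`others` must contain at least one population")
  as_model <- function(x) if (inherits(x, "gaussian_model")) x else fit_gaussian(x)
  gt <- as_model(target)
  go <- lapply(others, as_model)
  pair <- lapply(go, function(g) ptc_pair(gt, g))
  comps <- vapply(pair, function(p) p$ptc, 0)
  names(comps) <- vapply(go, function(g) g$label, "")
  warnings <- unique(unlist(lapply(pair, function(p) p$warnings)))
  if (mode == "sum_pairwise") {
    ptc <- min(1, sum(comps))
  } else {
    means <- c(gt$mean, vapply(go, function(g) g$mean, 0))
    sds <- c(gt$sd, vapply(go, function(g) g$sd, 0))
    grid <- seq(min(means) - 8 * max(sds), max(means) + 8 * max(sds),
                length.out = 1e5)
    f_t <- stats::dnorm(grid, gt$mean, gt$sd)
    g_mix <- Reduce(`+`, lapply(go, function(g) stats::dnorm(grid, g$mean, g$sd))) /
      length(go)
    ptc <- min(1, trapz(grid, pmin(f_t, g_mix)))
  }
  ptc_result(ptc, NA_real_, NA_real_, "one_vs_rest",
             c(gt$label, names(comps)), warnings,
             components = comps, mode = mode)
}

trapz <- function(x, y) sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)

#' Pairwise PTC matrix
#'
#' Tabulates the pairwise PTC for every pair of populations: a symmetric
#' matrix with unit diagonal. The full `ptc_result` objects sit in the
#' `"details"` attribute.
#'
#' @param populations list (length >= 2) of [labelled_population()]s or
#'   [gaussian_model()]s.
#' @return Numeric matrix with tissue names as dimnames.
#' @export
ptc_matrix <- function(populations) {
  if (length(populations) < 2) stopf("need at least 2 populations")
  models <- lapply(populations, function(p)
    if (inherits(p, "gaussian_model")) p else fit_gaussian(p))
  labels <- vapply(models, function(m) m$label, "")
  k <- length(models)
  m <- diag(1, k)
  dimnames(m) <- list(labels, labels)
  details <- list()
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    r <- ptc_pair(models[[i]], models[[j]])
    m[i, j] <- m[j, i] <- r$ptc
    details[[paste(labels[i], labels[j], sep = "|")]] <- r
  }
  attr(m, "details") <- details
  m
}

#' Export PTC results as a delimited table and/or JSON
#'
#' @param results a list of `ptc_result`s, or a [ptc_matrix()] output.
#' @param path output path; `.json` writes JSON, anything else a CSV table
#'   with columns labels, mean/sd/n per model when available, x_A, x_B,
#'   method, ptc, warnings.
#' @export
export_ptc <- function(results, path) {
  if (is.matrix(results)) results <- attr(results, "details")
  if (inherits(results, "ptc_result")) results <- list(results)
  rows <- lapply(results, function(r) data.frame(
    label_1 = r$labels[1], label_2 = paste(r$labels[-1], collapse = "+"),
    x_A = r$x_A, x_B = r$x_B, method = r$method, ptc = r$ptc,
    warnings = paste(r$warnings, collapse = "; "),
    stringsAsFactors = FALSE))
  df <- do.call(rbind, rows)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(lapply(results, unclass), path, auto_unbox = TRUE,
                         digits = NA, null = "null", na = "null")
  } else {
    utils::write.table(df, path, sep = ",", row.names = FALSE, quote = FALSE)
  }
  invisible(df)
}
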