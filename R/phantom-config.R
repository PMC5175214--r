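# Plain-text phantom configuration: INI-style sections of key = value
# lines. Sections: [volume] (shape_z/y/x, voxel_size_um, seed),
# [background] (mean, sd), [front] (axis, incision_index,
# velocity_mm_per_day, width_mm, days), and one [tissue <name>] per
# primitive. Numeric values may be space-separated vectors.

parse_config_value <- function(x) {
  x <- trimws(x)
  parts <- strsplit(x, "[[:space:]]+")[[1]]
  nums <- suppressWarnings(as.numeric(parts))
  if (!anyNA(nums)) nums else x
}

read_config_sections <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  sections <- list()
  current <- NULL
  for (ln in lines) {
    if (grepl("^\\[.*\\]$", ln)) {
      current <- sub("^\\[(.*)\\]$", "\\1", ln)
      sections[[current]] <- list()
    } else if (grepl("=", ln, fixed = TRUE)) {
      if (is.null(current)) stopf("config line before any [section]: %s", ln)
      kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
      sections[[current]][[trimws(kv[1])]] <-
        parse_config_value(paste(kv[-1], collapse = "="))
    }
  }
  sections
}

#' Read a phantom specification from a plain-text config
#'
#' @param path config file; see [write_phantom_config()] for the layout.
#' @return A [phantom_spec()].
#' @export
read_phantom_config <- function(path) {
  s <- read_config_sections(path)
  if (is.null(s$volume)) stopf("config %s lacks a [volume] section", path)
  vol <- s$volume
  tissue_secs <- grep("^tissue ", names(s), value = TRUE)
  tissues <- lapply(tissue_secs, function(nm) {
    t <- s[[nm]]
    name <- sub("^tissue ", "", nm)
    size <- switch(t$primitive,
      ellipsoid = list(semi_axes_mm = t$semi_axes_mm),
      cylinder = list(radius_mm = t$radius_mm, length_mm = t$length_mm,
                      axis = t$axis %||% "z"),
      sheet = list(thickness_mm = t$thickness_mm, normal = t$normal %||% "y",
                   extent_mm = t$extent_mm),
      blobs = list(radius_mm = t$radius_mm,
                   centers_mm = matrix(t$centers_mm, ncol = 3, byrow = TRUE)),
      stopf("tissue \"%s\": unknown primitive \"%s\"", name, t$primitive))
    phantom_tissue(name, t$primitive, center_mm = t$center_mm, size = size,
                   stained_mean = t$stained_mean, stained_sd = t$stained_sd,
                   unstained_mean = t$unstained_mean %||% 0.08,
                   unstained_sd = t$unstained_sd %||% 0.015)
  })
  fr <- s$front %||% list()
  phantom_spec(shape = c(vol$shape_z, vol$shape_y, vol$shape_x),
               voxel_size_um = vol$voxel_size_um,
               tissues = tissues,
               background_mean = s$background$mean %||% 0.05,
               background_sd = s$background$sd %||% 0.01,
               front = list(axis = fr$axis %||% "z",
                            incision_index = as.integer(fr$incision_index %||% 1),
                            velocity_mm_per_day = fr$velocity_mm_per_day %||% 0.17,
                            width_mm = fr$width_mm %||% 0.05,
                            days = fr$days %||% 3:7),
               seed = as.integer(vol$seed %||% 1))
}

#' Write a phantom specification as a plain-text config
#'
#' @param spec a [phantom_spec()].
#' @param path output file.
#' @export
write_phantom_config <- function(spec, path) {
  stopifnot(inherits(spec, "phantom_spec"))
  fmt <- function(v) paste(v, collapse = " ")
  out <- c("[volume]",
           paste("shape_z =", spec$shape[1]), paste("shape_y =", spec$shape[2]),
           paste("shape_x =", spec$shape[3]),
           paste("voxel_size_um =", spec$voxel_size_um),
           paste("seed =", spec$seed),
           "", "[background]",
           paste("mean =", spec$background_mean), paste("sd =", spec$background_sd),
           "", "[front]",
           paste("axis =", spec$front$axis),
           paste("incision_index =", spec$front$incision_index),
           paste("velocity_mm_per_day =", spec$front$velocity_mm_per_day),
           paste("width_mm =", spec$front$width_mm),
           paste("days =", fmt(spec$front$days)))
  for (t in spec$tissues) {
    out <- c(out, "", sprintf("[tissue %s]", t$name),
             paste("primitive =", t$primitive))
    if (!is.null(t$center_mm)) out <- c(out, paste("center_mm =", fmt(t$center_mm)))
    s <- t$size
    out <- c(out, switch(t$primitive,
      ellipsoid = paste("semi_axes_mm =", fmt(s$semi_axes_mm)),
      cylinder = c(paste("radius_mm =", s$radius_mm),
                   paste("length_mm =", s$length_mm), paste("axis =", s$axis)),
      sheet = c(paste("thickness_mm =", s$thickness_mm),
                paste("normal =", s$normal), paste("extent_mm =", fmt(s$extent_mm))),
      blobs = c(paste("radius_mm =", s$radius_mm),
                paste("centers_mm =", fmt(t(s$centers_mm))))))
    out <- c(out,
             paste("stained_mean =", t$stained_mean),
             paste("stained_sd =", t$stained_sd),
             paste("unstained_mean =", t$unstained_mean),
             paste("unstained_sd =", t$unstained_sd))
  }
  writeLines(out, path)
  invisible(path)
}
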