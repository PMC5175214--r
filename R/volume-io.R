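#' Construct a voxel volume
#'
#' The universal image container: a 3D greyvalue grid with its isotropic
#' voxel pitch. Axis order is slice-major `(z, y, x)`, i.e. `data[z, , ]` is
#' one reconstructed slice. Greyvalues are either unsigned integers (8- or
#' 16-bit, as reconstructions are exported) or reals in `[0, 1]` after
#' [normalize_volume()].
#'
#' @param data 3D numeric array, axis order `(z, y, x)`.
#' @param voxel_size_um positive isotropic voxel edge length in micrometres.
#' @param bit_depth `8`, `16`, or `"normalized"` for real values in `[0, 1]`.
#' @return A `voxel_volume` object.
#' @export
voxel_volume <- function(data, voxel_size_um, bit_depth = 16) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stopf("`data` must be a 3D array (z, y, x)")
  if (any(dim(data) < 1L)) stopf("all three extents must be positive")
  if (!is_scalar_number(voxel_size_um) || voxel_size_um <= 0)
    stopf("`voxel_size_um` must be a positive number")
  if (identical(bit_depth, "normalized")) {
    if (any(data < 0 | data > 1)) stopf("normalized greyvalues must lie in [0, 1]")
  } else {
    if (!bit_depth %in% c(8, 16)) stopf("`bit_depth` must be 8, 16 or \"normalized\"")
    maxv <- 2^bit_depth - 1
    if (any(data < 0) || any(data > maxv))
      stopf("greyvalues must lie in [0, %d] for bit depth %d", maxv, bit_depth)
  }
  structure(
    list(data = data, voxel_size_um = as.numeric(voxel_size_um), bit_depth = bit_depth),
    class = "voxel_volume"
  )
}

#' @export
print.voxel_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<voxel_volume> %d x %d x %d (z,y,x), %s, voxel %.3g um\n",
              d[1], d[2], d[3],
              if (identical(x$bit_depth, "normalized")) "normalized [0,1]"
              else paste0(x$bit_depth, "-bit"),
              x$voxel_size_um))
  invisible(x)
}

#' @export
dim.voxel_volume <- function(x) dim(x$data)

is_normalized <- function(volume) identical(volume$bit_depth, "normalized")

#' Construct a label mask
#'
#' Voxel-wise integer labels accompanying a [voxel_volume()]; label 0 is
#' reserved for unassigned voxels. `label_names` maps each nonzero label
#' present in the mask to a tissue name.
#'
#' @param data 3D integer array, same shape as the companion volume.
#' @param label_names named character vector; names are the integer labels
#'   (as strings), values are tissue names, e.g. `c("1" = "large_muscle")`.
#' @return A `label_mask` object.
#' @export
label_mask <- function(data, label_names) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stopf("`data` must be a 3D array (z, y, x)")
  storage.mode(data) <- "integer"
  if (any(data < 0L)) stopf("labels must be non-negative integers")
  present <- setdiff(sort(unique(as.vector(data))), 0L)
  if (is.null(names(label_names)) && length(label_names) == length(present))
    names(label_names) <- as.character(present)
  missing <- setdiff(as.character(present), names(label_names))
  if (length(missing))
    stopf("labels present in mask but absent from label_names: %s",
          paste(missing, collapse = ", "))
  structure(list(data = data, label_names = label_names), class = "label_mask")
}

#' @export
print.label_mask <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<label_mask> %d x %d x %d, %d labelled tissue(s): %s\n",
              d[1], d[2], d[3], length(x$label_names),
              paste(x$label_names, collapse = ", ")))
  invisible(x)
}

# Label integer for a tissue name; errors if absent.
label_id <- function(mask, tissue_label) {
  hit <- names(mask$label_names)[mask$label_names == tissue_label]
  if (!length(hit))
    stopf("label \"%s\" not present in mask (have: %s)", tissue_label,
          paste(mask$label_names, collapse = ", "))
  as.integer(hit[1])
}

# ---------------------------------------------------------------------------
# Readers and writers. Canonical interchange formats:
#  * TIFF: unsigned 8/16-bit greyscale, multi-page file (pages = z) or a
#    directory of single-page files stacked in lexicographic filename order.
#    A sidecar "<path>.meta" carries voxel_size_um (key = value lines).
#  * Raw + metadata: little-endian unsigned integers, z-major order, with a
#    sidecar "<path>.meta" giving shape_z, shape_y, shape_x, dtype
#    (uint8|uint16) and voxel_size_um.

read_sidecar <- function(path) {
  if (!file.exists(path)) return(list())
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  kv <- strsplit(lines, "=", fixed = TRUE)
  out <- list()
  for (p in kv) {
    if (length(p) < 2) next
    out[[trimws(p[1])]] <- trimws(paste(p[-1], collapse = "="))
  }
  out
}

write_sidecar <- function(path, fields) {
  writeLines(paste(names(fields), unlist(fields), sep = " = "), path)
}

#' Read a 3D greyscale volume
#'
#' Reads either a multi-page TIFF (or a directory of single-page TIFFs,
#' stacked in filename-sorted z order) or a raw binary volume with a
#' `<path>.meta` sidecar. Greyvalues are returned unmodified.
#'
#' @param path a TIFF file, a directory of TIFF slices, or a raw file with
#'   sidecar metadata.
#' @param voxel_size_um voxel pitch in micrometres; may be omitted when the
#'   sidecar metadata provides it. Supplying both consistently is allowed;
#'   contradictory values are a configuration error.
#' @return A [voxel_volume()].
#' @export
read_volume <- function(path, voxel_size_um = NULL) {
  if (!file.exists(path)) stopf("no such file or directory: %s", path)
  meta <- read_sidecar(paste0(sub("/$", "", path), ".meta"))
  meta_pitch <- if (!is.null(meta$voxel_size_um)) as.numeric(meta$voxel_size_um) else NULL
  pitch <- resolve_pitch(voxel_size_um, meta_pitch, path)

  depth <- if (!is.null(meta$bit_depth)) as.numeric(meta$bit_depth) else NULL
  if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.tiff?$", ignore.case = TRUE,
                             full.names = TRUE))
    if (!length(files)) stopf("directory contains no TIFF slices: %s", path)
    pages <- lapply(files, function(f) tiff::readTIFF(f, as.is = TRUE))
    return(stack_pages(pages, pitch, path, depth))
  }
  if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    return(stack_pages(pages, pitch, path, depth))
  }
  read_raw_volume(path, meta, pitch)
}

resolve_pitch <- function(arg, meta, path) {
  if (is.null(arg) && is.null(meta))
    stopf("voxel size for %s given neither as argument nor in sidecar metadata", path)
  if (!is.null(arg) && !is.null(meta) &&
      abs(arg - meta) > 1e-9 * max(arg, meta))
    stopf("contradictory voxel sizes for %s: argument %g vs metadata %g um",
          path, arg, meta)
  if (!is.null(arg)) arg else meta
}

stack_pages <- function(pages, pitch, path, depth = NULL) {
  shapes <- vapply(pages, function(p) dim(p)[1:2], integer(2))
  if (any(shapes[1, ] != shapes[1, 1]) || any(shapes[2, ] != shapes[2, 1]))
    stopf("ragged slice shapes in %s", path)
  if (any(!vapply(pages, function(p) is.matrix(p) || length(dim(p)) == 2L, TRUE)))
    stopf("non-greyscale (multi-channel) TIFF in %s", path)
  maxv <- max(vapply(pages, max, 0))
  # bit depth from sidecar metadata when recorded, else the smallest depth
  # that holds the data
  if (is.null(depth)) depth <- if (maxv > 255) 16 else 8
  if (!depth %in% c(8, 16)) stopf("unsupported bit depth %s in %s", depth, path)
  if (maxv > 2^depth - 1)
    stopf("greyvalues exceed the recorded %d-bit depth in %s", depth, path)
  nz <- length(pages)
  arr <- array(0, dim = c(nz, shapes[1, 1], shapes[2, 1]))
  for (z in seq_len(nz)) arr[z, , ] <- pages[[z]]
  voxel_volume(arr, pitch, depth)
}

read_raw_volume <- function(path, meta, pitch) {
  need <- c("shape_z", "shape_y", "shape_x", "dtype")
  if (!all(need %in% names(meta)))
    stopf("raw volume %s needs sidecar keys: %s", path, paste(need, collapse = ", "))
  shp <- as.integer(c(meta$shape_z, meta$shape_y, meta$shape_x))
  dtype <- meta$dtype
  if (!dtype %in% c("uint8", "uint16")) stopf("unsupported dtype \"%s\"", dtype)
  size <- if (dtype == "uint8") 1L else 2L
  n <- prod(shp)
  raw <- readBin(path, "integer", n = n, size = size, signed = FALSE,
                 endian = "little")
  if (length(raw) != n)
    stopf("raw file %s holds %d voxels, metadata promises %d", path, length(raw), n)
  # file is z-major (slice, row, column): fill an (x, y, z) array then permute
  arr <- aperm(array(raw, dim = rev(shp)), c(3, 2, 1))
  voxel_volume(arr, pitch, if (dtype == "uint8") 8 else 16)
}

#' Write a 3D greyscale volume
#'
#' Writes `.tif`/`.tiff` (multi-page, one page per slice) or `.raw`
#' (little-endian, z-major) with a `<path>.meta` sidecar carrying the voxel
#' pitch (and, for raw, shape and dtype). The output round-trips through
#' [read_volume()] bit-identically.
#'
#' Normalized volumes hold reals in `[0, 1]` and have no integer
#' representation; writing one requires `rescale_bits` (8 or 16) to make the
#' quantisation explicit — it is never done silently.
#'
#' @param volume a [voxel_volume()].
#' @param path output file ending in `.tif`, `.tiff` or `.raw`.
#' @param rescale_bits for normalized input only: target integer bit depth.
#' @export
write_volume <- function(volume, path, rescale_bits = NULL) {
  stopifnot(inherits(volume, "voxel_volume"))
  if (!dir.exists(dirname(path)))
    stopf("parent directory does not exist: %s", dirname(path))
  if (is_normalized(volume)) {
    if (is.null(rescale_bits))
      stopf(paste("volume is normalized; writing to an integer format needs",
                  "explicit `rescale_bits` (8 or 16)"))
    if (!rescale_bits %in% c(8, 16)) stopf("`rescale_bits` must be 8 or 16")
    maxv <- 2^rescale_bits - 1
    volume <- voxel_volume(array(round(volume$data * maxv), dim(volume$data)),
                           volume$voxel_size_um, rescale_bits)
  }
  if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    maxv <- 2^volume$bit_depth - 1
    pages <- lapply(seq_len(dim(volume$data)[1]),
                    function(z) volume$data[z, , ] / maxv)
    ok <- try(tiff::writeTIFF(pages, path, bits.per.sample = volume$bit_depth),
              silent = TRUE)
    if (inherits(ok, "try-error"))
      stopf("failed to write TIFF %s: %s", path, attr(ok, "condition")$message)
    write_sidecar(paste0(path, ".meta"),
                  list(voxel_size_um = volume$voxel_size_um,
                       bit_depth = volume$bit_depth))
  } else if (grepl("\\.raw$", path, ignore.case = TRUE)) {
    shp <- dim(volume$data)
    # z-major on disk: permute so x is fastest, z slowest, then stream out
    flat <- as.integer(aperm(volume$data, c(3, 2, 1)))
    size <- if (volume$bit_depth == 8) 1L else 2L
    con <- file(path, "wb")
    on.exit(close(con))
    writeBin(flat, con, size = size, endian = "little")
    write_sidecar(paste0(path, ".meta"),
                  list(shape_z = shp[1], shape_y = shp[2], shape_x = shp[3],
                       dtype = if (volume$bit_depth == 8) "uint8" else "uint16",
                       voxel_size_um = volume$voxel_size_um))
  } else {
    stopf("unsupported output format for %s (use .tif/.tiff or .raw)", path)
  }
  invisible(path)
}

#' Read a label mask
#'
#' Same formats as [read_volume()]; integer voxel values are labels. Tissue
#' names come from a `<path>.labels` sidecar with `label = name` lines, or
#' from `label_names`.
#'
#' @inheritParams read_volume
#' @param label_names optional named character vector overriding the sidecar.
#' @return A [label_mask()].
#' @export
read_mask <- function(path, voxel_size_um = NULL, label_names = NULL) {
  vol <- read_volume(path, voxel_size_um)
  if (is.null(label_names)) {
    lf <- read_sidecar(paste0(sub("/$", "", path), ".labels"))
    if (!length(lf)) stopf("no label names: supply `label_names` or %s.labels", path)
    label_names <- stats::setNames(unlist(lf), names(lf))
  }
  label_mask(vol$data, label_names)
}

#' Write a label mask
#'
#' @param mask a [label_mask()].
#' @param path output file (`.tif`/`.tiff` or `.raw`).
#' @param voxel_size_um voxel pitch recorded in the sidecar.
#' @export
write_mask <- function(mask, path, voxel_size_um) {
  stopifnot(inherits(mask, "label_mask"))
  depth <- if (max(mask$data) > 255) 16 else 8
  vol <- voxel_volume(mask$data, voxel_size_um, depth)
  write_volume(vol, path)
  write_sidecar(paste0(path, ".labels"), as.list(mask$label_names))
  invisible(path)
}

#' Normalize greyvalues to \[0, 1\]
#'
#' Divides by the maximum representable value of the bit depth (255 or
#' 65535), not by the per-volume maximum, so that a normalized threshold
#' (e.g. the 0.4 segmentation default) is comparable across volumes and
#' scanning days. Already-normalized input is returned unchanged with a
#' notice.
#'
#' @param volume a [voxel_volume()].
#' @return A normalized [voxel_volume()] with the same voxel pitch.
#' @export
normalize_volume <- function(volume) {
  stopifnot(inherits(volume, "voxel_volume"))
  if (is_normalized(volume)) {
    message("volume is already normalized; returning it unchanged")
    return(volume)
  }
  maxv <- 2^volume$bit_depth - 1
  voxel_volume(volume$data / maxv, volume$voxel_size_um, "normalized")
}
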