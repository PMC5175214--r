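# Independent brute-force oracles used to cross-check the implementation.

# Trapezoidal quadrature of the overlap integral min(f1, f2) between two
# Gaussian densities, on a grid wide enough that the truncated tail mass is
# negligible.
oracle_overlap <- function(m1, s1, m2, s2, n = 2e5) {
  lo <- min(m1, m2) - 10 * max(s1, s2)
  hi <- max(m1, m2) + 10 * max(s1, s2)
  x <- seq(lo, hi, length.out = n)
  y <- pmin(dnorm(x, m1, s1), dnorm(x, m2, s2))
  sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)
}

# Flood-fill 26-connectivity component labelling, queue-based, for tiny
# arrays only.
oracle_components <- function(mask) {
  d <- dim(mask)
  lab <- array(0L, d)
  nxt <- 0L
  idx <- which(mask, arr.ind = TRUE)
  for (r in seq_len(nrow(idx))) {
    p <- idx[r, ]
    if (lab[p[1], p[2], p[3]] > 0L) next
    nxt <- nxt + 1L
    queue <- list(p)
    lab[p[1], p[2], p[3]] <- nxt
    while (length(queue)) {
      q <- queue[[1]]; queue <- queue[-1]
      for (dz in -1:1) for (dy in -1:1) for (dx in -1:1) {
        n <- q + c(dz, dy, dx)
        if (any(n < 1) || any(n > d)) next
        if (mask[n[1], n[2], n[3]] && lab[n[1], n[2], n[3]] == 0L) {
          lab[n[1], n[2], n[3]] <- nxt
          queue[[length(queue) + 1]] <- n
        }
      }
    }
  }
  lab
}

# Direct O(n * m) Euclidean distance transform for tiny arrays.
oracle_edt <- function(mask) {
  d <- dim(mask)
  bg <- which(!mask, arr.ind = TRUE)
  out <- array(0, d)
  fg <- which(mask, arr.ind = TRUE)
  for (r in seq_len(nrow(fg))) {
    p <- fg[r, ]
    out[p[1], p[2], p[3]] <-
      sqrt(min((bg[, 1] - p[1])^2 + (bg[, 2] - p[2])^2 + (bg[, 3] - p[3])^2))
  }
  out
}

# Small two-tissue block phantom: a tissue cuboid inside a background box,
# Gaussian greyvalues, for contrast / segmentation / uptake tests.
block_phantom <- function(dims = c(40, 30, 30), tissue_mean = 0.5,
                          tissue_sd = 0.03, bg_mean = 0.1, bg_sd = 0.02,
                          voxel_size_um = 10, seed = 1,
                          tissue_box = list(z = c(8, 32), y = c(8, 24), x = c(8, 24))) {
  set.seed(seed)
  lab <- array(2L, dims)
  lab[tissue_box$z[1]:tissue_box$z[2], tissue_box$y[1]:tissue_box$y[2],
      tissue_box$x[1]:tissue_box$x[2]] <- 1L
  g <- array(rnorm(prod(dims), bg_mean, bg_sd), dims)
  nt <- sum(lab == 1L)
  g[lab == 1L] <- rnorm(nt, tissue_mean, tissue_sd)
  g <- pmin(pmax(g, 0), 1)
  list(volume = voxel_volume(g, voxel_size_um, "normalized"),
       mask = label_mask(lab, c("1" = "muscle", "2" = "background")))
}

# Tiny phantom spec (a few seconds of work) used where the full default
# phantom would be wasteful.
tiny_phantom_spec <- function(seed = 1) {
  phantom_spec(
    shape = c(80, 40, 40), voxel_size_um = 10,
    tissues = list(
      phantom_tissue("muscle", "ellipsoid", center_mm = c(0.40, 0.20, 0.20),
                     size = list(semi_axes_mm = c(0.25, 0.12, 0.10)),
                     stained_mean = 0.5, stained_sd = 0.03),
      phantom_tissue("cuticle", "cylinder", center_mm = c(0.45, 0.32, 0.12),
                     size = list(radius_mm = 0.03, length_mm = 0.5, axis = "z"),
                     stained_mean = 0.3, stained_sd = 0.02,
                     unstained_mean = 0.15, unstained_sd = 0.02)),
    background_mean = 0.05, background_sd = 0.01,
    front = list(axis = "z", incision_index = 1L, velocity_mm_per_day = 0.17,
                 width_mm = 0.05, days = 3:7),
    seed = seed)
}
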