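test_that("phantom generation is deterministic in spec + seed", {
  spec <- tiny_phantom_spec(seed = 5)
  a <- generate_phantom(spec, day = 4)
  b <- generate_phantom(spec, day = 4)
  expect_identical(a$volume$data, b$volume$data)
  expect_identical(a$mask$data, b$mask$data)
  # a different seed re-noises the greyvalues but not the geometry
  c <- generate_phantom(tiny_phantom_spec(seed = 6), day = 4)
  expect_identical(a$mask$data, c$mask$data)
  expect_false(identical(a$volume$data, c$volume$data))
})

test_that("rasterized primitive volumes approach the analytic values", {
  spec <- tiny_phantom_spec()
  ph <- generate_phantom(spec, day = 0)
  tt <- ph$truth$tissues
  expect_lt(abs(tt$muscle$rasterized_volume_mm3 - tt$muscle$analytic_volume_mm3) /
              tt$muscle$analytic_volume_mm3, 0.02)
  # finer pitch tightens the ellipsoid's rasterization error
  err_at <- function(pitch) {
    sp <- phantom_spec(shape = round(c(0.8, 0.5, 0.5) / (pitch * 1e-3)),
                       voxel_size_um = pitch,
                       tissues = list(phantom_tissue(
                         "blob", "ellipsoid", center_mm = c(0.4, 0.25, 0.25),
                         size = list(semi_axes_mm = c(0.3, 0.2, 0.15)),
                         stained_mean = 0.5, stained_sd = 0.03)),
                       seed = 1)
    t <- generate_phantom(sp, 0)$truth$tissues$blob
    abs(t$rasterized_volume_mm3 - t$analytic_volume_mm3) / t$analytic_volume_mm3
  }
  expect_lt(err_at(10), 0.02)
  expect_lt(err_at(5), 0.005)
})

test_that("emitted greyvalues recover the generating Gaussian parameters", {
  spec <- tiny_phantom_spec(seed = 2)
  ph <- generate_phantom(spec, day = 40)  # fully stained
  pops <- populations_from_mask(ph$volume, ph$mask)
  for (nm in names(ph$truth$tissues)) {
    tr <- ph$truth$tissues[[nm]]
    g <- fit_gaussian(pops[[nm]])
    n <- tr$voxel_count
    expect_lt(abs(g$mean - tr$stained_mean), 3 * tr$stained_sd / sqrt(n))
    expect_lt(abs(g$sd - tr$stained_sd), 3 * tr$stained_sd / sqrt(2 * n))
  }
  gb <- fit_gaussian(pops$background)
  expect_lt(abs(gb$mean - spec$background_mean),
            3 * spec$background_sd / sqrt(gb$n))
  expect_equal(ph$truth$tissues$muscle$drawn_stained_fraction, 1)
  expect_lt(ph$truth$clip_fraction, 1e-3)
})

test_that("the staining front advances as velocity times day", {
  spec <- tiny_phantom_spec(seed = 3)
  ts <- generate_time_series(spec, days = 3:7)
  fronts <- vapply(ts$truth, function(t) t$front_position_mm, 0)
  expect_equal(fronts, 0.17 * (3:7), tolerance = 1e-12)
  # stained fraction of a structure straddling the front grows monotonically
  fr <- vapply(ts$truth, function(t) t$tissues$cuticle$expected_stained_fraction, 0)
  expect_true(all(diff(fr) >= 0))
  expect_gt(fr[2], fr[1])
  # masks are shared across days
  expect_identical(ts$mask$data, generate_phantom(spec, 7)$mask$data)
})

test_that("zero velocity gives statistically identical days", {
  spec <- tiny_phantom_spec(seed = 4)
  spec$front$velocity_mm_per_day <- 0
  ts <- generate_time_series(spec, days = c(3, 7))
  f3 <- ts$truth[[1]]$tissues$muscle$expected_stained_fraction
  f7 <- ts$truth[[2]]$tissues$muscle$expected_stained_fraction
  expect_equal(f3, f7)
  m3 <- mean(ts$volumes[[1]]$data[ts$mask$data == 1L])
  m7 <- mean(ts$volumes[[2]]$data[ts$mask$data == 1L])
  expect_lt(abs(m3 - m7), 0.01)
})

test_that("overlapping primitives resolve later-wins with the overlap logged", {
  spec <- phantom_spec(
    shape = c(40, 30, 30), voxel_size_um = 10,
    tissues = list(
      phantom_tissue("first", "ellipsoid", center_mm = c(0.2, 0.15, 0.15),
                     size = list(semi_axes_mm = c(0.1, 0.08, 0.08)),
                     stained_mean = 0.5, stained_sd = 0.03),
      phantom_tissue("second", "ellipsoid", center_mm = c(0.24, 0.15, 0.15),
                     size = list(semi_axes_mm = c(0.1, 0.08, 0.08)),
                     stained_mean = 0.3, stained_sd = 0.03)),
    seed = 1)
  ph <- generate_phantom(spec, 0)
  expect_gt(ph$truth$overlap_fraction[["second"]], 0)
  # overlapped voxels belong to the later tissue
  expect_gt(ph$truth$tissues$second$voxel_count, 0)
  # a primitive poking out of the volume is a spec error
  bad <- phantom_spec(shape = c(20, 20, 20), voxel_size_um = 10,
                      tissues = list(phantom_tissue(
                        "out", "ellipsoid", center_mm = c(0.19, 0.1, 0.1),
                        size = list(semi_axes_mm = c(0.1, 0.05, 0.05)),
                        stained_mean = 0.5, stained_sd = 0.03)),
                      seed = 1)
  expect_error(generate_phantom(bad, 0), "bounds")
})

test_that("the default phantom carries the reference structure scales", {
  spec <- default_phantom_spec()
  vols <- vapply(spec$tissues, ptcontrast:::analytic_volume_mm3, 0)
  names(vols) <- vapply(spec$tissues, function(t) t$name, "")
  expect_equal(unname(vols["large_muscle"]), 0.99, tolerance = 0.001)
  expect_equal(unname(vols["small_muscle"]), 0.0043, tolerance = 0.001)
  expect_equal(unname(vols["neuropil"]), 0.056, tolerance = 0.01)
  cyl <- spec$tissues[[3]]
  expect_equal(2 * cyl$size$radius_mm * 1000, 57)  # apodeme diameter in um
  expect_equal(spec$tissues[[4]]$size$thickness_mm * 1000, 25)  # sclerite sheet
  expect_equal(spec$front$velocity_mm_per_day, 0.17)
})

test_that("phantom configs round-trip through the plain-text format", {
  spec <- default_phantom_spec(seed = 9)
  f <- withr::local_tempfile(fileext = ".cfg")
  write_phantom_config(spec, f)
  back <- read_phantom_config(f)
  expect_equal(back$shape, spec$shape)
  expect_equal(back$voxel_size_um, spec$voxel_size_um)
  expect_equal(back$seed, spec$seed)
  expect_equal(back$front, spec$front, ignore_attr = TRUE)
  expect_equal(length(back$tissues), length(spec$tissues))
  for (i in seq_along(spec$tissues)) {
    expect_equal(back$tissues[[i]]$name, spec$tissues[[i]]$name)
    expect_equal(back$tissues[[i]]$size, spec$tissues[[i]]$size,
                 ignore_attr = TRUE, tolerance = 1e-12)
    expect_equal(back$tissues[[i]]$stained_mean, spec$tissues[[i]]$stained_mean)
  }
  # a generated volume from the round-tripped spec is bit-identical
  a <- generate_phantom(spec, 3); b <- generate_phantom(back, 3)
  expect_identical(a$volume$data, b$volume$data)
})
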