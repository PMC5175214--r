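# Build a tissue rod along z with a staining front at a given position.
front_volume <- function(nz = 120, front_slab = NULL, width_slabs = 0,
                         pitch = 10, stained = 0.6, unstained = 0.08,
                         bg = 0.05, seed = 99) {
  set.seed(seed)
  d <- c(nz, 16, 16)
  g <- array(bg, d)
  lab <- array(0L, d)
  lab[1:(nz - 10), 5:12, 5:12] <- 1L
  for (zz in which(apply(lab, 1, any))) {
    sel <- lab[zz, , ] == 1L
    p <- if (is.null(front_slab)) 0
    else if (width_slabs == 0) as.numeric(zz <= front_slab)
    else pnorm(-((zz - front_slab) / width_slabs) * sqrt(2))
    is_stained <- runif(sum(sel)) < p
    g[zz, , ][sel] <- ifelse(is_stained, stained, unstained)
  }
  list(volume = voxel_volume(g, pitch, "normalized"),
       mask = label_mask(lab, c("1" = "muscle")))
}

test_that("front position finds a step front exactly and returns 0 when unstained", {
  fv <- front_volume(front_slab = 101)
  fp <- front_position(fv$volume, fv$mask, "muscle", axis = "z", incision_index = 1)
  expect_equal(fp$position_mm, 1.0)  # 100 slabs beyond the incision at 10 um
  un <- front_volume(front_slab = NULL)
  expect_equal(front_position(un$volume, un$mask, "muscle")$position_mm, 0)
  expect_error(front_position(fv$volume, fv$mask, "eye"), "not present")
})

test_that("an erf-shaped front is located within one slab of its centre", {
  fv <- front_volume(front_slab = 101, width_slabs = 5)
  fp <- front_position(fv$volume, fv$mask, "muscle", stained_threshold = 0.4)
  expect_lte(abs(fp$position_mm - 1.0), 0.0100001)  # at most one slab off
})

test_that("uptake rate is the OLS slope with gaps allowed", {
  r <- uptake_rate(uptake_series(c(3, 4, 5), c(0.51, 0.68, 0.85)))
  expect_equal(r$rate, 0.17, tolerance = 1e-12)
  expect_equal(uptake_rate(uptake_series(3:7, rep(0.4, 5)))$rate, 0)
  # two days: difference quotient, no standard error
  r2 <- uptake_rate(uptake_series(c(3, 7), c(0.5, 0.9)))
  expect_equal(r2$rate, 0.1)
  expect_true(is.na(r2$se))
  expect_error(uptake_rate(uptake_series(3, 0.5)), "at least 2")
  expect_error(uptake_series(c(3, 3), c(1, 2)), "strictly increasing")
  # gap series (days 3 & 5 lost) still fits
  r3 <- uptake_rate(uptake_series(c(4, 6, 7), 0.17 * c(4, 6, 7)))
  expect_equal(r3$rate, 0.17, tolerance = 1e-12)
})

test_that("noisy front positions recover the generating velocity", {
  set.seed(41)
  v <- 0.12; days <- 3:7
  pos <- v * days + rnorm(5, 0, 0.01)
  r <- uptake_rate(uptake_series(days, pos))
  se_true <- 0.01 / sqrt(sum((days - mean(days))^2))
  expect_lt(abs(r$rate - v), 2 * se_true)
})

test_that("stained-volume trajectories are monotone and bounded by the total", {
  mk_day <- function(front) front_volume(front_slab = front)
  fronts <- c(30, 60, 90, 105, 120)
  vols <- lapply(fronts, function(f) mk_day(f)$volume)
  mask <- mk_day(30)$mask
  traj <- stained_volume_trajectory(vols, 3:7, mask, "muscle")
  expect_equal(attr(traj, "kind"), "stained_volume_mm3")
  expect_true(all(diff(traj$value) >= 0))
  expect_true(all(traj$value <= attr(traj, "reference_total_mm3") + 1e-12))
  expect_equal(traj$fraction[5], 1)  # front past the whole rod by day 7
  expect_true(all(traj$lower <= traj$value & traj$value <= traj$upper))

  # fully stained every day: fraction 1 throughout
  full <- lapply(1:3, function(i) mk_day(120)$volume)
  t2 <- stained_volume_trajectory(full, 1:3, mask, "muscle")
  expect_true(all(t2$fraction == 1))

  # mismatched shapes are an alignment error
  small <- voxel_volume(array(0.5, c(10, 16, 16)), 10, "normalized")
  expect_error(stained_volume_trajectory(list(small), 3, mask, "muscle"),
               "alignment")
})

test_that("lowering the stained threshold never shrinks the stained volume", {
  fv <- front_volume(front_slab = 60, width_slabs = 10)
  vols <- vapply(seq(0.2, 0.6, by = 0.1), function(th)
    stained_volume_trajectory(list(fv$volume), 3, fv$mask, "muscle",
                              stained_threshold = th)$value, 0)
  expect_true(all(diff(vols) <= 0))
})

test_that("the erf front model recovers noiseless parameters to 1e-6", {
  days <- 3:7; x <- seq(0, 2, by = 0.02)
  prof <- do.call(rbind, lapply(days, function(t)
    data.frame(distance_mm = x, day = t,
               fraction = pnorm(-((x - 0.17 * t) / 0.05) * sqrt(2)))))
  fm <- fit_front_model(prof)
  expect_true(fm$converged)
  expect_lt(abs(fm$velocity_mm_per_day - 0.17) / 0.17, 1e-6)
  expect_lt(abs(fm$width_mm - 0.05) / 0.05, 1e-6)
  expect_lt(abs(fm$onset_day), 1e-4)
})

test_that("a step front yields a small width and the right velocity, reported honestly", {
  days <- 3:7; x <- seq(0, 2, by = 0.02)
  prof <- do.call(rbind, lapply(days, function(t)
    data.frame(distance_mm = x, day = t, fraction = as.numeric(x <= 0.17 * t))))
  fm <- fit_front_model(prof)
  expect_lt(abs(fm$velocity_mm_per_day - 0.17), 0.02 / 5)  # within one slab/day
  expect_gt(fm$width_mm, 0)
  expect_lt(fm$width_mm, 0.02)
  expect_type(fm$message, "character")  # convergence state always reported
  expect_error(fit_front_model(prof[1:2, ]), "at least 3")
})
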