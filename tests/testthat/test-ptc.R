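test_that("fit_gaussian is the moment fit with n-1 sd", {
  g <- fit_gaussian(labelled_population(c(0.3, 0.5), "t"))
  expect_equal(g$mean, 0.4)
  expect_equal(g$sd, sqrt(0.02), tolerance = 1e-12)
  expect_equal(g$n, 2L)
  expect_match(g$warnings, "small sample")

  set.seed(5)
  draws <- rnorm(1e5, 0.4, 0.05)
  g2 <- fit_gaussian(draws, label = "mc")
  expect_lt(abs(g2$mean - 0.4), 0.001)
  expect_lt(abs(g2$sd - 0.05), 0.002)
  expect_length(g2$warnings, 0)

  expect_error(fit_gaussian(rep(0.4, 10), label = "flat"), "degenerate")
  expect_error(fit_gaussian(numeric(0), label = "none"), "empty")
})

test_that("intersection points equate the two densities", {
  # equal sigma: midpoint
  expect_equal(intersection_points(gaussian_model(0, 1), gaussian_model(2, 1)), 1)
  # unequal sigma, equal mean: symmetric pair at +/- sqrt(8/3 * log 2)
  x <- intersection_points(gaussian_model(0, 1), gaussian_model(0, 2))
  expect_equal(x, c(-1, 1) * sqrt(8 / 3 * log(2)), tolerance = 1e-12)
  # defining property on random model pairs
  set.seed(42)
  for (i in 1:50) {
    g1 <- gaussian_model(runif(1, -2, 2), runif(1, 0.05, 2))
    g2 <- gaussian_model(runif(1, -2, 2), runif(1, 0.05, 2))
    p <- intersection_points(g1, g2)
    peak <- max(dnorm(g1$mean, g1$mean, g1$sd), dnorm(g2$mean, g2$mean, g2$sd))
    expect_lt(max(abs(dnorm(p, g1$mean, g1$sd) - dnorm(p, g2$mean, g2$sd))),
              1e-10 * peak)
  }
  expect_error(intersection_points(gaussian_model(1, 2), gaussian_model(1, 2)),
               "identical")
})

test_that("pairwise PTC matches its closed forms and the quadrature oracle", {
  # complete overlap
  expect_identical(ptc_pair(gaussian_model(0.4, 0.05), gaussian_model(0.4, 0.05))$ptc, 1)
  # fully separated
  expect_lt(ptc_pair(gaussian_model(0, 1), gaussian_model(100, 1))$ptc, 1e-15)
  # equal-sigma closed form
  r <- ptc_pair(gaussian_model(0, 1, label = "a"), gaussian_model(2, 1, label = "b"))
  expect_equal(r$ptc, 2 * pnorm(-1), tolerance = 1e-12)
  expect_equal(r$method, "equal_sigma")
  expect_equal(r$x_A, 1)
  expect_lt(abs(r$ptc - oracle_overlap(0, 1, 2, 1)), 1e-6)
  # two-intersection case against the oracle
  r2 <- ptc_pair(gaussian_model(0, 1), gaussian_model(0, 2))
  expect_equal(r2$method, "two_intersection")
  expect_lt(r2$x_A, r2$x_B)
  expect_lt(abs(r2$ptc - oracle_overlap(0, 1, 0, 2)), 1e-6)
})

test_that("closed-form PTC agrees with quadrature over random parameters", {
  set.seed(7)
  for (i in 1:60) {
    m1 <- runif(1); s1 <- runif(1, 0.02, 0.3)
    m2 <- runif(1); s2 <- runif(1, 0.02, 0.3)
    p <- ptc_pair(gaussian_model(m1, s1), gaussian_model(m2, s2))$ptc
    expect_lt(abs(p - oracle_overlap(m1, s1, m2, s2)), 1e-6)
  }
})

test_that("PTC is symmetric, bounded, and decreasing in mean separation", {
  set.seed(9)
  for (i in 1:30) {
    g1 <- gaussian_model(runif(1), runif(1, 0.01, 0.2), label = "a")
    g2 <- gaussian_model(runif(1), runif(1, 0.01, 0.2), label = "b")
    a <- ptc_pair(g1, g2)$ptc; b <- ptc_pair(g2, g1)$ptc
    expect_identical(a, b)
    expect_gte(a, 0); expect_lte(a, 1)
  }
  seps <- seq(0.01, 3, length.out = 100)
  vals <- vapply(seps, function(d)
    ptc_pair(gaussian_model(0, 0.4), gaussian_model(d, 0.7))$ptc, 0)
  expect_true(all(diff(vals) < 0))
})

test_that("the equal-sigma formula is the limit of the two-intersection one", {
  set.seed(12)
  for (i in 1:50) {
    m1 <- runif(1, -5, 5); m2 <- runif(1, -5, 5); s <- runif(1, 0.05, 2)
    if (abs(m1 - m2) < 1e-3) m2 <- m1 + 0.5
    a <- ptc_pair(gaussian_model(m1, s), gaussian_model(m2, s * (1 + 1e-6)))$ptc
    b <- ptc_pair(gaussian_model(m1, s), gaussian_model(m2, s))$ptc
    expect_lt(abs(a - b), 1e-5)
  }
})

test_that("PTC equals the misclassification fraction at the intersection threshold", {
  # Monte Carlo: classify draws from each tissue by the intersection
  # point(s); the summed conditional error fractions estimate the overlap.
  g1 <- gaussian_model(0.3, 0.05, label = "a")
  g2 <- gaussian_model(0.45, 0.08, label = "b")
  r <- ptc_pair(g1, g2)
  set.seed(31)
  n <- 2e5
  d1 <- rnorm(n, g1$mean, g1$sd); d2 <- rnorm(n, g2$mean, g2$sd)
  # classify by nearest-density rule given the intersections: between x_A
  # and x_B the narrow-sd tissue's density is the larger, so that region is
  # assigned to it; a draw from the narrow tissue errs outside it
  narrow_is_1 <- g1$sd < g2$sd
  inside <- function(x) x >= r$x_A & x <= r$x_B
  mis1 <- mean(if (narrow_is_1) !inside(d1) else inside(d1))
  mis2 <- mean(if (narrow_is_1) inside(d2) else !inside(d2))
  se <- sqrt(mis1 * (1 - mis1) / n + mis2 * (1 - mis2) / n)
  expect_lt(abs((mis1 + mis2) - r$ptc), 4 * se)
})

test_that("tissue-vs-background PTC behaves at the extremes", {
  set.seed(21)
  same <- rnorm(2e4, 0.3, 0.04)
  r <- ptc_vs_background(labelled_population(same[1:1e4], "t"),
                         labelled_population(same[10001:2e4], "bg"))
  expect_gt(r$ptc, 0.95)
  tis <- labelled_population(rnorm(1e5, 0.55, 0.03), "muscle")
  bg <- labelled_population(rnorm(1e5, 0.10, 0.02), "background")
  r2 <- ptc_vs_background(tis, bg)
  expect_lt(r2$ptc, 1e-3)  # clears the automatic-thresholding guideline
  expect_length(r2$warnings, 0)
  # small samples are flagged, not blocked
  r3 <- ptc_vs_background(labelled_population(rnorm(500, 0.5, 0.05), "t"),
                          labelled_population(rnorm(500, 0.1, 0.02), "bg"))
  expect_match(r3$warnings, "small sample")
})

test_that("one-vs-rest PTC reduces, clips, and matches Monte Carlo", {
  g <- gaussian_model(0, 1, label = "t")
  o1 <- gaussian_model(2, 1.3, label = "o")
  # single other: both modes equal the pairwise value
  expect_equal(ptc_one_vs_rest(g, list(o1))$ptc, ptc_pair(g, o1)$ptc)
  expect_equal(ptc_one_vs_rest(g, list(o1), mode = "pooled_mixture")$ptc,
               ptc_pair(g, o1)$ptc, tolerance = 1e-5)
  # identical distribution among the others clips the sum at 1
  expect_identical(
    ptc_one_vs_rest(g, list(o1, gaussian_model(0, 1), gaussian_model(5, 1)))$ptc, 1)
  # sum of pairwise overlaps for symmetric flankers
  r <- ptc_one_vs_rest(g, list(gaussian_model(5, 1, label = "hi"),
                               gaussian_model(-5, 1, label = "lo")))
  expect_equal(r$ptc, 2 * (2 * pnorm(-2.5)), tolerance = 1e-12)
  expect_named(r$components, c("hi", "lo"))
  # Monte Carlo: misclassification against both flankers
  set.seed(77)
  n <- 1e6
  d <- rnorm(n, 0, 1)
  mis <- mean(d > 2.5) + mean(d < -2.5) +
    mean(rnorm(n, 5, 1) < 2.5) + mean(rnorm(n, -5, 1) > -2.5)
  se <- sqrt(4 * pnorm(-2.5) * (1 - pnorm(-2.5)) / n)
  expect_lt(abs(r$ptc - mis), 4 * se)
  expect_error(ptc_one_vs_rest(g, list()), "at least one")
})

test_that("the PTC matrix is symmetric with unit diagonal and permutes consistently", {
  set.seed(3)
  pops <- lapply(1:4, function(i)
    labelled_population(rnorm(2000, 0.1 * i + 0.1, 0.02 + 0.01 * i), paste0("t", i)))
  m <- ptc_matrix(pops)
  expect_identical(dim(m), c(4L, 4L))
  expect_identical(diag(m), setNames(rep(1, 4), paste0("t", 1:4)))
  expect_lt(max(abs(m - t(m))), 1e-12)
  perm <- c(3, 1, 4, 2)
  m2 <- ptc_matrix(pops[perm])
  expect_equal(m2, m[perm, perm], ignore_attr = TRUE)
})

test_that("populations extract from a mask and export round-trips", {
  ph <- block_phantom(seed = 8)
  pops <- populations_from_mask(ph$volume, ph$mask)
  expect_named(pops, c("muscle", "background"))
  expect_equal(length(pops$muscle$values), sum(ph$mask$data == 1L))
  r <- ptc_vs_background(pops$muscle, pops$background)
  expect_lt(r$ptc, 1e-3)

  f <- withr::local_tempfile(fileext = ".csv")
  df <- export_ptc(list(r), f)
  expect_true(file.exists(f))
  expect_equal(df$ptc, r$ptc)
  fj <- withr::local_tempfile(fileext = ".json")
  export_ptc(list(r), fj)
  back <- jsonlite::read_json(fj)
  expect_equal(back[[1]]$ptc, r$ptc, tolerance = 1e-12)
})

test_that("populations load from two-column delimited text", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("label,greyvalue", "a,0.30", "a,0.50", "b,0.10", "b,0.20"), f)
  pops <- read_populations(f)
  expect_named(pops, c("a", "b"))
  expect_equal(pops$a$values, c(0.3, 0.5))
})
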