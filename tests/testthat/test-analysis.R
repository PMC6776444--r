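test_that("autocorrelogram is 1 at zero offset and rejects degenerate maps", {
  set.seed(1)
  m <- matrix(runif(400), 20, 20)
  ac <- autocorrelogram(m)
  expect_equal(ac[20, 20], 1)
  expect_equal(dim(unclass(ac)), c(39, 39))
  expect_error(autocorrelogram(matrix(1, 10, 10)), "degenerate")
  expect_error(autocorrelogram(matrix(NA_real_, 10, 10)), "defined")
})

test_that("autocorrelogram of an ideal grid has six innermost peaks on a ring", {
  # 50 cm lattice sampled at 3 cm bins
  sc <- 50 / 3
  f <- synthetic_grid_field(120, 120, sc, orientation_deg = 17)
  ac <- unclass(autocorrelogram(f))
  ctr <- 120
  pk <- oracle_peaks(ac, halfwin = 3, thresh = 0.4)
  rad <- sqrt((pk[, 1] - ctr)^2 + (pk[, 2] - ctr)^2)
  pk <- pk[rad > 2, , drop = FALSE]; rad <- rad[rad > 2]
  inner <- rad < 1.5 * min(rad)
  expect_equal(sum(inner), 6)
  expect_true(all(abs(rad[inner] - sc) <= 1.5))
  angs <- sort(atan2(pk[inner, 2] - ctr, pk[inner, 1] - ctr) * 180 / pi)
  expect_true(all(abs(diff(angs) - 60) < 6))
})

test_that("white-noise maps are not grids", {
  set.seed(2)
  wn <- matrix(rnorm(100 * 100), 100, 100)
  ac <- unclass(autocorrelogram(wn))
  ctr <- 100
  off <- expand.grid(i = 50:150, j = 50:150)
  r2 <- (off$i - ctr)^2 + (off$j - ctr)^2
  vals <- ac[cbind(off$i, off$j)][r2 >= 9]
  expect_lt(max(abs(vals), na.rm = TRUE), 0.2)
  expect_lt(grid_props(wn)$gridness, 0.6)
  expect_false(grid_props(wn)$is_grid)
})

test_that("plane-wave fields measure at the angle-averaged ring radius", {
  # For a pure three-cosine field the angle-averaged autocorrelation is
  # proportional to J0(k r); the measured scale is therefore the first
  # local maximum of J0 beyond zero, at k r = 7.0156, i.e. 0.967 x the
  # lattice constant. Locate that maximum independently with besselJ.
  x0 <- stats::optimize(function(x) besselJ(x, 0),
                        c(4, 10), maximum = TRUE)$maximum
  sc <- 24
  k <- 4 * pi / (sqrt(3) * sc)
  f <- synthetic_grid_field(160, 160, sc, orientation_deg = 12)
  gp <- grid_props(f)
  expect_equal(gp$scale, x0 / k, tolerance = 0.03)
  expect_gt(gp$gridness, 0.6)
  expect_lt(abs(gp$orientation - 12), 2)
})

test_that("the pipeline recovers bump-grid scale and orientation (property)", {
  set.seed(3)
  for (sc in c(10, 16, 25, 33)) {
    or <- stats::runif(1, 0, 60)
    ph <- stats::runif(2, 0, sc)
    f <- bump_grid_field(150, 150, sc, or, ph)
    gp <- grid_props(f)
    expect_true(gp$is_grid)
    expect_lt(abs(gp$scale - sc), 1)
    expect_lt(min(abs(gp$orientation - or), 60 - abs(gp$orientation - or)), 2)
    # the independent peak-spacing oracle agrees
    expect_lt(abs(oracle_spacing(f) - sc), 1.5)
  }
})

test_that("grid measurements transform correctly under map symmetries", {
  f1 <- bump_grid_field(150, 150, 18, 10)
  f2 <- bump_grid_field(150, 150, 36, 10)   # doubled lattice constant
  g1 <- grid_props(f1); g2 <- grid_props(f2)
  expect_equal(g2$scale / g1$scale, 2, tolerance = 0.05)
  # transposition reflects the orientation: theta -> (90 - theta) mod 60
  gt <- grid_props(t(f1))
  expect_lt(min(abs(gt$orientation - 20), 60 - abs(gt$orientation - 20)), 2)
  expect_equal(gt$scale, g1$scale, tolerance = 1e-6)
  # rotated generator: scale unchanged, orientation follows
  g3 <- grid_props(bump_grid_field(150, 150, 18, 40))
  expect_equal(g3$scale, g1$scale, tolerance = 0.1)
  expect_lt(min(abs(g3$orientation - 40), 60 - abs(g3$orientation - 40)), 2)
})

test_that("module clustering separates well-defined scale clusters", {
  set.seed(4)
  cells <- tibble::tibble(
    scale = c(rnorm(20, 40, 0.5), rnorm(20, 70, 0.5)),
    orientation = c(rnorm(20, 5, 0.5), rnorm(20, 35, 0.5)) %% 60,
    gridness = 0.9)
  part <- cluster_modules(cells)
  expect_equal(part$k, 2)
  expect_equal(nrow(part$pairs), 1)
  expect_equal(part$pairs$scale_ratio, 70 / 40, tolerance = 0.02)
  expect_equal(part$pairs$orientation_diff, 30, tolerance = 1)
  expect_true(all(diff(part$modules$scale) > 0))
  expect_true(all(part$pairs$scale_ratio > 1))
})

test_that("orientation is treated as circular modulo 60 degrees", {
  set.seed(5)
  cells <- tibble::tibble(
    scale = rnorm(30, 50, 0.5),
    orientation = c(rnorm(15, 58, 0.8), rnorm(15, 2, 0.8)) %% 60,
    gridness = 0.9)
  part <- cluster_modules(cells)
  expect_equal(part$k, 1)
  expect_lt(part$modules$orientation_sd, 4)
  # the circular mean lands near the wrap point, not at 30
  expect_lt(min(part$modules$orientation, 60 - part$modules$orientation), 6)
})

test_that("cells failing the gridness cutoff are excluded", {
  cells <- tibble::tibble(scale = c(40, 41, 70), orientation = c(5, 6, 30),
                          gridness = c(0.9, 0.9, 0.2))
  part <- cluster_modules(cells)
  expect_true(is.na(part$cells$module[3]))
  expect_equal(part$k, 1)
  # all cells failing -> empty partition
  none <- cluster_modules(dplyr::mutate(cells, gridness = 0.1))
  expect_equal(none$k, 0)
  expect_equal(nrow(none$pairs), 0)
})

test_that("lattice relationships classify by the stated criteria", {
  cl <- classify_relationship(
    c(1.73, 1.39, 1.05, 2.0, 1.25, 1.6),
    c(30, 6.7, 15, 0.5, 5, 20),
    registry = c(NA, NA, NA, NA, NA, 0.2))
  expect_equal(cl$class,
               c("commensurate", "discommensurate", "defect",
                 "commensurate", "discommensurate", "incommensurate"))
  # folding is applied to the orientation difference
  expect_equal(classify_relationship(1.73, 330 %% 60)$orientation_diff, 30)
})

test_that("peak registry distinguishes commensurate from random overlays", {
  S <- 24
  coarse <- bump_grid_field(140, 140, S, 0)
  fine <- bump_grid_field(140, 140, S / sqrt(3), 30)
  reg <- overlay_registry(coarse, fine)
  expect_equal(reg$registry_coarse, 1, tolerance = 0.02)
  expect_equal(reg$registry_fine, 1 / 3, tolerance = 0.08)
  # identical patterns are in full registry
  self <- overlay_registry(coarse, coarse)
  expect_equal(self$registry_fine, 1)
  expect_equal(self$registry_coarse, 1)
  expect_error(overlay_registry(matrix(0, 30, 30), matrix(0, 30, 30)))
})

test_that("random point fields register at the capture-disk coverage rate", {
  set.seed(6)
  bumps <- function(pts, n) {
    f <- matrix(0, n, n)
    xs <- seq_len(n)
    for (i in seq_len(nrow(pts)))
      f <- f + exp(-(outer((xs - pts[i, 1])^2, (xs - pts[i, 2])^2, `+`)) / 8)
    f
  }
  n <- 120
  npts <- 60
  reps <- purrr::map_dbl(1:4, function(r) {
    pa <- cbind(runif(npts, 8, n - 8), runif(npts, 8, n - 8))
    pb <- cbind(runif(npts, 8, n - 8), runif(npts, 8, n - 8))
    overlay_registry(bumps(pa, n), bumps(pb, n), capture = 4)$registry_fine
  })
  # analytic expectation for Poisson points: 1 - exp(-rho * pi * r^2)
  expect_equal(mean(reps), 1 - exp(-npts / (n - 16)^2 * pi * 16),
               tolerance = 0.12)
})
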