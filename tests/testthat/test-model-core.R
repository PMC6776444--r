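test_that("drive profile matches the closed form at reference points", {
  expect_equal(drive_profile(0, a_mag = 1), 1, tolerance = 1e-12)
  expect_equal(drive_profile(0.5, a_mag = 1, a_fall = 4), exp(-1),
               tolerance = 1e-12)
  expect_identical(drive_profile(1), 0)
  expect_identical(drive_profile(1.7), 0)
})

test_that("drive field is centered, maximal at center and radially nonincreasing", {
  p <- grid_params(h = 1, n = 160, l_min = 9, l_max = 9)
  a <- build_drive(p)
  cc <- (p$n + 1) / 2
  # field equals the closed form on the integer grid
  for (pt in list(c(80, 80), c(1, 1), c(160, 31), c(40, 121))) {
    r_scaled <- sqrt((pt[1] - cc)^2 + (pt[2] - cc)^2) / p$n
    expect_equal(a[pt[1], pt[2]], drive_profile(r_scaled, p$a_mag, p$a_fall),
                 tolerance = 1e-12)
  }
  expect_equal(max(a), a[80, 80])
  # monotone nonincreasing along a row through the center
  row <- a[80, 80:160]
  expect_true(all(diff(row) <= 1e-12))
  expect_error(build_drive(grid_params(n = 2)), "n must be")
})

test_that("inhibition-distance profile interpolates with tunable concavity", {
  p <- grid_params()  # l_min 4, l_max 15, l_exp -1, h 12
  l <- inhibition_profile(p)
  expect_equal(l[1], 4)
  expect_equal(l[12], 15)
  # harmonic interpolation at z = 2: [1/4 + (1/15 - 1/4)/11]^-1 = 30/7
  expect_equal(l[2], 30 / 7, tolerance = 1e-12)
  # geometric-mean limit at l_exp = 0
  p0 <- grid_params(h = 3, l_min = 4, l_max = 16, l_exp = 0)
  expect_equal(inhibition_profile(p0)[2], 8, tolerance = 1e-12)
  # monotone for assorted exponents; more negative exponent is more concave
  for (e in c(-2, -1, 0, 0.5, 1)) {
    le <- inhibition_profile(grid_params(l_exp = e))
    expect_true(all(diff(le) >= -1e-12))
  }
  l1 <- inhibition_profile(grid_params(l_exp = -1))
  l2 <- inhibition_profile(grid_params(l_exp = -2))
  expect_true(all(l2[2:11] <= l1[2:11] + 1e-12))
  expect_error(grid_params(h = 1, l_min = 4, l_max = 15), "l_min == l_max")
})

test_that("inhibition kernel has the stated shape, peak and support", {
  expect_identical(inhibition_weight(0, 4), 0)
  expect_equal(inhibition_weight(4, 4, w_mag = 2.4), -2.4 / 16,
               tolerance = 1e-12)
  expect_identical(inhibition_weight(8, 4), 0)   # r = 2l cutoff
  expect_identical(inhibition_weight(9.5, 4), 0)
  r <- seq(0, 10, by = 0.01)
  w <- inhibition_weight(r, 4, 2.4)
  expect_true(all(w <= 0))
  expect_equal(min(w), -2.4 / 16)
  expect_equal(r[which.min(w)], 4, tolerance = 0.01)
  # sampled kernel is zero at and beyond the cutoff
  K <- build_inhibition_kernel(4, grid_params())
  R <- (nrow(K) - 1) / 2
  off <- seq(-R, R)
  rr <- sqrt(outer(off^2, off^2, `+`))
  expect_true(all(K[rr >= 8] == 0))
})

test_that("coupling kernel has the stated shape, peak and support", {
  expect_equal(coupling_weight(0, d = 8, u_mag = 2.6), 2.6 / 64,
               tolerance = 1e-12)
  expect_equal(coupling_weight(4, d = 8, u_mag = 2.6), 2.6 / 128,
               tolerance = 1e-12)  # r = d/2 -> u_mag/(2 d^2)
  expect_identical(coupling_weight(8, d = 8), 0)
  expect_identical(coupling_weight(12, d = 8), 0)
  r <- seq(0, 8, by = 0.01)
  u <- coupling_weight(r, 8, 2.6)
  expect_true(all(u >= 0))
  expect_true(all(diff(u) <= 1e-12))
})

test_that("integrated inhibition is approximately depth-independent", {
  p <- grid_params()
  k <- build_kernels(p)
  tot <- vapply(k$inhibition, function(K) sum(abs(K)), numeric(1))
  expect_lt((max(tot) - min(tot)) / mean(tot), 0.05)
})

test_that("subpopulations tile the sheet evenly and deterministically", {
  p2 <- grid_params(h = 1, n = 4, l_min = 4, l_max = 4)
  sp <- assign_subpopulations(p2)
  expect_equal(sort(unique(as.vector(sp$code))), 1:4)
  expect_true(all(table(sp$code) == 4))
  # the four directions all appear within any 2x2 block
  expect_setequal(as.vector(sp$code[1:2, 1:2]), 1:4)
  p <- grid_params()
  sp1 <- assign_subpopulations(p)
  expect_true(all(table(sp1$code) == p$n^2 / 4))
  expect_identical(sp1, assign_subpopulations(p))
  # network and spatial preferred directions are paired unit vectors
  expect_true(all(abs(sp1$e_x) + abs(sp1$e_y) == 1))
  expect_identical(sp1$e_x, sp1$E_x)
  expect_error(grid_params(n = 41), "even")
})

test_that("parameter validation rejects contract violations", {
  expect_error(grid_params(h = 0), "h must")
  expect_error(grid_params(dt = 11, tau = 10), "dt <= tau")
  expect_error(grid_params(l_min = 5, l_max = 4), "l_min <= l_max")
  expect_error(grid_params(d = 0), "d must")
  expect_error(grid_params(alpha = 0), "alpha")
  expect_error(grid_params(w_mag = -1), "w_mag")
})

test_that("configuration files round-trip and reject unknown keys", {
  p <- grid_params(h = 6, n = 76, l_exp = 0, coupling_direction = "bidirectional")
  f <- withr::local_tempfile(fileext = ".yaml")
  write_params(p, f)
  q <- read_params(f)
  expect_equal(unclass(q), unclass(p))
  writeLines("bogus_key: 3", f)
  expect_error(read_params(f), "unknown configuration keys")
})
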