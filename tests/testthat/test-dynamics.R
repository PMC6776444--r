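test_that("optimized recurrent input equals direct summation", {
  set.seed(7)
  for (n in c(12, 16)) {
    p <- grid_params(h = 1, n = n, l_min = 3, l_max = 3, xi = 1,
                     coupling_direction = "none")
    k <- build_kernels(p)
    s <- matrix(runif(n^2), n, n)
    fast <- recurrent_input(s, k, 1)
    slow <- brute_recurrent(s, k$subpop$code, p$xi, 3, p$w_mag)
    expect_lt(max(abs(fast - slow)), 1e-9)
  }
})

test_that("optimized coupling input equals direct summation", {
  set.seed(8)
  for (n in c(10, 16)) {
    p <- grid_params(h = 2, n = n, l_min = 3, l_max = 3, d = 5)
    k <- build_kernels(p)
    st <- network_state(p)
    st$rates <- list(matrix(runif(n^2), n, n), matrix(runif(n^2), n, n))
    fast <- coupling_input(st, k, 1)
    slow <- brute_coupling(st$rates[[2]], p$d, p$u_mag)
    expect_lt(max(abs(fast - slow)), 1e-9)
  }
})

test_that("impulse responses reproduce the kernels", {
  n <- 16
  p <- grid_params(h = 2, n = n, l_min = 3, l_max = 3, d = 5, xi = 0)
  k <- build_kernels(p)
  s <- matrix(0, n, n); s[8, 8] <- 1
  # recurrent input from one active neuron is the kernel centered there
  out <- recurrent_input(s, k, 1)
  K <- k$inhibition[[1]]; R <- (nrow(K) - 1) / 2
  expect_equal(out[8, 8], K[R + 1, R + 1], tolerance = 1e-10)
  expect_equal(out[8 + 3, 8], inhibition_weight(3, 3, p$w_mag),
               tolerance = 1e-10)
  expect_equal(out[8, 8 + 2], inhibition_weight(2, 3, p$w_mag),
               tolerance = 1e-10)
  # coupling: target field is u centered on the source position
  st <- network_state(p)
  st$rates <- list(matrix(0, n, n), s)
  cp <- coupling_input(st, k, 1)
  expect_equal(cp[8, 8], coupling_weight(0, p$d, p$u_mag), tolerance = 1e-10)
  expect_equal(cp[8, 12], coupling_weight(4, p$d, p$u_mag), tolerance = 1e-10)
  # topmost source network receives nothing under default direction
  expect_identical(coupling_input(st, k, 2), matrix(0, n, n))
  # all-zero rates give all-zero input
  expect_identical(recurrent_input(matrix(0, n, n), k, 1), matrix(0, n, n))
})

test_that("one Euler step follows the rectified dynamics exactly", {
  n <- 12
  p <- grid_params(h = 2, n = n, l_min = 3, l_max = 3, d = 5,
                   a_mag = 0.7, xi = 1)
  k <- build_kernels(p)
  sim <- prepare_simulation(p, k)
  set.seed(9)
  st <- network_state(p)
  V <- c(0.4, -0.2)
  st1 <- step_state(sim, st, V)
  drv <- build_drive(p)
  for (z in 1:2) {
    tot <- recurrent_input(st, k, z) + coupling_input(st, k, z) +
      drv * (1 + p$alpha * (k$subpop$E_x * V[1] + k$subpop$E_y * V[2]))
    tot[tot < 0] <- 0
    manual <- st$rates[[z]] + (p$dt / p$tau) * (tot - st$rates[[z]])
    expect_lt(max(abs(st1$rates[[z]] - manual)), 1e-12)
  }
})

test_that("with no input rates decay geometrically and stay rectified", {
  # zero drive, zero recurrent weights: s(t+dt) = (1 - dt/tau) s(t)
  p <- grid_params(h = 1, n = 8, l_min = 3, l_max = 3, a_mag = 0,
                   w_mag = 0, coupling_direction = "none",
                   dt = 1, tau = 10)
  sim <- prepare_simulation(p)
  st <- network_state(p)
  st$rates[[1]][] <- 1
  st1 <- step_state(sim, st)
  expect_equal(unique(as.vector(st1$rates[[1]])), 0.9, tolerance = 1e-12)
  # strong uniform inhibition drives the rectified target to zero
  p2 <- grid_params(h = 1, n = 8, l_min = 3, l_max = 3, a_mag = 0,
                    w_mag = 50, coupling_direction = "none")
  sim2 <- prepare_simulation(p2)
  st2 <- network_state(p2)
  st2$rates[[1]][] <- 1
  out <- st2
  for (i in 1:20) out <- step_state(sim2, out)
  expect_true(all(out$rates[[1]] >= 0))
  expect_true(all(out$rates[[1]] < 1))
  expect_equal(max(out$rates[[1]]), 0.9^20, tolerance = 1e-9)
})

test_that("rates remain nonnegative along random runs (property)", {
  for (seed in 1:3) {
    p <- tiny_params()
    sim <- prepare_simulation(p)
    st <- network_state(p, seed = seed)
    set.seed(seed + 100)
    nst <- 300
    vel <- matrix(runif(2 * nst, -0.5, 0.5), nst, 2)
    st <- advance(sim, st, velocities = vel)$state
    expect_true(all(vapply(st$rates, function(m) all(m >= 0), logical(1))))
  }
})

test_that("identical seeds give bit-identical trajectories", {
  p <- tiny_params()
  run <- function() {
    sim <- prepare_simulation(p)
    st <- network_state(p, seed = 11)
    advance(sim, st, duration = 0.3)$state$rates
  }
  expect_identical(run(), run())
})

test_that("velocity contract violations are rejected", {
  p <- tiny_params()
  sim <- prepare_simulation(p)
  st <- network_state(p, seed = 1)
  expect_error(advance(sim, st, velocities = matrix(c(NA, 0), 1, 2)),
               "nonfinite")
  expect_error(advance(sim, st, velocities = matrix(c(5, 0), 1, 2)),
               "speed")
  expect_error(grid_params(dt = 20, tau = 10), "dt <= tau")
})

test_that("lesions mask the stated neurons and hold them at zero", {
  p <- tiny_params()
  n <- p$n
  sim <- prepare_simulation(p)
  st <- network_state(p, seed = 2)
  st <- advance(sim, st, duration = 0.2)$state
  full <- apply_lesion(st, lesion_spec("full", z = 2), p)
  expect_true(all(full$rates[[2]] == 0))
  expect_true(all(full$lesion[[2]] == 0))
  expect_identical(full$rates[[1]], st$rates[[1]])
  after <- advance(sim, full, duration = 0.2)$state
  expect_true(all(after$rates[[2]] == 0))
  expect_gt(max(after$rates[[1]]), 0)
  # decimation spares exactly one neuron per 3x3 block
  dec <- apply_lesion(st, lesion_spec("decimation", z = 2), p)
  expect_equal(sum(dec$lesion[[2]]), ceiling(n / 3)^2)
  # regional lesion with zero preserved corner equals a full lesion
  reg0 <- apply_lesion(st, lesion_spec("regional", z = 2, corner_frac = 0), p)
  expect_identical(reg0$lesion[[2]], full$lesion[[2]])
  reg <- apply_lesion(st, lesion_spec("regional", z = 2, corner_frac = 0.25), p)
  side <- floor(n * sqrt(0.25))
  expect_equal(sum(reg$lesion[[2]]), side^2)
  expect_true(all(reg$lesion[[2]][1:side, 1:side] == 1))
  expect_error(apply_lesion(st, lesion_spec("full", z = 9), p), "outside")
})

test_that("variant flags perturb but do not break the dynamics", {
  p <- tiny_params()
  # rate noise: still nonnegative, still forms activity
  sim_n <- prepare_simulation(p, flags = sim_flags(noise_sd = 0.05))
  st <- network_state(p, seed = 3)
  stn <- advance(sim_n, st, duration = 0.3)$state
  expect_true(all(vapply(stn$rates, function(m) all(m >= 0), logical(1))))
  expect_true(all(vapply(stn$rates, function(m) all(is.finite(m)), logical(1))))
  # coupling shift: deterministic given the seed, and close to unshifted
  run_cs <- function() {
    set.seed(4)
    sim <- prepare_simulation(p, flags = sim_flags(coupling_shift = TRUE))
    st <- network_state(p)
    advance(sim, st, duration = 0.3)$state$rates
  }
  expect_identical(run_cs(), run_cs())
  # spiking: recording returns integer Poisson counts
  set.seed(5)
  simsp <- prepare_simulation(p, flags = sim_flags(spiking = TRUE,
                                                   spike_rate_scale = 400))
  stsp <- network_state(p)
  rec <- matrix(c(1L, 20L, 20L), 1, 3)
  out <- advance(simsp, stsp, duration = 0.2, record = rec, rec_every = 1L)
  expect_true(all(out$recording == round(out$recording)))
  expect_true(all(out$recording >= 0))
  expect_true(all(vapply(out$state$rates, function(m) all(m >= 0),
                         logical(1))))
})
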