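# Structural tests of the protocol orchestration run at a deliberately
# small scale (3 networks of 40 x 40, short settling); the scientific
# assertions at the protocols' real operating points live in
# test-acceptance.R.

test_that("the standard protocol assembles replicate analyses", {
  p <- tiny_params()
  rs <- run_standard(coupled = TRUE, params = p, seeds = 1:2, settle = 2,
                     keep_snapshots = TRUE)
  expect_s3_class(rs, "grid_run_set")
  expect_equal(nrow(rs$network_props), 2 * p$h)
  expect_named(rs$network_props,
               c("seed", "z", "l", "scale", "orientation", "gridness",
                 "is_grid"))
  expect_equal(length(rs$partitions), 2)
  expect_equal(length(rs$snapshots), 2)
  expect_true(all(dim(rs$snapshots[[1]][[1]]) == p$n))
  if (nrow(rs$pairs)) {
    expect_true(all(rs$pairs$scale_ratio >= 1))
    expect_true(all(rs$pairs$orientation_diff >= 0 &
                      rs$pairs$orientation_diff <= 30))
    expect_true(all(rs$pairs$class %in%
                      c("commensurate", "discommensurate", "incommensurate",
                        "defect", "unclassified")))
  }
  # uncoupled switch actually disables coupling
  ru <- run_standard(coupled = FALSE, params = p, seeds = 1, settle = 1)
  expect_equal(ru$params$coupling_direction, "none")
  expect_equal(ru$protocol, "standard_uncoupled")
  # tidiers
  expect_s3_class(tidy(rs, "networks"), "tbl_df")
  expect_equal(nrow(glance(rs)), 1)
})

test_that("replicates are reproducible end to end", {
  p <- tiny_params()
  r1 <- run_standard(TRUE, p, seeds = 7, settle = 1, keep_snapshots = TRUE)
  r2 <- run_standard(TRUE, p, seeds = 7, settle = 1, keep_snapshots = TRUE)
  expect_identical(r1$snapshots, r2$snapshots)
  expect_identical(r1$network_props, r2$network_props)
})

test_that("variants apply their documented overrides", {
  p <- tiny_params()
  rv <- run_variant("reverse_coupling", params = p, seeds = 1, settle = 1)
  expect_equal(rv$params$coupling_direction, "dorsal_to_ventral")
  expect_equal(rv$protocol, "variant_reverse_coupling")
  rb <- run_variant("bidirectional", params = p, seeds = 1, settle = 1)
  expect_equal(rb$params$coupling_direction, "bidirectional")
  rd <- run_variant("d_equals_l", params = p, seeds = 1, settle = 1)
  expect_true(rd$params$d_follows_l)
  rn <- run_variant("rate_noise", params = p, seeds = 1, settle = 1)
  expect_gt(rn$flags$noise_sd, 0)
  rs <- run_variant("spiking", params = p, seeds = 1, settle = 0.5)
  expect_true(rs$flags$spiking)
  # small_system override reshapes the stack
  ov <- gridmodules:::variant_overrides("small_system")
  expect_equal(ov$params$h, 6L)
  expect_equal(ov$params$n, 76L)
  expect_error(run_variant("bogus"), "unknown variant")
})

test_that("the depth-dependent coupling spread builds per-depth kernels", {
  p <- tiny_params(d_follows_l = TRUE)
  k <- build_kernels(p)
  expect_equal(k$d_profile, k$l_profile)
  sizes <- vapply(k$coupling, nrow, numeric(1))
  expect_equal(sizes, 2 * ceiling(k$l_profile) + 1)
})

test_that("the two-network phase sweep reports per-point majorities", {
  p <- grid_params(n = 60, enclosure_diameter = 100)
  pt <- run_phase_sweep(u_mag = 2.6, l_ratio = c(1.2, 1.7), d = 6,
                        replicates = 2, params = p, settle = 2)
  expect_s3_class(pt, "phase_table")
  expect_equal(nrow(pt), 4)
  expect_true(all(c("scale_ratio", "orientation_diff", "registry",
                    "class") %in% names(pt)))
  maj <- attr(pt, "majority")
  expect_equal(nrow(maj), 2)
  # the inhibition-distance mean is held fixed at 9
  l1 <- 2 * 9 / (1 + pt$l_ratio)
  expect_equal(unique(round((l1 + l1 * pt$l_ratio) / 2, 9)), 9)
})

test_that("the lesion protocol separates pre and post analyses", {
  p <- tiny_params()
  lr <- run_lesion("full", z = 2, params = p, seeds = 1, pre = 2, post = 1,
                   keep_snapshots = TRUE)
  expect_s3_class(lr, "lesion_result")
  np <- lr$network_props
  expect_equal(nrow(np), 2 * p$h)
  expect_setequal(unique(np$phase), c("pre", "post"))
  # the lesioned sheet is silent afterwards
  expect_true(all(lr$snapshots[[1]]$post[[2]] == 0))
  expect_gt(max(lr$snapshots[[1]]$pre[[2]]), 0)
  expect_s3_class(tidy(lr, "networks"), "tbl_df")
  expect_equal(glance(lr)$kind, "full")
})

test_that("ensemble statistics summarize pooled module pairs", {
  set.seed(9)
  pairs <- tibble::tibble(
    pair = rep(c("M2/M1", "M3/M2"), each = 12),
    seed = rep(1:12, 2),
    scale_ratio = c(rnorm(12, 1.5, 0.1), rnorm(12, 1.55, 0.1)),
    orientation_diff = pmin(pmax(c(rnorm(12, 8, 3), rnorm(12, 10, 3)), 0), 30))
  st <- ensemble_stats(pairs)
  expect_named(st, c("rank_correlation", "by_position", "ratio_test",
                     "diff_test", "pooled_ratio"))
  expect_equal(nrow(st$by_position), 2)
  expect_true(st$ratio_test > 0 && st$ratio_test <= 1)
  expect_equal(st$pooled_ratio$mean, mean(pairs$scale_ratio))
})

test_that("run sets persist losslessly through the run directory", {
  p <- tiny_params()
  rs <- run_standard(TRUE, p, seeds = 1:2, settle = 1, keep_snapshots = TRUE)
  dir <- withr::local_tempdir()
  write_run(rs, dir)
  expect_true(file.exists(file.path(dir, "config.yaml")))
  back <- read_run(dir)
  expect_equal(as.data.frame(back$network_props),
               as.data.frame(rs$network_props))
  expect_equal(as.data.frame(back$cell_props),
               as.data.frame(rs$cell_props))
  expect_identical(back$snapshots, rs$snapshots)
  expect_equal(unclass(back$params), unclass(rs$params))
  expect_equal(back$protocol, rs$protocol)
})

test_that("plot constructors return ggplot objects", {
  p <- tiny_params()
  rs <- run_standard(TRUE, p, seeds = 1, settle = 1, keep_snapshots = TRUE)
  snap <- rs$snapshots[[1]][[1]]
  expect_s3_class(plot_snapshot(snap), "ggplot")
  expect_s3_class(plot_overlay(snap, rs$snapshots[[1]][[2]]), "ggplot")
  expect_s3_class(autoplot(autocorrelogram(snap)), "ggplot")
  expect_s3_class(plot_scale_profile(rs), "ggplot")
  tr <- generate_trajectory(1, p, seed = 1)
  expect_s3_class(autoplot(tr), "ggplot")
  part <- cluster_modules(tibble::tibble(
    scale = c(40, 41, 70, 71), orientation = c(5, 6, 35, 34),
    gridness = 0.9))
  expect_s3_class(autoplot(part), "ggplot")
})
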