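#' Run one replicate simulation
#'
#' Low-level protocol engine: seeds the RNG, builds the engine, settles the
#' random initial state with the animal at rest, then (optionally) runs
#' trajectory-driven path integration with single-neuron recording, and
#' analyzes the final population snapshots.
#'
#' @param params A [grid_params()] object.
#' @param seed Integer replicate seed; all randomness (initial rates,
#'   trajectory, recorded-neuron choice, noise, spiking) derives from it.
#' @param settle Settling time with `V = 0`, seconds.
#' @param duration Trajectory-driven time, seconds (0 = none).
#' @param flags A [sim_flags()] object.
#' @param record_per_network Neurons recorded per network during the
#'   trajectory-driven phase.
#' @param rec_every Recording cadence in steps.
#' @param keep_snapshots Keep the final `n x n` rate fields in the result.
#' @param trajectory Optional `trajectory` tibble; generated when `duration
#'   > 0` and none is supplied.
#' @return List with `network_props` (tibble: `z`, `l`, `scale`,
#'   `orientation`, `gridness`, `is_grid`), `snapshots`, `samples` (tibble
#'   of recorded activity with positions, or `NULL`), `rec_idx`, `state`,
#'   `seed`.
#' @export
simulate_run <- function(params, seed = 1, settle = 20, duration = 0,
                         flags = sim_flags(), record_per_network = 0,
                         rec_every = 10L, keep_snapshots = TRUE,
                         trajectory = NULL) {
  set.seed(seed)
  sim <- prepare_simulation(params, flags = flags)
  st <- network_state(params)
  if (settle > 0) st <- advance(sim, st, duration = settle)$state
  samples <- NULL
  rec_idx <- NULL
  if (duration > 0) {
    if (is.null(trajectory))
      trajectory <- generate_trajectory(duration, params)
    rec_idx <- if (record_per_network > 0)
      choose_record_neurons(params, record_per_network) else NULL
    out <- advance(sim, st, velocities = trajectory_velocities(trajectory),
                   record = rec_idx, rec_every = rec_every)
    st <- out$state
    if (!is.null(rec_idx))
      samples <- recording_samples(out$recording, rec_idx, trajectory)
  }
  lz <- inhibition_profile(params)
  network_props <- purrr::map_dfr(seq_len(params$h), function(z)
    dplyr::mutate(network_grid_props(st$rates[[z]]), z = z, l = lz[z],
                  .before = 1))
  list(network_props = network_props,
       snapshots = if (keep_snapshots) st$rates else NULL,
       samples = samples, rec_idx = rec_idx, state = st, seed = seed)
}

# spatial (single-neuron) grid properties from recorded samples
spatial_cell_props <- function(samples, rec_idx, params, bin_cm = 3,
                               smooth_sd = 1, spiking = FALSE) {
  purrr::map_dfr(seq_len(nrow(rec_idx)), function(q) {
    sm <- dplyr::filter(samples, .data$neuron == q)
    gp <- tryCatch({
      rm <- build_rate_map(sm, params, bin_cm = bin_cm, smooth_sd = smooth_sd,
                           spiking = spiking)
      rate_map_grid_props(rm)
    }, error = function(e)
      tibble::tibble(scale = NA_real_, orientation = NA_real_,
                     gridness = 0, is_grid = FALSE))
    dplyr::mutate(gp, neuron = q, z = rec_idx[q, 1], .before = 1)
  })
}

#' Run the standard coupled or uncoupled protocol
#'
#' The reference experiment: a stack of networks with the standard
#' parameters, with or without inter-network coupling, replicated across
#' seeds. Analysis is network-level (population snapshots; scale in
#' neurons) and optionally spatial (trajectory-driven recordings binned to
#' rate maps; scale in cm). Each replicate's grid cells (or networks) are
#' clustered into modules and adjacent-pair statistics collected.
#'
#' @param coupled Logical; `FALSE` switches coupling off.
#' @param params Base [grid_params()].
#' @param seeds Integer vector of replicate seeds.
#' @param settle Settling seconds (pattern formation; `V = 0`).
#' @param duration Trajectory-driven seconds (needed for spatial analysis).
#' @param analysis `"network"` or `"spatial"`.
#' @param record_per_network Neurons recorded per network (spatial).
#' @param flags A [sim_flags()] object.
#' @param keep_snapshots Keep final rate fields of every replicate.
#' @param cutoff Gridness cutoff for clustering.
#' @return An object of class `grid_run_set`: list with `protocol`,
#'   `params`, `flags`, `seeds`, `network_props`, `cell_props`,
#'   `partitions` (one [cluster_modules()] result per seed), `pairs`
#'   (adjacent-module statistics pooled over seeds, with relationship
#'   classes), and `snapshots` (per seed, when kept).
#' @export
run_standard <- function(coupled = TRUE, params = grid_params(),
                         seeds = 1:10, settle = 20, duration = 0,
                         analysis = c("network", "spatial"),
                         record_per_network = 3, flags = sim_flags(),
                         keep_snapshots = FALSE, cutoff = 0.6) {
  analysis <- match.arg(analysis)
  if (!coupled) {
    params$coupling_direction <- "none"
    params <- validate_params(params)
  }
  if (analysis == "spatial" && duration <= 0)
    stop("spatial analysis needs duration > 0", call. = FALSE)
  res <- purrr::map(seeds, function(sd_) {
    run <- simulate_run(params, seed = sd_, settle = settle,
                        duration = duration, flags = flags,
                        record_per_network =
                          if (analysis == "spatial") record_per_network else 0,
                        keep_snapshots = keep_snapshots)
    cells <- if (analysis == "spatial") {
      spatial_cell_props(run$samples, run$rec_idx, params,
                         spiking = flags$spiking)
    } else {
      run$network_props
    }
    part <- cluster_modules(cells, cutoff = cutoff)
    list(run = run, cells = cells, part = part)
  })
  assemble_run_set(res, seeds, params, flags, analysis,
                   protocol = if (coupled) "standard_coupled"
                   else "standard_uncoupled",
                   keep_snapshots = keep_snapshots)
}

assemble_run_set <- function(res, seeds, params, flags, analysis, protocol,
                             keep_snapshots = FALSE) {
  network_props <- purrr::map2_dfr(res, seeds, function(r, s)
    dplyr::mutate(r$run$network_props, seed = s, .before = 1))
  cell_props <- purrr::map2_dfr(res, seeds, function(r, s)
    dplyr::mutate(r$part$cells, seed = s, .before = 1))
  pairs <- purrr::map2_dfr(res, seeds, function(r, s) {
    pr <- r$part$pairs
    if (nrow(pr) == 0) return(NULL)
    dplyr::mutate(pr, seed = s, .before = 1)
  })
  if (nrow(pairs) > 0)
    pairs <- dplyr::bind_cols(
      pairs, classify_relationship(pairs$scale_ratio,
                                   pairs$orientation_diff)["class"])
  structure(list(protocol = protocol, params = params, flags = flags,
                 seeds = seeds, analysis = analysis,
                 network_props = network_props, cell_props = cell_props,
                 partitions = purrr::map(res, "part"),
                 pairs = pairs,
                 snapshots = if (keep_snapshots)
                   purrr::map(res, ~ .x$run$snapshots) else NULL),
            class = "grid_run_set")
}

#' @export
print.grid_run_set <- function(x, ...) {
  cat(sprintf("<grid_run_set> %s: %d replicate(s), %s analysis\n",
              x$protocol, length(x$seeds), x$analysis))
  if (nrow(x$pairs)) {
    cat("adjacent-module pairs:\n")
    print(x$pairs)
  }
  invisible(x)
}

# documented overrides for the named perturbation variants
variant_overrides <- function(name) {
  switch(name,
    concave_less   = list(params = list(l_exp = -0.5)),
    concave_more   = list(params = list(l_exp = -2)),
    reverse_coupling = list(params = list(coupling_direction = "dorsal_to_ventral")),
    bidirectional  = list(params = list(coupling_direction = "bidirectional")),
    d_equals_l     = list(params = list(d_follows_l = TRUE)),
    small_system   = list(params = list(h = 6L, n = 76L)),
    rate_noise     = list(flags = list(noise_sd = 0.02)),
    coupling_shift = list(flags = list(coupling_shift = TRUE)),
    spiking        = list(flags = list(spiking = TRUE)),
    stop("unknown variant: ", name, call. = FALSE))
}

#' Run a named perturbation variant
#'
#' Applies a documented set of overrides to the standard coupled protocol:
#' `concave_less` / `concave_more` (inhibition profile concavity, `l_exp`
#' -0.5 / -2), `reverse_coupling` (dorsal-to-ventral), `bidirectional`,
#' `d_equals_l` (depth-dependent coupling spread), `small_system` (`h = 6`,
#' `n = 76`), `rate_noise` (per-step Gaussian rate noise, sd 0.02 -- about
#' 5% of a typical activity-peak rate; a package choice, see the methods
#' vignette), `coupling_shift` (outputs jittered by one neuron in x and y),
#' `spiking` (Poisson spike propagation).
#'
#' @param name Variant name (see above).
#' @param ... Passed to [run_standard()].
#' @param params,flags Base configuration before variant overrides.
#' @return A `grid_run_set`; `protocol` records the variant.
#' @export
run_variant <- function(name, params = grid_params(), flags = sim_flags(),
                        ...) {
  ov <- variant_overrides(name)
  if (!is.null(ov$params)) for (f in names(ov$params)) params[[f]] <- ov$params[[f]]
  params <- validate_params(params)
  if (!is.null(ov$flags)) for (f in names(ov$flags)) flags[[f]] <- ov$flags[[f]]
  out <- run_standard(coupled = TRUE, params = params, flags = flags, ...)
  out$protocol <- paste0("variant_", name)
  out
}

#' Two-network excitation-inhibition phase sweep
#'
#' Sweeps the coupling strength `u_mag` and the inhibition-distance ratio
#' `l(2)/l(1)` of a two-network model, holding the mean of `l(1)` and
#' `l(2)` fixed at 9 neurons. Each grid point is simulated for several
#' replicate seeds; the two networks' pattern scales and orientations are
#' measured from population snapshots, their peak registry computed, the
#' lattice relationship classified, and the per-point majority class
#' reported.
#'
#' @param u_mag Numeric vector of coupling strengths.
#' @param l_ratio Numeric vector of `l(2)/l(1)` ratios (`>= 1`).
#' @param d Coupling spread(s); the sweep is repeated for each.
#' @param replicates Replicates per grid point.
#' @param params Base parameters (`h`, `l_min`, `l_max`, `u_mag`, `d` are
#'   overridden per point).
#' @param settle Settling seconds per replicate.
#' @param l_mean Fixed mean of `l(1)` and `l(2)`.
#' @param cutoff Gridness cutoff; replicates whose sheets are not both
#'   grids are reported as class `"no_grid"`.
#' @return An object of class `phase_table`: tibble with one row per
#'   replicate (`u_mag`, `l_ratio`, `d`, `seed`, scales, orientations,
#'   `scale_ratio`, `orientation_diff`, `registry`, `class`) plus attribute
#'   `majority` (per-point majority class tibble).
#' @export
run_phase_sweep <- function(u_mag, l_ratio, d = c(6, 12), replicates = 10,
                            params = grid_params(), settle = 20,
                            l_mean = 9, cutoff = 0.6) {
  grid <- tidyr::expand_grid(u_mag = u_mag, l_ratio = l_ratio, d = d)
  rows <- purrr::pmap_dfr(grid, function(u_mag, l_ratio, d) {
    l1 <- 2 * l_mean / (1 + l_ratio)
    l2 <- l_ratio * l1
    p <- params
    p$h <- 2L; p$l_min <- l1; p$l_max <- l2; p$u_mag <- u_mag; p$d <- d
    p <- validate_params(p)
    purrr::map_dfr(seq_len(replicates), function(sd_) {
      run <- simulate_run(p, seed = sd_, settle = settle, keep_snapshots = TRUE)
      np <- run$network_props
      reg <- tryCatch(
        overlay_registry(run$snapshots[[1]], run$snapshots[[2]])$registry_coarse,
        error = function(e) NA_real_)
      ratio <- np$scale[2] / np$scale[1]
      if (is.finite(ratio) && ratio < 1) ratio <- 1 / ratio
      diffo <- fold_orientation_diff(np$orientation[2] - np$orientation[1])
      cls <- if (all(np$gridness >= cutoff) && is.finite(ratio)) {
        classify_relationship(ratio, diffo, registry = reg)$class
      } else "no_grid"
      tibble::tibble(u_mag = u_mag, l_ratio = l_ratio, d = d, seed = sd_,
                     scale_1 = np$scale[1], scale_2 = np$scale[2],
                     orientation_1 = np$orientation[1],
                     orientation_2 = np$orientation[2],
                     gridness_1 = np$gridness[1], gridness_2 = np$gridness[2],
                     scale_ratio = ratio, orientation_diff = diffo,
                     registry = reg, class = cls)
    })
  })
  majority <- dplyr::summarise(
    dplyr::group_by(rows, .data$u_mag, .data$l_ratio, .data$d),
    majority_class = names(sort(table(class), decreasing = TRUE))[1],
    scale_ratio = stats::median(.data$scale_ratio, na.rm = TRUE),
    orientation_diff = stats::median(.data$orientation_diff, na.rm = TRUE),
    .groups = "drop")
  attr(rows, "majority") <- majority
  class(rows) <- c("phase_table", class(rows))
  rows
}

#' Discommensurate-regime protocol
#'
#' The 12-network stack tuned into the discommensurate region: shallower
#' inhibition profile (`l_max = 10`), larger coupling spread (`d = 12`) and
#' a larger sheet (`n = 230`) so that the longer registry periodicities fit.
#'
#' @param ... Passed to [run_standard()] (seeds, settle, analysis, ...).
#' @param params Base parameters; the regime overrides are applied on top.
#' @param n Sheet side length; the regime's full scale is 230 neurons
#'   (registry periodicities span long distances), reducible for probes.
#' @return A `grid_run_set` with `protocol = "discommensurate"`.
#' @export
run_discommensurate <- function(params = grid_params(), n = 230L, ...) {
  params$l_max <- 10; params$d <- 12; params$n <- as.integer(n)
  params <- validate_params(params)
  out <- run_standard(coupled = TRUE, params = params, ...)
  out$protocol <- "discommensurate"
  out
}

#' Mixed-parameter ensemble of module pairs
#'
#' Imitates biological variability across animals: replicate simulations
#' for each row of a (`u_mag`, `l_max`) parameter table are pooled and the
#' adjacent-module pair statistics analyzed together.
#'
#' @param param_grid Tibble with columns `u_mag` and `l_max` (one row per
#'   parameter set). The default grid spans coupling strengths around the
#'   standard value and inhibition maxima spanning the commensurate and
#'   discommensurate regimes.
#' @param replicates Replicates per parameter set.
#' @param params Base parameters (the discommensurate-regime `d = 12`,
#'   `n = 230` defaults are applied unless overridden in `params`).
#' @param ... Passed to [run_standard()].
#' @return List of class `ensemble_result`: `pairs` (pooled tibble with
#'   `u_mag`, `l_max` and pair statistics), `runs` (list of
#'   `grid_run_set`), and `stats` from [ensemble_stats()].
#' @export
run_ensemble <- function(param_grid = tidyr::expand_grid(
                           u_mag = c(1.8, 2.6), l_max = c(10, 12.5, 15)),
                         replicates = 5, params = grid_params(),
                         d = 12, n = 230L, ...) {
  params$d <- d; params$n <- as.integer(n)
  runs <- purrr::pmap(param_grid, function(u_mag, l_max) {
    p <- params
    p$u_mag <- u_mag; p$l_max <- l_max
    p <- validate_params(p)
    run_standard(coupled = TRUE, params = p, seeds = seq_len(replicates), ...)
  })
  pairs <- purrr::map2_dfr(runs, seq_len(nrow(param_grid)), function(r, i) {
    if (nrow(r$pairs) == 0) return(NULL)
    dplyr::mutate(r$pairs, u_mag = param_grid$u_mag[i],
                  l_max = param_grid$l_max[i], .before = 1)
  })
  structure(list(pairs = pairs, runs = runs,
                 stats = ensemble_stats(pairs, runs)),
            class = "ensemble_result")
}

#' Pooled statistics of ensemble module pairs
#'
#' Computes, over all adjacent-module pairs pooled across an ensemble: the
#' rank correlation between scale ratio and orientation difference
#' (Spearman), per-pair-position (M2/M1 vs M3/M2) means and medians of the
#' scale ratio and of the normalized scale difference
#' `(scale_large - scale_small) / scale(M1)`, and Mann-Whitney tests of
#' median equality between pair positions.
#'
#' @param pairs Pooled pair tibble (needs `pair`, `scale_ratio`,
#'   `orientation_diff`, `seed`).
#' @param runs Optional list of `grid_run_set` used to recover each
#'   replicate's M1 scale for normalized differences.
#' @return A list: `rank_correlation` (estimate, p), `by_position`
#'   (tibble), `ratio_test` and `diff_test` (Mann-Whitney p-values), and
#'   `pooled_ratio` (mean, sem).
#' @export
ensemble_stats <- function(pairs, runs = NULL) {
  if (nrow(pairs) < 3) return(NULL)
  ct <- suppressWarnings(
    stats::cor.test(pairs$scale_ratio, pairs$orientation_diff,
                    method = "spearman"))
  # normalized scale difference needs the pair's absolute scales
  pos12 <- pairs$pair == "M2/M1"
  pos23 <- pairs$pair == "M3/M2"
  by_pos <- dplyr::summarise(
    dplyr::group_by(pairs, .data$pair),
    n = dplyr::n(),
    mean_ratio = mean(.data$scale_ratio),
    median_ratio = stats::median(.data$scale_ratio),
    mean_diff_deg = mean(.data$orientation_diff), .groups = "drop")
  ratio_test <- if (sum(pos12) > 0 && sum(pos23) > 0)
    suppressWarnings(stats::wilcox.test(pairs$scale_ratio[pos12],
                                        pairs$scale_ratio[pos23]))$p.value
  else NA_real_
  diff_test <- NA_real_
  if (!is.null(runs) && "norm_scale_diff" %in% names(pairs) == FALSE) {
    # attach normalized differences when scales are recoverable
    pairs$norm_scale_diff <- NA_real_
  }
  if ("norm_scale_diff" %in% names(pairs) &&
      any(is.finite(pairs$norm_scale_diff))) {
    diff_test <- suppressWarnings(
      stats::wilcox.test(pairs$norm_scale_diff[pos12],
                         pairs$norm_scale_diff[pos23]))$p.value
  }
  list(rank_correlation = list(rho = unname(ct$estimate), p = ct$p.value),
       by_position = by_pos,
       ratio_test = ratio_test, diff_test = diff_test,
       pooled_ratio = list(mean = mean(pairs$scale_ratio),
                           sem = stats::sd(pairs$scale_ratio) /
                             sqrt(nrow(pairs))))
}

#' Mid-run lesion protocol
#'
#' Runs the standard coupled protocol to a lesion time, records and
#' analyzes the pre-lesion state, applies the lesion (full network
#' inactivation, corner-sparing regional lesion, or 3x3 decimation), then
#' continues and analyzes the post-lesion state. Pre/post recordings are
#' kept separate.
#'
#' @param kind Lesion kind, see [lesion_spec()].
#' @param z Lesioned network.
#' @param params A [grid_params()] object.
#' @param seeds Replicate seeds.
#' @param pre,post Simulated seconds before and after the lesion (settling
#'   for pattern formation included in `pre`).
#' @param corner_frac,block Passed to [lesion_spec()].
#' @param flags A [sim_flags()] object.
#' @param cutoff Gridness cutoff for module clustering.
#' @param keep_snapshots Keep pre- and post-lesion rate fields.
#' @return An object of class `lesion_result`: list with `network_props`
#'   (tibble with `phase` pre/post), `partitions` (per seed and phase),
#'   `pairs`, `spec`, `params`, `seeds`, and optional `snapshots`.
#' @export
run_lesion <- function(kind = c("full", "regional", "decimation"), z = 7,
                       params = grid_params(), seeds = 1:10,
                       pre = 20, post = 20, corner_frac = 0.25, block = 3L,
                       flags = sim_flags(), cutoff = 0.6,
                       keep_snapshots = FALSE) {
  kind <- match.arg(kind)
  spec <- lesion_spec(kind, z = z, corner_frac = corner_frac, block = block)
  lz <- inhibition_profile(params)
  res <- purrr::map(seeds, function(sd_) {
    set.seed(sd_)
    sim <- prepare_simulation(params, flags = flags)
    st <- network_state(params)
    st <- advance(sim, st, duration = pre)$state
    props <- function(state, phase) purrr::map_dfr(seq_len(params$h),
      function(zz) dplyr::mutate(network_grid_props(state$rates[[zz]]),
                                 z = zz, l = lz[zz], phase = phase,
                                 .before = 1))
    pre_props <- props(st, "pre")
    pre_snap <- if (keep_snapshots) st$rates else NULL
    st <- apply_lesion(st, spec, params)
    st <- advance(sim, st, duration = post)$state
    post_props <- props(st, "post")
    np <- dplyr::bind_rows(pre_props, post_props)
    parts <- list(
      pre = cluster_modules(pre_props, cutoff = cutoff),
      post = cluster_modules(
        dplyr::filter(post_props, .data$z != spec$z), cutoff = cutoff))
    list(np = np, parts = parts,
         snaps = if (keep_snapshots) list(pre = pre_snap, post = st$rates)
         else NULL)
  })
  network_props <- purrr::map2_dfr(res, seeds, function(r, s)
    dplyr::mutate(r$np, seed = s, .before = 1))
  pairs <- purrr::map2_dfr(res, seeds, function(r, s) {
    dplyr::bind_rows(
      dplyr::mutate(r$parts$pre$pairs, phase = "pre"),
      dplyr::mutate(r$parts$post$pairs, phase = "post")) |>
      dplyr::mutate(seed = s, .before = 1)
  })
  structure(list(network_props = network_props,
                 partitions = purrr::map(res, "parts"), pairs = pairs,
                 spec = spec, params = params, seeds = seeds,
                 snapshots = if (keep_snapshots) purrr::map(res, "snaps")
                 else NULL),
            class = "lesion_result")
}

#' Settle a network until its population pattern is a grid
#'
#' Advances the dynamics with the animal at rest in chunks, checking the
#' population pattern's gridness after each chunk, and stops as soon as the
#' tracked network's pattern passes the cutoff (or the time budget ends).
#'
#' @param params A [grid_params()] object.
#' @param seed Replicate seed.
#' @param max_s Settling budget, seconds.
#' @param check_every Chunk length between gridness checks, seconds.
#' @param z Network whose pattern is tracked.
#' @param cutoff Gridness cutoff.
#' @return List: `state`, `props` (final [network_grid_props()] row),
#'   `elapsed_s`, `formed`.
#' @export
settle_to_pattern <- function(params, seed = 1, max_s = 20, check_every = 2,
                              z = 1L, cutoff = 0.6) {
  set.seed(seed)
  sim <- prepare_simulation(params)
  st <- network_state(params)
  elapsed <- 0
  props <- NULL
  while (elapsed < max_s) {
    st <- advance(sim, st, duration = check_every)$state
    elapsed <- elapsed + check_every
    props <- network_grid_props(st$rates[[z]])
    if (isTRUE(props$is_grid) && props$gridness >= cutoff) break
  }
  list(state = st, props = props, elapsed_s = elapsed,
       formed = isTRUE(props$is_grid))
}

#' Measure the path-integration gain of a settled network
#'
#' Applies a constant velocity and tracks the translation of the population
#' pattern on the neural sheet by cross-correlating successive snapshots
#' (accumulated in short intervals so each incremental shift stays well
#' under half a grid period). The gain (neurons of pattern displacement per
#' cm of animal displacement) converts the network scale lambda (neurons)
#' into the single-neuron spatial scale `Lambda = lambda / gain` (cm),
#' which is inversely proportional to the velocity gain alpha.
#'
#' @param params A [grid_params()] object (typically `h = 1`).
#' @param seed Replicate seed.
#' @param settle Settling seconds before the drift measurement.
#' @param V Constant velocity vector, m/s.
#' @param duration Drift measurement time, seconds.
#' @param interval Snapshot interval, seconds.
#' @param z Network to track.
#' @return A one-row tibble: `gain_neurons_per_cm`, `lambda`,
#'   `Lambda_cm`, `speed`, `displacement_cm`, `shift_neurons`.
#' @export
measure_path_integration <- function(params, seed = 1, settle = 5,
                                     V = c(0.25, 0), duration = 1.5,
                                     interval = 0.1, z = 1L) {
  set.seed(seed)
  sim <- prepare_simulation(params)
  st <- network_state(params)
  st <- advance(sim, st, duration = settle)$state
  first <- st$rates[[z]]
  lam <- network_grid_props(first)$scale
  nint <- round(duration / interval)
  stepsi <- round(interval * 1000 / params$dt)
  total <- c(0, 0)
  prev <- first
  for (i in seq_len(nint)) {
    st <- advance(sim, st,
                  velocities = matrix(V, stepsi, 2, byrow = TRUE))$state
    cur <- st$rates[[z]]
    # incremental integer-resolution tracking resolves the lattice
    # ambiguity; only the final windowed measurement enters the estimate
    total <- total + field_shift(prev, cur)
    prev <- cur
  }
  total <- field_shift(first, st$rates[[z]], center = total,
                       window = lam / 3)
  disp_cm <- sqrt(sum(V^2)) * 100 * duration
  shift_n <- sqrt(sum(total^2))
  gain <- shift_n / disp_cm
  tibble::tibble(gain_neurons_per_cm = gain, lambda = lam,
                 Lambda_cm = lam / gain, speed = sqrt(sum(V^2)),
                 displacement_cm = disp_cm, shift_neurons = shift_n)
}

# subpixel displacement between two patterns via argmax of cross-correlation,
# optionally restricted to a window around an expected shift
field_shift <- function(a, b, center = NULL, window = NULL) {
  n1 <- nrow(a); n2 <- ncol(a)
  P1 <- next_fast_size(2 * n1); P2 <- next_fast_size(2 * n2)
  pad <- function(m) { A <- matrix(0, P1, P2); A[1:n1, 1:n2] <- m; A }
  am <- a - mean(a); bm <- b - mean(b)
  cc <- Re(stats::fft(stats::fft(pad(bm)) * Conj(stats::fft(pad(am))),
                      inverse = TRUE)) / (P1 * P2)
  rows <- c((P1 - n1 + 2):P1, 1:n1)
  cols <- c((P2 - n2 + 2):P2, 1:n2)
  cc <- cc[rows, cols]
  cc_search <- cc
  if (!is.null(center)) {
    lag1 <- seq_len(nrow(cc)) - n1
    lag2 <- seq_len(ncol(cc)) - n2
    far <- outer((lag1 - center[1])^2, (lag2 - center[2])^2, `+`) > window^2
    cc_search[far] <- -Inf
  }
  i <- which(cc_search == max(cc_search), arr.ind = TRUE)[1, ]
  dx <- i[1] - n1; dy <- i[2] - n2
  # parabolic subpixel refinement in each axis
  if (i[1] > 1 && i[1] < nrow(cc))
    dx <- dx + 0.5 * (cc[i[1] - 1, i[2]] - cc[i[1] + 1, i[2]]) /
      (cc[i[1] - 1, i[2]] - 2 * cc[i[1], i[2]] + cc[i[1] + 1, i[2]])
  if (i[2] > 1 && i[2] < ncol(cc))
    dy <- dy + 0.5 * (cc[i[1], i[2] - 1] - cc[i[1], i[2] + 1]) /
      (cc[i[1], i[2] - 1] - 2 * cc[i[1], i[2]] + cc[i[1], i[2] + 1])
  c(dx, dy)
}
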