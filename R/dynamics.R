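#' @useDynLib gridmodules, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# smallest 5-smooth integer >= m (fast FFT sizes)
next_fast_size <- function(m) {
  k <- m
  repeat {
    q <- k
    for (f in c(2, 3, 5)) while (q %% f == 0) q <- q / f
    if (q == 1) return(k)
    k <- k + 1
  }
}

# FFT of a small centered kernel embedded (wrapped) in a P x P array
kernel_fft <- function(kern, P) {
  R <- (nrow(kern) - 1) / 2
  A <- matrix(0, P, P)
  idx <- ((-R:R) %% P) + 1
  A[idx, idx] <- kern
  stats::fft(A)
}

#' Variant flags for a simulation
#'
#' Optional perturbations of the standard rate dynamics. All default to off.
#'
#' @param noise_sd Standard deviation of independent zero-mean Gaussian noise
#'   added to every neuron's firing rate at every timestep (rates are
#'   re-rectified afterwards). The default magnitude used by the noise
#'   variant protocol is documented in [run_variant()].
#' @param coupling_shift If `TRUE`, every neuron's coupling outputs are
#'   displaced by a fixed random shift of one neuron in both the x- and
#'   y-directions, drawn once per run.
#' @param spiking If `TRUE`, each neuron emits spikes from an independent
#'   Poisson process with intensity `rate * spike_rate_scale`, and spike
#'   counts (normalized by their expectation scale) rather than rates
#'   propagate through the recurrent and coupling sums.
#' @param spike_rate_scale Spikes per second per unit rate (spiking mode).
#' @return An object of class `sim_flags`.
#' @export
sim_flags <- function(noise_sd = 0, coupling_shift = FALSE,
                      spiking = FALSE, spike_rate_scale = 500) {
  stopifnot(noise_sd >= 0, spike_rate_scale > 0)
  structure(list(noise_sd = noise_sd, coupling_shift = isTRUE(coupling_shift),
                 spiking = isTRUE(spiking), spike_rate_scale = spike_rate_scale),
            class = "sim_flags")
}

#' Prepare a simulation engine
#'
#' Precomputes everything static: kernels, their padded FFTs, the coupling
#' wiring implied by `coupling_direction`, the velocity-modulated drive
#' fields, and (if enabled) the per-neuron coupling-output shifts. The
#' returned engine is passed to [advance()] together with a mutable state.
#'
#' @param params A [grid_params()] object.
#' @param kernels Optional precomputed [build_kernels()] result.
#' @param flags A [sim_flags()] object.
#' @return An object of class `grid_sim`.
#' @export
prepare_simulation <- function(params, kernels = NULL, flags = sim_flags()) {
  validate_params(params)
  if (is.null(kernels)) kernels <- build_kernels(params)
  h <- params$h; n <- params$n; xi <- params$xi
  rad_w <- vapply(kernels$inhibition, function(k) (nrow(k) - 1) / 2, numeric(1))
  rad_u <- vapply(kernels$coupling, function(k) (nrow(k) - 1) / 2, numeric(1))
  maxR <- max(rad_w, if (params$coupling_direction != "none") rad_u else 0)
  m0 <- xi + 2L
  P <- next_fast_size(n + 2L * (as.integer(ceiling(maxR)) + m0))
  # kernel spectra pre-scaled by 1/P^2: the core's inverse FFT is unnormalized
  wfft <- lapply(kernels$inhibition, function(k) kernel_fft(k, P) / P^2)

  src_a <- src_b <- integer(h)
  z <- seq_len(h)
  if (params$coupling_direction %in% c("ventral_to_dorsal", "bidirectional"))
    src_a <- ifelse(z < h, z + 1L, 0L)
  if (params$coupling_direction == "dorsal_to_ventral")
    src_a <- ifelse(z > 1L, z - 1L, 0L)
  if (params$coupling_direction == "bidirectional")
    src_b <- ifelse(z > 1L, z - 1L, 0L)

  ufft <- vector("list", h)
  needed <- unique(c(src_a, src_b)); needed <- needed[needed > 0]
  for (s in needed) ufft[[s]] <- kernel_fft(kernels$coupling[[s]], P) / P^2

  cshift <- list()
  if (flags$coupling_shift) {
    cshift <- lapply(seq_len(h), function(z)
      matrix(sample.int(4L, n * n, replace = TRUE), n, n))
  }

  dvx <- params$alpha * kernels$drive * kernels$subpop$E_x
  dvy <- params$alpha * kernels$drive * kernels$subpop$E_y

  structure(list(params = params, kernels = kernels, flags = flags,
                 P = P, m0 = m0, wfft = wfft, ufft = ufft,
                 src_a = src_a, src_b = src_b, cshift = cshift,
                 dvx = dvx, dvy = dvy),
            class = "grid_sim")
}

#' Initialize the network state
#'
#' Firing rates are drawn independently and uniformly from `[0, 1)`; the
#' attractor dynamics then relax this random state into a triangular pattern
#' during a settling period.
#'
#' @param params A [grid_params()] object.
#' @param seed Optional integer seed (set before drawing).
#' @return An object of class `grid_state`: list with `rates` (length-`h`
#'   list of `n x n` matrices), `time` (ms) and `lesion` (`NULL` or a
#'   length-`h` list of 0/1 activity masks, 1 = neuron active).
#' @export
network_state <- function(params, seed = NULL) {
  validate_params(params)
  if (!is.null(seed)) set.seed(seed)
  rates <- lapply(seq_len(params$h), function(z)
    matrix(stats::runif(params$n^2), params$n, params$n))
  structure(list(rates = rates, time = 0, lesion = NULL), class = "grid_state")
}

#' Advance the simulation
#'
#' Steps the rectified Euler dynamics forward, either for `duration` seconds
#' with the animal at rest (`V = 0`; used for settling), or along an explicit
#' per-step velocity matrix.
#'
#' @param sim A [prepare_simulation()] engine.
#' @param state A [network_state()] object.
#' @param velocities Optional `steps x 2` matrix of velocities (m/s), one row
#'   per timestep.
#' @param duration Simulated seconds to run with `V = 0` (ignored when
#'   `velocities` is given).
#' @param record Optional integer matrix with columns `z, x, y` of neurons to
#'   record (see [choose_record_neurons()]).
#' @param rec_every Record every this many steps.
#' @return List with the updated `state` and, when recording, `recording`: a
#'   matrix (timepoints x neurons) plus attributes `steps` and `time_ms`.
#' @export
advance <- function(sim, state, velocities = NULL, duration = NULL,
                    record = NULL, rec_every = 1L) {
  stopifnot(inherits(sim, "grid_sim"), inherits(state, "grid_state"))
  p <- sim$params
  if (is.null(velocities)) {
    stopifnot(!is.null(duration), duration > 0)
    nsteps <- round(duration * 1000 / p$dt)
    velocities <- matrix(0, nsteps, 2)
  }
  velocities <- as.matrix(velocities)
  stopifnot(ncol(velocities) == 2)
  if (any(!is.finite(velocities))) stop("nonfinite velocity", call. = FALSE)
  spd <- sqrt(rowSums(velocities^2))
  if (any(spd > p$speed_max + 1e-9))
    stop("speed exceeds speed_max", call. = FALSE)

  rec_idx <- if (is.null(record)) matrix(0L, 0, 3) else {
    storage.mode(record) <- "integer"; record
  }
  lesion <- if (is.null(state$lesion)) list() else state$lesion
  res <- sim_core_cpp(state$rates, sim$wfft, sim$ufft,
                      sim$src_a, sim$src_b,
                      sim$kernels$drive, sim$dvx, sim$dvy, velocities,
                      p$dt / p$tau, sim$P, sim$m0, p$xi,
                      sim$kernels$subpop$code,
                      sim$flags$noise_sd, sim$flags$spiking,
                      sim$flags$spike_rate_scale * p$dt / 1000,
                      lesion, sim$cshift,
                      rec_idx, if (is.null(record)) 0L else as.integer(rec_every))
  new_state <- state
  new_state$rates <- res$rates
  nsteps <- nrow(velocities)
  new_state$time <- state$time + nsteps * p$dt
  out <- list(state = new_state)
  if (!is.null(record)) {
    rec <- res$rec
    steps <- seq_len(nrow(rec)) * rec_every
    attr(rec, "steps") <- steps
    attr(rec, "time_ms") <- state$time + steps * p$dt
    out$recording <- rec
  }
  out
}

#' Single Euler step
#'
#' @param sim A [prepare_simulation()] engine.
#' @param state A [network_state()] object.
#' @param V Length-2 spatial velocity (m/s).
#' @return The updated `grid_state`.
#' @export
step_state <- function(sim, state, V = c(0, 0)) {
  advance(sim, state, velocities = matrix(V, 1, 2))$state
}

#' Recurrent inhibitory input to one network (reference path)
#'
#' Computes the within-sheet inhibitory drive: each source neuron's output
#' kernel is displaced by `xi` neurons along its preferred network direction,
#' and contributions falling outside the open (non-periodic) sheet are
#' dropped. This R implementation mirrors the optimized C++ path and is used
#' for validation; both are checked against direct summation in the tests.
#'
#' @param state A [network_state()] or an `n x n` rate matrix.
#' @param kernels A [build_kernels()] object.
#' @param z Network index.
#' @return An `n x n` input field.
#' @export
recurrent_input <- function(state, kernels, z) {
  s <- if (inherits(state, "grid_state")) state$rates[[z]] else state
  p <- kernels$params
  n <- p$n; xi <- p$xi
  kern <- kernels$inhibition[[z]]
  R <- (nrow(kern) - 1) / 2
  m0 <- xi + 2
  P <- next_fast_size(n + 2 * (R + m0))
  Fpad <- matrix(0, P, P)
  code <- kernels$subpop$code
  ex <- c(1L, -1L, 0L, 0L); ey <- c(0L, 0L, 1L, -1L)
  for (k in 1:4) {
    sk <- s * (code == k)
    rows <- m0 + seq_len(n) - xi * ex[k]
    cols <- m0 + seq_len(n) - xi * ey[k]
    Fpad[rows, cols] <- Fpad[rows, cols] + sk
  }
  kf <- kernel_fft(kern, P)
  conv <- Re(stats::fft(stats::fft(Fpad) * kf, inverse = TRUE)) / P^2
  conv[m0 + seq_len(n), m0 + seq_len(n)]
}

#' Excitatory coupling input to one network (reference path)
#'
#' Input received by network `z` from its coupled neighbor(s) under the
#' configured coupling direction; networks lacking a source (e.g. the most
#' ventral sheet under ventral-to-dorsal coupling) receive a zero field.
#'
#' @inheritParams recurrent_input
#' @param direction Coupling direction; defaults to the configuration's.
#' @return An `n x n` input field.
#' @export
coupling_input <- function(state, kernels, z,
                           direction = kernels$params$coupling_direction) {
  p <- kernels$params
  n <- p$n; h <- p$h
  src <- switch(direction,
                ventral_to_dorsal = if (z < h) z + 1L else integer(0),
                dorsal_to_ventral = if (z > 1L) z - 1L else integer(0),
                bidirectional = c(if (z < h) z + 1L, if (z > 1L) z - 1L),
                none = integer(0))
  out <- matrix(0, n, n)
  for (s_z in src) {
    s <- if (inherits(state, "grid_state")) state$rates[[s_z]] else state
    kern <- kernels$coupling[[s_z]]
    R <- (nrow(kern) - 1) / 2
    m0 <- 2
    P <- next_fast_size(n + 2 * (R + m0))
    Fpad <- matrix(0, P, P)
    Fpad[m0 + seq_len(n), m0 + seq_len(n)] <- s
    kf <- kernel_fft(kern, P)
    conv <- Re(stats::fft(stats::fft(Fpad) * kf, inverse = TRUE)) / P^2
    out <- out + conv[m0 + seq_len(n), m0 + seq_len(n)]
  }
  out
}

#' Describe a lesion
#'
#' @param kind `"full"` (inactivate a whole network), `"regional"` (spare a
#'   contiguous corner region) or `"decimation"` (spare one fixed neuron per
#'   `block x block` tile).
#' @param z Index of the lesioned network.
#' @param corner_frac For regional lesions, the fraction of the sheet area
#'   preserved as a square corner region (0 reduces to a full lesion).
#' @param block Decimation block size.
#' @return An object of class `lesion_spec`.
#' @export
lesion_spec <- function(kind = c("full", "regional", "decimation"),
                        z, corner_frac = 0.25, block = 3L) {
  kind <- match.arg(kind)
  stopifnot(corner_frac >= 0, corner_frac <= 1, block >= 1)
  structure(list(kind = kind, z = as.integer(z),
                 corner_frac = corner_frac, block = as.integer(block)),
            class = "lesion_spec")
}

#' Apply a lesion to the network state
#'
#' Updates the activity mask and immediately zeroes the rates of inactivated
#' neurons; [advance()] holds them at zero thereafter.
#'
#' @param state A [network_state()] object.
#' @param spec A [lesion_spec()].
#' @param params The [grid_params()] the state was built with.
#' @return The lesioned `grid_state`.
#' @export
apply_lesion <- function(state, spec, params) {
  stopifnot(inherits(state, "grid_state"), inherits(spec, "lesion_spec"))
  h <- length(state$rates); n <- nrow(state$rates[[1]])
  if (spec$z < 1L || spec$z > h) stop("lesioned network z outside 1..h", call. = FALSE)
  mask <- matrix(0, n, n)
  if (spec$kind == "regional") {
    side <- floor(n * sqrt(spec$corner_frac))
    if (side > 0) mask[seq_len(side), seq_len(side)] <- 1
  } else if (spec$kind == "decimation") {
    keep <- seq(1L, n, by = spec$block)
    mask[keep, keep] <- 1
  }
  lesion <- state$lesion
  if (is.null(lesion)) lesion <- lapply(seq_len(h), function(z) matrix(1, n, n))
  lesion[[spec$z]] <- lesion[[spec$z]] * mask
  state$lesion <- lesion
  state$rates <- lapply(seq_len(h), function(z) state$rates[[z]] * lesion[[z]])
  state
}
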