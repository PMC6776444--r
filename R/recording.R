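#' Choose neurons to record
#'
#' Picks `per_network` neurons per network, deterministically from the
#' current RNG state, restricted to the central part of the sheet (at least
#' a quarter-width away from the edges, where the tapered drive keeps the
#' attractor pattern well formed).
#'
#' @param params A [grid_params()] object.
#' @param per_network Neurons recorded per network (default 3).
#' @param seed Optional integer seed.
#' @return Integer matrix with columns `z, x, y`.
#' @export
choose_record_neurons <- function(params, per_network = 3, seed = NULL) {
  validate_params(params)
  if (!is.null(seed)) set.seed(seed)
  if (per_network == 0) return(matrix(integer(0), 0, 3,
                                      dimnames = list(NULL, c("z", "x", "y"))))
  n <- params$n
  lo <- ceiling(n / 4); hi <- floor(3 * n / 4)
  out <- do.call(rbind, lapply(seq_len(params$h), function(z)
    cbind(z = z, x = sample(lo:hi, per_network, replace = FALSE),
          y = sample(lo:hi, per_network, replace = FALSE))))
  storage.mode(out) <- "integer"
  out
}

#' Combine a recording with trajectory positions
#'
#' @param recording The `recording` matrix returned by [advance()].
#' @param rec_idx The `z, x, y` matrix the recording was made with.
#' @param traj The `trajectory` the simulation was driven by.
#' @return A tibble: `neuron`, `z`, `x_n`, `y_n` (sheet position), `time_ms`,
#'   `pos_x`, `pos_y` (cm), `rate`.
#' @export
recording_samples <- function(recording, rec_idx, traj) {
  steps <- attr(recording, "steps")
  tms <- attr(recording, "time_ms")
  px <- traj$x[steps + 1L]; py <- traj$y[steps + 1L]
  purrr::map_dfr(seq_len(nrow(rec_idx)), function(q)
    tibble::tibble(neuron = q, z = rec_idx[q, 1],
                   x_n = rec_idx[q, 2], y_n = rec_idx[q, 3],
                   time_ms = tms, pos_x = px, pos_y = py,
                   rate = recording[, q]))
}

#' Build a spatial rate map from recorded samples
#'
#' Bins the recorded activity of one neuron by the animal's position. Rates
#' are continuous, so the per-bin value is the occupancy-weighted (here:
#' equal-duration sample) mean rate; in spiking mode the recorded samples
#' are spike counts and the per-bin value is total count over occupancy
#' time. Optional Gaussian smoothing uses normalized convolution so that
#' unvisited (`NA`) bins neither bleed nor shrink the visited region.
#'
#' @param samples Tibble from [recording_samples()] filtered to one neuron
#'   (columns `pos_x`, `pos_y`, `rate`), or any tibble with those columns.
#' @param params A [grid_params()] object (enclosure size).
#' @param bin_cm Spatial bin width, cm.
#' @param smooth_sd Gaussian smoothing sd in bins; 0 disables.
#' @param sample_dt_ms Duration represented by one sample, ms (for the
#'   occupancy map).
#' @param spiking Samples are spike counts rather than rates.
#' @return An object of class `rate_map`: list with `rate` (matrix, `NA` =
#'   unvisited), `occupancy` (seconds), `bin_cm`, `centers_x`, `centers_y`.
#' @export
build_rate_map <- function(samples, params = grid_params(), bin_cm = 3,
                           smooth_sd = 1, sample_dt_ms = NULL,
                           spiking = FALSE) {
  stopifnot(nrow(samples) > 0)
  R <- params$enclosure_diameter / 2
  edges <- seq(-R, R + bin_cm, by = bin_cm)
  nb <- length(edges) - 1
  ix <- findInterval(samples$pos_x, edges, rightmost.closed = TRUE)
  iy <- findInterval(samples$pos_y, edges, rightmost.closed = TRUE)
  keep <- ix >= 1 & ix <= nb & iy >= 1 & iy <= nb
  ix <- ix[keep]; iy <- iy[keep]; rate <- samples$rate[keep]
  if (length(rate) == 0) stop("no samples fall inside the enclosure", call. = FALSE)
  if (is.null(sample_dt_ms)) {
    tms <- samples$time_ms[keep]
    sample_dt_ms <- if (length(unique(tms)) > 1) min(diff(sort(unique(tms)))) else 1
  }
  counts <- matrix(0, nb, nb); sums <- matrix(0, nb, nb)
  for (q in seq_along(rate)) {
    counts[ix[q], iy[q]] <- counts[ix[q], iy[q]] + 1
    sums[ix[q], iy[q]] <- sums[ix[q], iy[q]] + rate[q]
  }
  occupancy <- counts * sample_dt_ms / 1000
  rmap <- if (spiking) {
    ifelse(counts > 0, sums / pmax(occupancy, .Machine$double.eps), NA_real_)
  } else {
    ifelse(counts > 0, sums / pmax(counts, 1), NA_real_)
  }
  rmap[counts == 0] <- NA_real_
  if (all(is.na(rmap))) stop("all bins unvisited", call. = FALSE)
  if (smooth_sd > 0) rmap <- smooth_na(rmap, smooth_sd)
  structure(list(rate = rmap, occupancy = occupancy, bin_cm = bin_cm,
                 centers_x = edges[1:nb] + bin_cm / 2,
                 centers_y = edges[1:nb] + bin_cm / 2),
            class = "rate_map")
}

# Gaussian smoothing with NA-aware normalized convolution
smooth_na <- function(m, sd_bins) {
  r <- ceiling(3 * sd_bins)
  off <- -r:r
  g <- exp(-off^2 / (2 * sd_bins^2)); g <- g / sum(g)
  ok <- is.finite(m)
  x <- m; x[!ok] <- 0
  conv1 <- function(a, along) {
    out <- array(0, dim(a))
    for (i in seq_along(off)) {
      sh <- shift_mat(a, if (along == 1) off[i] else 0,
                      if (along == 2) off[i] else 0)
      out <- out + g[i] * sh
    }
    out
  }
  num <- conv1(conv1(x, 1), 2)
  den <- conv1(conv1(ok + 0, 1), 2)
  out <- num / pmax(den, .Machine$double.eps)
  out[!ok] <- NA_real_
  out
}

# shift a matrix with zero fill
shift_mat <- function(a, dx, dy) {
  nr <- nrow(a); nc <- ncol(a)
  out <- matrix(0, nr, nc)
  sr <- max(1, 1 + dx):min(nr, nr + dx)
  sc <- max(1, 1 + dy):min(nc, nc + dy)
  out[sr, sc] <- a[sr - dx, sc - dy]
  out
}

#' Grid properties of a spatial rate map
#'
#' @param map A [build_rate_map()] object.
#' @inheritParams grid_props
#' @return A one-row tibble as in [grid_props()]; `scale` in cm.
#' @export
rate_map_grid_props <- function(map, cutoff = 0.6) {
  stopifnot(inherits(map, "rate_map"))
  grid_props(map$rate, bin = map$bin_cm, cutoff = cutoff)
}
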