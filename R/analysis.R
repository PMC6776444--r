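#' Spatial autocorrelogram of a 2D field
#'
#' Normalized autocorrelation: the Pearson correlation of the field with a
#' copy of itself displaced by each offset, computed over the bins where both
#' copies are defined. Undefined (`NA`) bins -- e.g. unvisited rate-map bins
#' -- are excluded from every overlap. Evaluated with FFT cross-correlations
#' of the field, its square and its defined-bin indicator.
#'
#' @param map Numeric matrix, possibly with `NA`s.
#' @param min_overlap Minimum number of overlapping defined bins for a
#'   correlation to be reported; offsets with fewer are `NA`.
#' @return A `(2 nrow - 1) x (2 ncol - 1)` matrix of correlations; entry
#'   `[nrow, ncol]` is the zero offset and equals 1.
#' @export
autocorrelogram <- function(map, min_overlap = 20) {
  stopifnot(is.matrix(map))
  ok <- is.finite(map)
  if (sum(ok) < 2) stop("map has fewer than two defined bins", call. = FALSE)
  v <- stats::var(map[ok])
  if (!is.finite(v) || v == 0)
    stop("degenerate (constant) map has no autocorrelation", call. = FALSE)
  x <- map; x[!ok] <- 0
  nr <- nrow(map); nc <- ncol(map)
  P1 <- next_fast_size(2 * nr); P2 <- next_fast_size(2 * nc)
  pad <- function(m) { A <- matrix(0, P1, P2); A[1:nr, 1:nc] <- m; A }
  f <- function(m) stats::fft(pad(m))
  X <- f(x); X2 <- f(x^2); I <- f(ok + 0)
  xc <- function(A, B) Re(stats::fft(A * Conj(B), inverse = TRUE)) / (P1 * P2)
  s_xy <- xc(X, X)    # sum over overlap of x(r) x(r+t)
  s_x  <- xc(X, I)    # sum of x over overlap, shifted copy defined
  s_y  <- xc(I, X)
  s_x2 <- xc(X2, I)
  s_y2 <- xc(I, X2)
  m    <- xc(I, I)    # overlap counts
  wrap <- function(A) {
    # reorder circular lags to -(nr-1)..(nr-1) x -(nc-1)..(nc-1)
    rows <- c((P1 - nr + 2):P1, 1:nr)
    cols <- c((P2 - nc + 2):P2, 1:nc)
    A[rows, cols]
  }
  s_xy <- wrap(s_xy); s_x <- wrap(s_x); s_y <- wrap(s_y)
  s_x2 <- wrap(s_x2); s_y2 <- wrap(s_y2); m <- round(wrap(m))
  num <- s_xy - s_x * s_y / m
  den <- sqrt(pmax(s_x2 - s_x^2 / m, 0) * pmax(s_y2 - s_y^2 / m, 0))
  ac <- num / den
  ac[m < min_overlap | den <= .Machine$double.eps^0.5 * abs(num + 1)] <- NA
  ac[!is.finite(ac)] <- NA
  ac[nr, nc] <- 1
  structure(ac, class = c("autocorrelogram", "matrix"))
}

# bilinear interpolation of the autocorrelogram on polar samples
polar_profile <- function(ac, dr = 0.5, dtheta = 1) {
  nr <- (nrow(ac) + 1) / 2; nc <- (ncol(ac) + 1) / 2
  rmax <- floor(min(nr, nc) - 2)
  radii <- seq(dr, rmax, by = dr)
  angles <- seq(0, 360 - dtheta, by = dtheta) * pi / 180
  ca <- cos(angles); sa <- sin(angles)
  vals <- matrix(NA_real_, length(radii), length(angles))
  for (i in seq_along(radii)) {
    px <- nr + radii[i] * ca
    py <- nc + radii[i] * sa
    x0 <- floor(px); y0 <- floor(py)
    fx <- px - x0; fy <- py - y0
    v00 <- ac[cbind(x0, y0)]; v10 <- ac[cbind(x0 + 1, y0)]
    v01 <- ac[cbind(x0, y0 + 1)]; v11 <- ac[cbind(x0 + 1, y0 + 1)]
    vals[i, ] <- (1 - fx) * (1 - fy) * v00 + fx * (1 - fy) * v10 +
      (1 - fx) * fy * v01 + fx * fy * v11
  }
  list(radii = radii, angles_deg = angles * 180 / pi, values = vals)
}

# first local minimum of a (lightly smoothed) radial profile
first_local_min <- function(r, v) {
  vs <- stats::filter(v, rep(1 / 5, 5), sides = 2)
  vs[is.na(vs)] <- v[is.na(vs)]
  for (i in 2:(length(vs) - 1)) {
    if (is.na(vs[i]) || is.na(vs[i - 1]) || is.na(vs[i + 1])) next
    if (vs[i] <= vs[i - 1] && vs[i] <= vs[i + 1]) return(r[i])
  }
  NA_real_
}

# parabolic refinement of a discrete argmax
refine_peak <- function(x, y, i) {
  if (i <= 1 || i >= length(x) || any(!is.finite(y[(i - 1):(i + 1)])))
    return(x[i])
  d <- (y[i - 1] - y[i + 1]) / 2 / (y[i - 1] - 2 * y[i] + y[i + 1])
  x[i] + d * (x[2] - x[1])
}

#' Grid scale, orientation and gridness of a 2D field
#'
#' Implements the annulus analysis of the autocorrelogram. The annulus is
#' bounded below by the first local minimum of the angle-averaged
#' autocorrelation and extends to 1.5x the six-peak ring radius (estimated as
#' the radius maximizing the angle-averaged autocorrelation, iterated once).
#' Grid scale is that maximizing radius. The annulus is then averaged over
#' radius to a function of angle whose sixth Fourier harmonic yields
#' gridness (sixth-harmonic power over total non-constant power; the
#' constant angular component is excluded from the denominator) and
#' orientation (the coefficient's complex phase divided by six, reported in
#' `[0, 60)` degrees). Fields with gridness at or above `cutoff` count as
#' grids.
#'
#' @param map Matrix: a population snapshot or a rate map (`NA`s allowed).
#' @param bin Physical size of one bin (neurons for snapshots, cm for rate
#'   maps); scale is reported in these units.
#' @param cutoff Gridness threshold for `is_grid`.
#' @param ac Optionally, a precomputed [autocorrelogram()] of `map`.
#' @return A one-row tibble: `scale`, `orientation`, `gridness`, `is_grid`.
#'   `scale` and `orientation` are `NA` when no peak annulus is identifiable.
#' @export
grid_props <- function(map, bin = 1, cutoff = 0.6, ac = NULL) {
  empty <- tibble::tibble(scale = NA_real_, orientation = NA_real_,
                          gridness = 0, is_grid = FALSE)
  if (is.null(ac)) {
    # degenerate maps (e.g. a silent lesioned sheet) are not grids
    ac <- tryCatch(autocorrelogram(map), error = function(e) NULL)
    if (is.null(ac)) return(empty)
  }
  pol <- polar_profile(ac)
  radial <- rowMeans(pol$values, na.rm = TRUE)
  # a ring that holds six peaks needs most of its circle inside the map:
  # radii with under half their angular samples defined cannot be the ring
  coverage <- rowMeans(is.finite(pol$values))
  radial[coverage < 0.5] <- NA
  r <- pol$radii
  r_in <- first_local_min(r, radial)
  if (!is.finite(r_in) || r_in >= max(r)) return(empty)
  # six-peak ring radius: angle-averaged maximum beyond the central peak,
  # then restricted to 1.5x the first estimate (one iteration)
  r_out <- max(r)
  for (iter in 1:2) {
    sel <- which(r > r_in & r <= r_out)
    if (length(sel) < 3) return(empty)
    i <- sel[which.max(radial[sel])]
    ring <- refine_peak(r, radial, i)
    r_out <- min(1.5 * ring, max(r))
  }
  sel <- which(r > r_in & r <= r_out)
  ang <- pol$angles_deg
  g <- colMeans(pol$values[sel, , drop = FALSE], na.rm = TRUE)
  if (any(!is.finite(g))) return(empty)
  th <- ang * pi / 180
  co <- vapply(1:(length(ang) %/% 2), function(m)
    abs(mean(g * exp(-1i * m * th)))^2, numeric(1))
  gridness <- co[6] / sum(co)
  c6 <- mean(g * exp(-1i * 6 * th))
  orientation <- (-Arg(c6) / 6 * 180 / pi) %% 60
  tibble::tibble(scale = ring * bin, orientation = orientation,
                 gridness = gridness, is_grid = gridness >= cutoff)
}

#' Grid properties of a population-activity snapshot
#'
#' Applies the same scale/orientation/gridness pipeline to the instantaneous
#' `n x n` population activity of one network; scale is in neurons.
#'
#' @param snapshot An `n x n` rate field.
#' @inheritParams grid_props
#' @return A one-row tibble as in [grid_props()].
#' @export
network_grid_props <- function(snapshot, cutoff = 0.6) {
  grid_props(snapshot, bin = 1, cutoff = cutoff)
}

#' Ideal triangular grid field
#'
#' Sum of three plane waves at 60 degree spacing: a noise-free triangular
#' lattice used as the analysis pipeline's ground-truth generator.
#'
#' @param nx,ny Field dimensions (bins).
#' @param scale Lattice constant (distance between neighboring peaks), bins.
#' @param orientation_deg Direction from a lattice point to a nearest
#'   neighbor, degrees.
#' @param phase Length-2 offset of the lattice origin, bins.
#' @param bin Bin size; `scale` is interpreted in these units.
#' @return Matrix with values in `[-1.5, 3]` (maxima at lattice points).
#' @export
synthetic_grid_field <- function(nx, ny, scale, orientation_deg = 0,
                                 phase = c(0, 0), bin = 1) {
  k <- 4 * pi / (sqrt(3) * (scale / bin))
  wave_ang <- (orientation_deg + c(30, 90, 150)) * pi / 180
  x <- seq_len(nx); y <- seq_len(ny)
  f <- matrix(0, nx, ny)
  for (a in wave_ang) {
    kx <- k * cos(a); ky <- k * sin(a)
    f <- f + cos(outer(kx * (x - phase[1] / bin), ky * (y - phase[2] / bin), `+`))
  }
  f
}
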