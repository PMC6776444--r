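# Brute-force oracles: direct summation of the recurrent and coupling sums,
# independent of any FFT machinery.

brute_recurrent <- function(s, code, xi, l, w_mag) {
  n <- nrow(s)
  out <- matrix(0, n, n)
  ex <- c(1, -1, 0, 0); ey <- c(0, 0, 1, -1)
  for (x in 1:n) for (y in 1:n) {
    acc <- 0
    for (xs in 1:n) for (ys in 1:n) {
      k <- code[xs, ys]
      dx <- x - xs + xi * ex[k]; dy <- y - ys + xi * ey[k]
      acc <- acc + inhibition_weight(sqrt(dx^2 + dy^2), l, w_mag) * s[xs, ys]
    }
    out[x, y] <- acc
  }
  out
}

brute_coupling <- function(s_src, d, u_mag) {
  n <- nrow(s_src)
  out <- matrix(0, n, n)
  for (x in 1:n) for (y in 1:n) {
    acc <- 0
    for (xs in 1:n) for (ys in 1:n)
      acc <- acc + coupling_weight(sqrt((x - xs)^2 + (y - ys)^2), d, u_mag) *
        s_src[xs, ys]
    out[x, y] <- acc
  }
  out
}

# peak-finding oracle: local maxima of a field, nearest-neighbor spacing and
# direction (independent of the autocorrelogram pipeline)
oracle_peaks <- function(f, halfwin = 2, thresh = 0.7) {
  n1 <- nrow(f); n2 <- ncol(f)
  thr <- thresh * max(f, na.rm = TRUE)
  pk <- NULL
  for (i in (1 + halfwin):(n1 - halfwin))
    for (j in (1 + halfwin):(n2 - halfwin)) {
      v <- f[i, j]
      if (is.na(v) || v <= thr) next
      w <- f[(i - halfwin):(i + halfwin), (j - halfwin):(j + halfwin)]
      if (v >= max(w, na.rm = TRUE)) pk <- rbind(pk, c(i, j))
    }
  pk
}

oracle_spacing <- function(f, ...) {
  pk <- oracle_peaks(f, ...)
  d <- as.matrix(stats::dist(pk)); diag(d) <- Inf
  stats::median(apply(d, 1, min))
}

# sharpened (bump-like) triangular field, closer to real rate maps than the
# raw three-wave sum
bump_grid_field <- function(nx, ny, scale, orientation_deg = 0,
                            phase = c(0, 0), sharp = 2) {
  f <- synthetic_grid_field(nx, ny, scale, orientation_deg, phase)
  exp(sharp * (f - 3))
}

# small fast parameter sets for structural tests
tiny_params <- function(...) {
  grid_params(h = 3, n = 40, l_min = 4, l_max = 8, d = 5,
              enclosure_diameter = 100, ...)
}
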