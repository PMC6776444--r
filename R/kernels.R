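#' Broad excitatory drive profile
#'
#' Closed-form drive as a function of scaled radial distance from the sheet
#' center. Neurons at scaled radius `r_scaled >= 1` (outside the circle
#' inscribed in the sheet) receive zero drive; the Gaussian falloff toward
#' the sheet edge prevents boundary artifacts in the attractor pattern.
#'
#' @param r_scaled Radial distance from the sheet center divided by the sheet
#'   half-width `n/2`.
#' @param a_mag,a_fall Drive magnitude and falloff.
#' @return Drive values, same shape as `r_scaled`.
#' @export
drive_profile <- function(r_scaled, a_mag = 1, a_fall = 4) {
  ifelse(r_scaled < 1, a_mag * exp(-a_fall * r_scaled^2), 0)
}

#' Build the n x n broad drive field
#'
#' Samples [drive_profile()] on the integer neuron grid. The sheet center is
#' at `((n + 1)/2, (n + 1)/2)` and distances are normalized by the half-width
#' `n/2`, so the drive reaches zero at the circle inscribed in the sheet.
#'
#' @param params A [grid_params()] object.
#' @return An `n x n` matrix `a[x, y]`.
#' @export
build_drive <- function(params) {
  validate_params(params)
  n <- params$n
  cc <- (n + 1) / 2
  dx <- (seq_len(n) - cc)
  r_scaled <- sqrt(outer(dx^2, dx^2, `+`)) / n
  matrix(drive_profile(r_scaled, params$a_mag, params$a_fall), n, n)
}

#' Inhibition-distance profile along the stack
#'
#' Interpolates the inhibition distance from `l_min` at the most dorsal
#' network to `l_max` at the most ventral one, with concavity set by `l_exp`:
#' `l(z) = [l_min^l_exp + (l_max^l_exp - l_min^l_exp) (z-1)/(h-1)]^(1/l_exp)`.
#' For `l_exp = 0` the limiting log-linear (geometric) interpolation is used.
#'
#' @param params A [grid_params()] object.
#' @return Numeric vector `l(z)`, `z = 1..h`; monotone nondecreasing.
#' @export
inhibition_profile <- function(params) {
  validate_params(params)
  h <- params$h
  if (h == 1L) return(params$l_min)
  z <- seq_len(h)
  frac <- (z - 1) / (h - 1)
  if (params$l_exp == 0) {
    params$l_min^(1 - frac) * params$l_max^frac
  } else {
    e <- params$l_exp
    (params$l_min^e + (params$l_max^e - params$l_min^e) * frac)^(1 / e)
  }
}

#' Radial inhibition weight
#'
#' Center-surround (purely inhibitory) recurrent weight with peak inhibition
#' `-w_mag / l^2` at distance `l` and compact support `r < 2 l`. The `1/l^2`
#' scaling keeps the integrated inhibition approximately constant across
#' networks with different inhibition distances.
#'
#' @param r Distance on the neural sheet, neurons.
#' @param l Inhibition distance, neurons (`> 0`).
#' @param w_mag Inhibition magnitude.
#' @return Weight values `<= 0`, zero for `r >= 2 l`.
#' @export
inhibition_weight <- function(r, l, w_mag = 2.4) {
  stopifnot(l > 0)
  ifelse(r < 2 * l, -(w_mag / l^2) * (1 - cos(pi * r / l)) / 2, 0)
}

#' Radial coupling weight
#'
#' Excitatory weight from a neuron in one network onto neurons at sheet
#' distance `r` in the neighboring network: maximal `u_mag / d^2` at `r = 0`,
#' decaying to zero at the spread `d`.
#'
#' @param r Distance on the neural sheet, neurons.
#' @param d Coupling spread, neurons (`> 0`).
#' @param u_mag Coupling magnitude.
#' @return Weight values `>= 0`, zero for `r >= d`.
#' @export
coupling_weight <- function(r, d = 8, u_mag = 2.6) {
  stopifnot(d > 0)
  ifelse(r < d, (u_mag / d^2) * (1 + cos(pi * r / d)) / 2, 0)
}

#' Sample a radial kernel on integer sheet offsets
#'
#' @param fun Function of Euclidean offset length returning a weight.
#' @param radius Kernel half-width in neurons; the result is a
#'   `(2 radius + 1)` square matrix whose center entry is the zero offset.
#' @return Matrix of sampled weights.
#' @export
sample_kernel <- function(fun, radius) {
  off <- seq(-radius, radius)
  r <- sqrt(outer(off^2, off^2, `+`))
  matrix(fun(r), length(off), length(off))
}

#' Build the per-depth inhibition kernel
#'
#' Samples [inhibition_weight()] on integer offsets with half-width
#' `ceiling(2 l)`, matching the continuous cutoff exactly (the sampled kernel
#' is identically zero outside the support).
#'
#' @param l_z Inhibition distance for this network.
#' @param params A [grid_params()] object.
#' @export
build_inhibition_kernel <- function(l_z, params) {
  stopifnot(l_z > 0)
  sample_kernel(function(r) inhibition_weight(r, l_z, params$w_mag),
                ceiling(2 * l_z))
}

#' Build the coupling kernel
#'
#' @param params A [grid_params()] object.
#' @param d Coupling spread; defaults to `params$d`. Pass `l(z)` values here
#'   for the depth-dependent spread variant.
#' @export
build_coupling_kernel <- function(params, d = params$d) {
  stopifnot(d > 0)
  sample_kernel(function(r) coupling_weight(r, d, params$u_mag), ceiling(d))
}

#' Assign the four direction subpopulations
#'
#' Every neuron belongs to one of four subpopulations that evenly tile the
#' sheet in repeated 2x2 blocks (top row `+x`, `-x`; bottom row `+y`, `-y`).
#' Each subpopulation has a preferred network direction `e` (the direction in
#' which its inhibitory outputs are shifted by `xi` neurons) and a paired
#' preferred spatial direction `E` (the direction of animal motion that
#' increases its drive).
#'
#' @param params A [grid_params()] object (only `n` is used; `n` even).
#' @return A list with `code` (`n x n` integer matrix in 1..4), `e_x`, `e_y`
#'   (network direction components) and `E_x`, `E_y` (spatial direction
#'   components), each `n x n`.
#' @export
assign_subpopulations <- function(params) {
  validate_params(params)
  n <- params$n
  xi_ <- seq_len(n)
  odd_x <- matrix(xi_ %% 2L == 1L, n, n)
  odd_y <- matrix(rep(xi_ %% 2L == 1L, each = n), n, n)
  code <- matrix(0L, n, n)
  code[odd_x & odd_y]   <- 1L  # +x
  code[!odd_x & odd_y]  <- 2L  # -x
  code[odd_x & !odd_y]  <- 3L  # +y
  code[!odd_x & !odd_y] <- 4L  # -y
  ex <- c(1, -1, 0, 0); ey <- c(0, 0, 1, -1)
  list(code = code,
       e_x = matrix(ex[code], n, n), e_y = matrix(ey[code], n, n),
       E_x = matrix(ex[code], n, n), E_y = matrix(ey[code], n, n))
}

#' Precompute all static model structures
#'
#' Bundles the drive field, inhibition-distance profile, per-depth inhibition
#' kernels, coupling kernel(s) and subpopulation direction fields.
#'
#' @param params A [grid_params()] object.
#' @return An object of class `grid_kernels`: list with `drive`, `l_profile`,
#'   `inhibition` (list over `z`), `coupling` (list over source `z`; entries
#'   are identical unless `d_follows_l`), `d_profile`, and `subpop`.
#' @export
build_kernels <- function(params) {
  validate_params(params)
  lz <- inhibition_profile(params)
  dz <- if (params$d_follows_l) lz else rep(params$d, params$h)
  structure(list(
    drive = build_drive(params),
    l_profile = lz,
    inhibition = lapply(lz, build_inhibition_kernel, params = params),
    coupling = lapply(dz, function(d) build_coupling_kernel(params, d)),
    d_profile = dz,
    subpop = assign_subpopulations(params),
    params = params
  ), class = "grid_kernels")
}
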