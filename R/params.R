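#' Model parameters for the coupled attractor stack
#'
#' Constructs and validates the single configuration object used throughout
#' the package. Defaults are the standard values of the full 12-network grid
#' system; pass overrides to explore variants.
#'
#' Lowercase quantities live on the neural sheet (units of neurons); the
#' animal's environment uses physical units (cm, m/s).
#'
#' @param h Number of attractor networks along the dorso-ventral axis.
#' @param n Side length of each square neural sheet, in neurons (even).
#' @param dt Simulation timestep, ms.
#' @param tau Neural relaxation time, ms. Must satisfy `dt <= tau`.
#' @param a_mag Magnitude of the broad excitatory drive (dimensionless).
#' @param a_fall Falloff of the broad drive with scaled radius.
#' @param l_min,l_max Inhibition distance at the most dorsal (`z = 1`) and
#'   most ventral (`z = h`) network, in neurons.
#' @param l_exp Exponent controlling the concavity of the inhibition-distance
#'   profile; more negative is more concave. `l_exp = 0` uses the geometric
#'   (log-linear) limit.
#' @param w_mag Inhibition magnitude; the kernel is scaled by `1/l(z)^2` so
#'   integrated inhibition is approximately depth-independent.
#' @param xi Subpopulation output shift, neurons.
#' @param u_mag Inter-network coupling magnitude; scaled by `1/d^2`.
#' @param d Coupling spread, neurons. When `d_follows_l` is `TRUE` the spread
#'   for projections out of network `z` is `l(z)` instead.
#' @param alpha Velocity gain, s/m: how strongly the animal's velocity
#'   modulates the broad drive of the four direction subpopulations.
#' @param coupling_direction One of `"ventral_to_dorsal"` (default: network
#'   `z + 1` excites `z`), `"dorsal_to_ventral"`, `"bidirectional"`, `"none"`.
#' @param d_follows_l Use a per-depth coupling spread `d(z) = l(z)`.
#' @param enclosure_diameter Diameter of the circular enclosure, cm.
#' @param speed_max Maximum animal speed, m/s.
#' @param rng_seed Optional default seed recorded with the configuration.
#'
#' @return An object of class `grid_params` (a validated named list).
#' @examples
#' p <- grid_params(h = 6, n = 76)
#' inhibition_profile(p)
#' @export
grid_params <- function(h = 12, n = 160, dt = 1, tau = 10,
                        a_mag = 1, a_fall = 4,
                        l_min = 4, l_max = 15, l_exp = -1,
                        w_mag = 2.4, xi = 1,
                        u_mag = 2.6, d = 8,
                        alpha = 0.3,
                        coupling_direction = c("ventral_to_dorsal",
                                               "dorsal_to_ventral",
                                               "bidirectional", "none"),
                        d_follows_l = FALSE,
                        enclosure_diameter = 180, speed_max = 1,
                        rng_seed = NULL) {
  coupling_direction <- match.arg(coupling_direction)
  p <- structure(
    list(h = as.integer(h), n = as.integer(n), dt = dt, tau = tau,
         a_mag = a_mag, a_fall = a_fall,
         l_min = l_min, l_max = l_max, l_exp = l_exp,
         w_mag = w_mag, xi = as.integer(xi),
         u_mag = u_mag, d = d, alpha = alpha,
         coupling_direction = coupling_direction,
         d_follows_l = isTRUE(d_follows_l),
         enclosure_diameter = enclosure_diameter,
         speed_max = speed_max,
         rng_seed = rng_seed),
    class = "grid_params")
  validate_params(p)
}

validate_params <- function(p) {
  stopifnot(inherits(p, "grid_params"))
  if (p$h < 1L) stop("h must be >= 1", call. = FALSE)
  if (p$n < 4L) stop("n must be >= 4", call. = FALSE)
  if (p$n %% 2L != 0L) stop("n must be even (2x2 subpopulation tiling)", call. = FALSE)
  if (!(p$dt > 0 && p$dt <= p$tau))
    stop("need 0 < dt <= tau for a stable rectified Euler update", call. = FALSE)
  if (!(p$l_min > 0 && p$l_max > 0 && p$l_min <= p$l_max))
    stop("need 0 < l_min <= l_max", call. = FALSE)
  if (p$h == 1L && p$l_min != p$l_max)
    stop("h = 1 requires l_min == l_max (profile endpoints coincide)", call. = FALSE)
  if (p$d <= 0) stop("coupling spread d must be > 0", call. = FALSE)
  if (p$alpha <= 0) stop("velocity gain alpha must be > 0", call. = FALSE)
  for (f in c("a_mag", "a_fall", "w_mag", "u_mag"))
    if (p[[f]] < 0) stop(f, " must be >= 0", call. = FALSE)
  if (p$xi < 0) stop("xi must be >= 0", call. = FALSE)
  if (p$enclosure_diameter <= 0 || p$speed_max <= 0)
    stop("enclosure_diameter and speed_max must be > 0", call. = FALSE)
  p
}

#' @export
print.grid_params <- function(x, ...) {
  cat(sprintf("<grid_params> %d networks of %d x %d neurons\n", x$h, x$n, x$n))
  cat(sprintf("  l(z): %.3g..%.3g (exponent %.3g)  w_mag %.3g  xi %d\n",
              x$l_min, x$l_max, x$l_exp, x$w_mag, x$xi))
  cat(sprintf("  coupling: %s, u_mag %.3g, d %s\n", x$coupling_direction,
              x$u_mag, if (x$d_follows_l) "= l(z)" else format(x$d)))
  cat(sprintf("  dt %g ms, tau %g ms, alpha %g s/m, arena %g cm, |V| <= %g m/s\n",
              x$dt, x$tau, x$alpha, x$enclosure_diameter, x$speed_max))
  invisible(x)
}

#' Read or write a flat key-value configuration file
#'
#' The configuration file is YAML with one documented key per [grid_params()]
#' field; unknown keys are rejected. Missing keys fall back to the defaults.
#'
#' @param path File path.
#' @return `read_params()` returns a `grid_params` object.
#' @export
read_params <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(grid_params))
  bad <- setdiff(names(vals), known)
  if (length(bad) > 0)
    stop("unknown configuration keys: ", paste(bad, collapse = ", "), call. = FALSE)
  do.call(grid_params, vals)
}

#' @rdname read_params
#' @param params A `grid_params` object.
#' @export
write_params <- function(params, path) {
  stopifnot(inherits(params, "grid_params"))
  vals <- unclass(params)
  vals <- vals[!vapply(vals, is.null, logical(1))]
  yaml::write_yaml(vals, path)
  invisible(path)
}
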