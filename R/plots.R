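#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

# long-format tibble for a matrix field
field_tbl <- function(m, xname = "x", yname = "y") {
  tibble::tibble(
    !!xname := rep(seq_len(nrow(m)), times = ncol(m)),
    !!yname := rep(seq_len(ncol(m)), each = nrow(m)),
    value = as.vector(m))
}

#' Plot a population-activity snapshot
#'
#' @param snapshot An `n x n` rate field.
#' @return A ggplot raster of the population pattern.
#' @export
plot_snapshot <- function(snapshot) {
  ggplot2::ggplot(field_tbl(snapshot),
                  ggplot2::aes(.data$x, .data$y, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = "rate") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (neurons)", y = "y (neurons)") +
    ggplot2::theme_minimal()
}

#' Overlay two population patterns
#'
#' Renders the classic two-color overlay: the first pattern in magenta, the
#' second in green; common activity appears white, emphasizing the lattice
#' registry between adjacent networks.
#'
#' @param snapshot_a,snapshot_b Same-sized rate fields (a = smaller `z`).
#' @return A ggplot raster.
#' @export
plot_overlay <- function(snapshot_a, snapshot_b) {
  norm <- function(m) m / max(m)
  a <- norm(snapshot_a); b <- norm(snapshot_b)
  tb <- field_tbl(a)
  tb$col <- grDevices::rgb(pmin(a, 1), pmin(b, 1), pmin(a, 1))
  ggplot2::ggplot(tb, ggplot2::aes(.data$x, .data$y, fill = .data$col)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_identity() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (neurons)", y = "y (neurons)") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.autocorrelogram <- function(object, ...) {
  m <- unclass(object)
  nr <- (nrow(m) + 1) / 2; nc <- (ncol(m) + 1) / 2
  tb <- field_tbl(m)
  tb$x <- tb$x - nr; tb$y <- tb$y - nc
  ggplot2::ggplot(tb, ggplot2::aes(.data$x, .data$y, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient2(name = "corr", limits = c(-1, 1)) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "offset x", y = "offset y") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.rate_map <- function(object, ...) {
  m <- object$rate
  tb <- field_tbl(m)
  tb$x <- object$centers_x[tb$x]; tb$y <- object$centers_y[tb$y]
  ggplot2::ggplot(tb, ggplot2::aes(.data$x, .data$y, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = "rate", na.value = "white") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (cm)", y = "y (cm)") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.module_partition <- function(object, ...) {
  cells <- dplyr::filter(object$cells, !is.na(.data$module))
  ggplot2::ggplot(cells,
                  ggplot2::aes(.data$scale, .data$orientation,
                               colour = factor(.data$module))) +
    ggplot2::geom_point(size = 2) +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_continuous(limits = c(0, 60),
                                breaks = seq(0, 60, 15)) +
    ggplot2::labs(x = "grid scale", y = "orientation (deg, mod 60)",
                  colour = "module") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.trajectory <- function(object, ...) {
  R <- attr(object, "enclosure_diameter") / 2
  circ <- tibble::tibble(t = seq(0, 2 * pi, length.out = 256))
  ggplot2::ggplot(object, ggplot2::aes(.data$x, .data$y)) +
    ggplot2::geom_path(alpha = 0.5, linewidth = 0.2) +
    ggplot2::geom_path(data = circ,
                       ggplot2::aes(R * cos(.data$t), R * sin(.data$t)),
                       colour = "red") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (cm)", y = "y (cm)") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.phase_table <- function(object, ...) {
  maj <- attr(object, "majority")
  ggplot2::ggplot(maj, ggplot2::aes(.data$l_ratio, .data$u_mag,
                                    fill = .data$majority_class)) +
    ggplot2::geom_tile() +
    ggplot2::facet_wrap(~d, labeller = ggplot2::label_both) +
    ggplot2::labs(x = "l(2)/l(1)", y = "coupling strength u_mag",
                  fill = "relationship") +
    ggplot2::theme_minimal()
}

#' Plot grid scales along the stack
#'
#' Scales per network (or per recorded cell) against depth z, colored by
#' replicate: the standard visualization of scale plateaus and module
#' jumps.
#'
#' @param run_set A `grid_run_set`.
#' @return A ggplot.
#' @export
plot_scale_profile <- function(run_set) {
  tb <- run_set$network_props
  ggplot2::ggplot(tb, ggplot2::aes(.data$z, .data$scale,
                                   colour = factor(.data$seed))) +
    ggplot2::geom_point() + ggplot2::geom_line(alpha = 0.4) +
    ggplot2::labs(x = "network z (dorsal to ventral)",
                  y = "network grid scale (neurons)", colour = "seed") +
    ggplot2::theme_minimal()
}
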