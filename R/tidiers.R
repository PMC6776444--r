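#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a module partition
#'
#' @param x A [cluster_modules()] result.
#' @param ... Unused.
#' @return The per-cell tibble with module assignments.
#' @export
tidy.module_partition <- function(x, ...) x$cells

#' @rdname tidy.module_partition
#' @export
glance.module_partition <- function(x, ...) {
  tibble::tibble(
    k = x$k,
    n_cells = nrow(x$cells),
    n_grid_cells = sum(!is.na(x$cells$module)),
    mean_scale_ratio = if (nrow(x$pairs)) mean(x$pairs$scale_ratio) else NA_real_,
    mean_orientation_diff = if (nrow(x$pairs)) mean(x$pairs$orientation_diff)
    else NA_real_)
}

#' Tidy a run set
#'
#' @param x A `grid_run_set` from [run_standard()] and friends.
#' @param what `"cells"` (per-cell or per-network grid properties with
#'   module labels), `"networks"` (per-network population-pattern
#'   properties) or `"pairs"` (adjacent-module statistics).
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.grid_run_set <- function(x, what = c("cells", "networks", "pairs"), ...) {
  switch(match.arg(what),
         cells = x$cell_props,
         networks = x$network_props,
         pairs = x$pairs)
}

#' @rdname tidy.grid_run_set
#' @export
glance.grid_run_set <- function(x, ...) {
  ks <- vapply(x$partitions, function(p) p$k, integer(1))
  tibble::tibble(
    protocol = x$protocol,
    replicates = length(x$seeds),
    modal_k = as.integer(names(sort(table(ks), decreasing = TRUE))[1]),
    mean_scale_ratio = if (nrow(x$pairs)) mean(x$pairs$scale_ratio) else NA_real_,
    sd_scale_ratio = if (nrow(x$pairs) > 1) stats::sd(x$pairs$scale_ratio)
    else NA_real_,
    mean_orientation_diff = if (nrow(x$pairs)) mean(x$pairs$orientation_diff)
    else NA_real_,
    sd_orientation_diff = if (nrow(x$pairs) > 1)
      stats::sd(x$pairs$orientation_diff) else NA_real_)
}

#' Tidy a lesion result
#'
#' @param x A [run_lesion()] result.
#' @param what `"networks"` or `"pairs"`.
#' @param ... Unused.
#' @export
tidy.lesion_result <- function(x, what = c("networks", "pairs"), ...) {
  switch(match.arg(what), networks = x$network_props, pairs = x$pairs)
}

#' @rdname tidy.lesion_result
#' @export
glance.lesion_result <- function(x, ...) {
  tibble::tibble(kind = x$spec$kind, z = x$spec$z,
                 replicates = length(x$seeds))
}
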