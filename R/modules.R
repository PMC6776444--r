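# circular helpers for orientations with 60-degree lattice period
circ_mean60 <- function(theta) {
  (Arg(mean(exp(1i * theta * 6 * pi / 180))) * 180 / pi / 6) %% 60
}
circ_sd60 <- function(theta) {
  Rbar <- Mod(mean(exp(1i * theta * 6 * pi / 180)))
  sqrt(pmax(-2 * log(Rbar), 0)) * 180 / pi / 6
}

#' Fold an orientation difference by lattice symmetry
#'
#' Triangular lattices are sixfold symmetric, so orientation is periodic
#' modulo 60 degrees and the difference between two lattices is at most 30.
#'
#' @param dtheta Differences in degrees.
#' @return Differences folded to `[0, 30]`.
#' @export
fold_orientation_diff <- function(dtheta) {
  d <- abs(dtheta) %% 60
  pmin(d, 60 - d)
}

# number of modes of a kernel-smoothed density over log-scale; the
# bandwidth floor (5% in scale) keeps plug-in bandwidths from resolving
# within-module measurement noise as spurious modes -- adjacent grid
# modules are separated by 35-70% in scale
kde_mode_count <- function(log_scale, min_frac = 0.05, bw_floor = 0.05) {
  x <- log_scale[is.finite(log_scale)]
  if (length(x) < 2 || stats::sd(x) == 0) return(1L)
  bw <- tryCatch(stats::bw.SJ(x), error = function(e) stats::bw.nrd0(x))
  if (!is.finite(bw) || bw <= 0) bw <- stats::bw.nrd0(x)
  bw <- max(bw, bw_floor)
  den <- stats::density(x, bw = bw, n = 512)
  y <- den$y
  peaks <- which(diff(sign(diff(y))) == -2) + 1
  if (y[1] > y[2]) peaks <- c(1, peaks)
  ny <- length(y)
  if (y[ny] > y[ny - 1]) peaks <- c(peaks, ny)
  max(1L, sum(y[peaks] >= min_frac * max(y)))
}

#' Cluster grid cells into modules
#'
#' Cells passing the gridness cutoff are clustered with k-means on
#' standardized (log scale, orientation) coordinates, the orientation being
#' embedded on a circle of period 60 degrees so that 58 and 2 degrees are
#' close. The number of modules k is the number of modes of a kernel-smoothed
#' density of log scale (Gaussian kernel, Sheather-Jones plug-in bandwidth,
#' modes below 5% of the density maximum ignored). Initial centers are the
#' within-group means after an ordered split of the scales, which makes the
#' procedure deterministic. Modules are relabelled in order of increasing
#' mean scale (M1 smallest).
#'
#' @param cells Tibble with columns `scale`, `orientation`, `gridness` (and
#'   any identifying columns, which are carried through), e.g. rows from
#'   [grid_props()].
#' @param cutoff Gridness cutoff; cells below it are dropped before
#'   clustering and returned with module `NA`.
#' @param k Optional fixed module count (overrides density-based selection).
#' @param orientation_weight Relative weight of the orientation embedding
#'   against standardized log scale.
#' @return An object of class `module_partition`: list with `cells` (input
#'   plus `module`), `modules` (per-module mean scale, circular mean and sd
#'   of orientation, size), `pairs` (adjacent-module scale ratios and folded
#'   orientation differences) and `k`.
#' @export
cluster_modules <- function(cells, cutoff = 0.6, k = NULL,
                            orientation_weight = 1) {
  stopifnot(all(c("scale", "orientation", "gridness") %in% names(cells)))
  cells <- tibble::as_tibble(cells)
  ok <- is.finite(cells$scale) & cells$gridness >= cutoff
  if (sum(ok) < 2) {
    cells$module <- NA_integer_
    return(structure(list(cells = cells,
                          modules = tibble::tibble(module = integer(0),
                                                   scale = numeric(0),
                                                   orientation = numeric(0),
                                                   orientation_sd = numeric(0),
                                                   n_cells = integer(0)),
                          pairs = empty_pairs(), k = 0L),
                     class = "module_partition"))
  }
  g <- cells[ok, ]
  ls <- log(g$scale)
  if (is.null(k)) k <- kde_mode_count(ls)
  k <- min(k, length(unique(ls)))
  sdl <- stats::sd(ls)
  z1 <- if (sdl > 0) (ls - mean(ls)) / sdl else ls * 0
  phi <- g$orientation * 6 * pi / 180
  feat <- cbind(z1, orientation_weight * cos(phi), orientation_weight * sin(phi))
  if (k == 1L) {
    lab <- rep(1L, nrow(g))
  } else {
    ord_split <- cut(rank(ls, ties.method = "first"),
                     breaks = k, labels = FALSE)
    centers <- do.call(rbind, lapply(seq_len(k), function(j)
      colMeans(feat[ord_split == j, , drop = FALSE])))
    lab <- tryCatch(
      suppressWarnings(stats::kmeans(feat, centers = centers)$cluster),
      error = function(e) ord_split)  # duplicate points: keep ordered split
  }
  # order modules by mean scale
  means <- vapply(seq_len(k), function(j) mean(g$scale[lab == j]), numeric(1))
  relab <- match(seq_len(k), order(means))
  lab <- relab[lab]
  cells$module <- NA_integer_
  cells$module[ok] <- lab
  modules <- dplyr::arrange(dplyr::summarise(
    dplyr::group_by(cells[ok, ], .data$module),
    scale = mean(.data$scale),
    orientation = circ_mean60(.data$orientation),
    orientation_sd = circ_sd60(.data$orientation),
    n_cells = dplyr::n(), .groups = "drop"), .data$module)
  structure(list(cells = cells, modules = modules,
                 pairs = module_pairs(modules), k = as.integer(max(lab))),
            class = "module_partition")
}

empty_pairs <- function() {
  tibble::tibble(pair = character(0), module_small = integer(0),
                 module_large = integer(0), scale_ratio = numeric(0),
                 orientation_diff = numeric(0))
}

# adjacent-module scale ratios (larger over smaller) and folded differences
module_pairs <- function(modules) {
  if (nrow(modules) < 2) return(empty_pairs())
  m <- dplyr::arrange(modules, .data$scale)
  i <- seq_len(nrow(m) - 1)
  tibble::tibble(
    pair = paste0("M", i + 1, "/M", i),
    module_small = m$module[i], module_large = m$module[i + 1],
    scale_ratio = m$scale[i + 1] / m$scale[i],
    orientation_diff = fold_orientation_diff(m$orientation[i + 1] -
                                               m$orientation[i]))
}

#' @export
print.module_partition <- function(x, ...) {
  cat(sprintf("<module_partition> %d modules from %d cells (%d grid cells)\n",
              x$k, nrow(x$cells), sum(!is.na(x$cells$module))))
  if (nrow(x$modules)) print(x$modules)
  if (nrow(x$pairs)) print(x$pairs)
  invisible(x)
}

#' Catalogue of commensurate triangular-lattice relationships
#'
#' Scale ratios and orientation differences at which two triangular lattices
#' admit a regular registry of lattice points (coincidence relations). The
#' principal case is ratio `sqrt(3)` with a 30 degree orientation
#' difference; the catalogue also ships the further standard coincidence
#' relations `2 / 0`, `sqrt(7) / 19.1` and `sqrt(13) / 13.9` (artifact
#' choice; extend or replace as needed).
#'
#' @return Tibble with `ratio` and `angle` (degrees).
#' @export
commensurate_catalogue <- function() {
  tibble::tibble(
    ratio = c(sqrt(3), 2, sqrt(7), sqrt(13)),
    angle = c(30, 0, 19.106605, 13.897886))
}

#' Classify the lattice relationship of an adjacent pair
#'
#' Applies the geometric taxonomy of adjacent-module (or adjacent-network)
#' grid relationships:
#' \itemize{
#'   \item commensurate: scale ratio within `ratio_tol` and orientation
#'     difference within `angle_tol` of a catalogue coincidence pair;
#'   \item defect: ratio below 1.1 with difference above 10 degrees (low
#'     activity overlap under strong coupling);
#'   \item discommensurate: ratio in 1.1--1.4 with difference at most 10
#'     degrees (registered patches separated by discommensuration lines);
#'   \item incommensurate: ratio above 1.3 with no consistent registry
#'     (weak coupling); requires low peak registry when `registry` is given.
#' }
#' Pairs matching none of the rules are resolved by the registry overlap
#' when available (high overlap is reported commensurate, low overlap
#' incommensurate) and are otherwise `unclassified`.
#'
#' @param scale_ratio Scale ratio(s), larger over smaller.
#' @param orientation_diff Orientation difference(s), degrees in `[0, 30]`.
#' @param registry Optional peak-registry fraction(s) from
#'   [overlay_registry()] used to break ties.
#' @param catalogue Commensurate catalogue tibble (`ratio`, `angle`).
#' @param ratio_tol,angle_tol Matching tolerances for commensurate pairs.
#' @param registry_low Registry fraction below which overlap counts as low.
#' @return Tibble: `scale_ratio`, `orientation_diff`, `class`.
#' @export
classify_relationship <- function(scale_ratio, orientation_diff,
                                  registry = NA_real_,
                                  catalogue = commensurate_catalogue(),
                                  ratio_tol = 0.05, angle_tol = 3,
                                  registry_low = 0.5) {
  nn <- max(length(scale_ratio), length(orientation_diff))
  r <- rep_len(scale_ratio, nn)
  a <- rep_len(fold_orientation_diff(orientation_diff), nn)
  reg <- rep_len(registry, nn)
  cls <- character(nn)
  for (i in seq_len(nn)) {
    comm <- any(abs(r[i] - catalogue$ratio) <= ratio_tol &
                  abs(a[i] - catalogue$angle) <= angle_tol)
    cls[i] <- if (comm) {
      "commensurate"
    } else if (r[i] < 1.1 && a[i] > 10) {
      "defect"
    } else if (r[i] >= 1.1 && r[i] <= 1.4 && a[i] <= 10) {
      "discommensurate"
    } else if (r[i] > 1.3 && (is.na(reg[i]) || reg[i] < registry_low)) {
      "incommensurate"
    } else if (!is.na(reg[i])) {
      if (reg[i] >= registry_low) "commensurate" else "incommensurate"
    } else {
      "unclassified"
    }
  }
  tibble::tibble(scale_ratio = r, orientation_diff = a, class = cls)
}

# local maxima of a smooth nonnegative field above a relative threshold
find_peaks <- function(field, rel_thresh = 0.2, halfwin = 2) {
  n1 <- nrow(field); n2 <- ncol(field)
  if (max(field) <= 0)
    return(matrix(numeric(0), 0, 2, dimnames = list(NULL, c("x", "y"))))
  thr <- rel_thresh * max(field)
  out <- NULL
  for (i in (1 + halfwin):(n1 - halfwin)) {
    for (j in (1 + halfwin):(n2 - halfwin)) {
      v <- field[i, j]
      if (v < thr) next
      w <- field[(i - halfwin):(i + halfwin), (j - halfwin):(j + halfwin)]
      if (v >= max(w)) out <- rbind(out, c(i, j))
    }
  }
  if (is.null(out)) out <- matrix(numeric(0), 0, 2)
  colnames(out) <- c("x", "y")
  out
}

#' Peak registry between two population patterns
#'
#' Extracts activity peaks from two same-sized population snapshots and
#' measures their registry: the fraction of peaks of the finer (smaller
#' scale, denser) pattern that lie within a capture radius of a peak of the
#' coarser pattern, and vice versa. Commensurate overlays score 1 for the
#' coarse pattern's peaks; incommensurate overlays score near the areal
#' coverage of the capture disks.
#'
#' @param snapshot_a,snapshot_b `n x n` rate fields.
#' @param capture Capture radius in neurons; defaults to 30% of the finer
#'   pattern's grid scale.
#' @param rel_thresh Peak detection threshold relative to the field maximum.
#' @return A one-row tibble: `n_peaks_fine`, `n_peaks_coarse`,
#'   `registry_fine` (fraction of fine peaks captured), `registry_coarse`,
#'   `capture_radius`. The classification tie-break uses `registry_coarse`.
#' @export
overlay_registry <- function(snapshot_a, snapshot_b, capture = NULL,
                             rel_thresh = 0.2) {
  stopifnot(all(dim(snapshot_a) == dim(snapshot_b)))
  pa <- find_peaks(snapshot_a, rel_thresh)
  pb <- find_peaks(snapshot_b, rel_thresh)
  if (nrow(pa) == 0 || nrow(pb) == 0)
    stop("no activity peaks found", call. = FALSE)
  # finer pattern = more peaks
  if (nrow(pa) >= nrow(pb)) { fine <- pa; coarse <- pb } else { fine <- pb; coarse <- pa }
  if (is.null(capture)) {
    d <- as.matrix(stats::dist(fine))
    diag(d) <- Inf
    capture <- 0.3 * stats::median(apply(d, 1, min))
  }
  mind <- function(from, to) {
    apply(from, 1, function(p)
      min(sqrt((to[, 1] - p[1])^2 + (to[, 2] - p[2])^2)))
  }
  tibble::tibble(
    n_peaks_fine = nrow(fine), n_peaks_coarse = nrow(coarse),
    registry_fine = mean(mind(fine, coarse) <= capture),
    registry_coarse = mean(mind(coarse, fine) <= capture),
    capture_radius = capture)
}
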