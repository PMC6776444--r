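#' Persist a run set to a directory
#'
#' Writes a run directory containing the configuration (`config.yaml`, one
#' key per [grid_params()] field, plus protocol metadata and the replicate
#' seeds), the analysis tables as delimited text (`network_props.tsv`,
#' `cell_props.tsv`, `pairs.tsv`) and, when snapshots were kept, the rate
#' fields as an RDS array container (`snapshots.rds`).
#'
#' @param run_set A `grid_run_set`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_run <- function(run_set, dir) {
  stopifnot(inherits(run_set, "grid_run_set"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cfg <- unclass(run_set$params)
  cfg <- cfg[!vapply(cfg, is.null, logical(1))]
  meta <- list(protocol = run_set$protocol, analysis = run_set$analysis,
               seeds = run_set$seeds, flags = unclass(run_set$flags))
  yaml::write_yaml(list(params = cfg, meta = meta),
                   file.path(dir, "config.yaml"))
  readr::write_tsv(run_set$network_props, file.path(dir, "network_props.tsv"))
  if (nrow(run_set$cell_props))
    readr::write_tsv(run_set$cell_props, file.path(dir, "cell_props.tsv"))
  if (nrow(run_set$pairs))
    readr::write_tsv(run_set$pairs, file.path(dir, "pairs.tsv"))
  if (!is.null(run_set$snapshots))
    saveRDS(run_set$snapshots, file.path(dir, "snapshots.rds"))
  invisible(dir)
}

#' Read a persisted run directory
#'
#' @param dir Directory written by [write_run()].
#' @return A `grid_run_set` (without partition objects; the tables are
#'   restored losslessly).
#' @export
read_run <- function(dir) {
  cfg <- yaml::read_yaml(file.path(dir, "config.yaml"))
  params <- do.call(grid_params, cfg$params)
  flags <- do.call(sim_flags, cfg$meta$flags)
  rd <- function(f, empty) {
    path <- file.path(dir, f)
    if (file.exists(path))
      readr::read_tsv(path, show_col_types = FALSE)
    else empty
  }
  snaps <- NULL
  if (file.exists(file.path(dir, "snapshots.rds")))
    snaps <- readRDS(file.path(dir, "snapshots.rds"))
  structure(list(protocol = cfg$meta$protocol, params = params,
                 flags = flags, seeds = unlist(cfg$meta$seeds),
                 analysis = cfg$meta$analysis,
                 network_props = rd("network_props.tsv", tibble::tibble()),
                 cell_props = rd("cell_props.tsv", tibble::tibble()),
                 partitions = NULL,
                 pairs = rd("pairs.tsv", tibble::tibble()),
                 snapshots = snaps),
            class = "grid_run_set")
}
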