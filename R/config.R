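#' Run configuration
#'
#' Collects the tunable parameters of the pipeline with the defaults used
#' throughout: 1000 randomization rounds for colocalization nulls, clipping of
#' the top and bottom 0.1% of intensities during normalization, cross-
#' correlation shifts of +/- 10 pixels, and terminals required to span at
#' least 2 z-planes.
#'
#' @param seed Integer RNG seed recorded with every report.
#' @param n_randomizations Rounds of puncta randomization for the null
#'   (default 1000).
#' @param clip_fraction Fraction clipped at each intensity extreme during
#'   normalization (default 0.001, i.e. 0.1%).
#' @param max_shift Maximum in-plane shift, in pixels, for cross-correlation
#'   maps (default 10).
#' @param min_z_planes Minimum number of z-planes a terminal must span
#'   (default 2).
#' @param terminal_size_bounds Length-2 integer vector, allowed terminal size
#'   in voxels.
#' @param n_shells Number of single-voxel concentric shells for profiles.
#' @param thresholds Named list of per-stage threshold overrides.
#' @return A list of class `run_config`.
#' @export
run_config <- function(seed = 1L,
                       n_randomizations = 1000L,
                       clip_fraction = 0.001,
                       max_shift = 10L,
                       min_z_planes = 2L,
                       terminal_size_bounds = c(4L, 10000L),
                       n_shells = 10L,
                       thresholds = list()) {
  stopifnot(
    n_randomizations >= 1,
    clip_fraction >= 0, clip_fraction < 0.5,
    max_shift >= 0,
    min_z_planes >= 1,
    length(terminal_size_bounds) == 2,
    terminal_size_bounds[1] <= terminal_size_bounds[2],
    n_shells >= 1
  )
  structure(
    list(
      seed = as.integer(seed),
      n_randomizations = as.integer(n_randomizations),
      clip_fraction = clip_fraction,
      max_shift = as.integer(max_shift),
      min_z_planes = as.integer(min_z_planes),
      terminal_size_bounds = as.integer(terminal_size_bounds),
      n_shells = as.integer(n_shells),
      thresholds = thresholds
    ),
    class = "run_config"
  )
}

#' Read a run configuration from YAML
#'
#' @param path Path to a YAML file whose keys match the arguments of
#'   [run_config()].
#' @return A `run_config`.
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(run_config, vals[intersect(names(vals), names(formals(run_config)))])
}

#' Stable hash of a configuration
#'
#' @param config A `run_config` (or any R object).
#' @return A short hash string recorded in report manifests.
#' @export
config_hash <- function(config) {
  rlang::hash(config)
}

#' Write result tables with a manifest
#'
#' Writes one CSV per table and a JSON manifest recording, for each table,
#' the stage name, seed and configuration hash, so any report row can be
#' traced to the exact run that produced it. Numeric fields are formatted at
#' fixed precision, so re-running with the same seed and configuration
#' reproduces byte-identical files.
#'
#' @param tables Named list of data frames (name = stage name).
#' @param path Output directory, created if needed.
#' @param config The `run_config` of the run.
#' @param digits Significant digits used when formatting numeric columns.
#' @return Invisibly, the manifest list.
#' @export
write_report <- function(tables, path, config = run_config(), digits = 10) {
  stopifnot(is.list(tables))
  if (length(tables) > 0 && is.null(names(tables))) {
    stop("tables must be named by stage", call. = FALSE)
  }
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(path)) stop("cannot create output directory: ", path, call. = FALSE)
  hash <- config_hash(config)
  manifest <- list(
    seed = config$seed,
    config_hash = hash,
    tables = lapply(names(tables), function(nm) {
      tab <- as.data.frame(tables[[nm]])
      num <- vapply(tab, is.numeric, logical(1))
      tab[num] <- lapply(tab[num], function(col) signif(col, digits))
      fn <- file.path(path, paste0(nm, ".csv"))
      utils::write.csv(
        cbind(tab, stage = nm, seed = config$seed, config_hash = hash),
        fn,
        row.names = FALSE
      )
      list(stage = nm, file = basename(fn), rows = nrow(tab))
    })
  )
  jsonlite::write_json(
    manifest, file.path(path, "manifest.json"),
    auto_unbox = TRUE, pretty = TRUE
  )
  invisible(manifest)
}
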