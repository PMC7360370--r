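#' Detect putative presynaptic terminals
#'
#' Thresholds the terminal-reporter channel (Synaptophysin-YFP/mCherry),
#' removes voxels inside nuclei, labels 26-connected 3D components, and keeps
#' components that fall within the size bounds and span at least
#' `min_z_planes` z-planes. `threshold = "auto"` uses Otsu's method on the
#' reporter intensities restricted to the tissue mask.
#'
#' @param reporter_channel Normalized 3D array.
#' @param nuclear_mask Optional logical array; voxels inside are excluded.
#' @param threshold Numeric intensity threshold, or `"auto"`.
#' @param size_bounds Length-2 vector, allowed voxel counts (inclusive).
#' @param min_z_planes Minimum distinct z-planes per terminal.
#' @param tissue_mask Optional logical array restricting the auto threshold
#'   sample (and detection) to tissue.
#' @return A `terminal_set`: list with `labels` (integer 3D array, dense ids
#'   from 1 in scan order) and `terminals` (tibble with `id`, `n_voxels`,
#'   `z_extent`, centroid `z`/`y`/`x`, bounding box, and the threshold used).
#' @export
detect_terminals <- function(reporter_channel,
                             nuclear_mask = NULL,
                             threshold = "auto",
                             size_bounds = c(4L, 10000L),
                             min_z_planes = 2L,
                             tissue_mask = NULL) {
  stopifnot(is.array(reporter_channel), length(dim(reporter_channel)) == 3)
  d <- dim(reporter_channel)
  if (identical(threshold, "auto")) {
    sample_vals <- if (is.null(tissue_mask)) {
      as.numeric(reporter_channel)
    } else {
      reporter_channel[tissue_mask != 0]
    }
    if (length(unique(sample_vals)) < 2) {
      stop("auto threshold failed: constant reporter channel", call. = FALSE)
    }
    threshold <- otsu_threshold(sample_vals)
  }
  fg <- reporter_channel >= threshold
  if (!is.null(tissue_mask)) fg <- fg & (tissue_mask != 0)
  if (!is.null(nuclear_mask)) fg <- fg & !(nuclear_mask != 0)
  lab <- label_components(fg)
  n0 <- max(lab)
  if (n0 == 0) {
    return(new_terminal_set(lab, empty_terminal_table(), threshold))
  }
  idx <- which(lab > 0)
  ids <- lab[idx]
  co <- arrayInd(idx, d)
  stats_tab <- tibble::tibble(id = ids, z = co[, 1], y = co[, 2], x = co[, 3]) |>
    dplyr::group_by(.data$id) |>
    dplyr::summarise(
      n_voxels = dplyr::n(),
      z_extent = dplyr::n_distinct(.data$z),
      zc = mean(.data$z), yc = mean(.data$y), xc = mean(.data$x),
      z0 = min(.data$z), z1 = max(.data$z),
      y0 = min(.data$y), y1 = max(.data$y),
      x0 = min(.data$x), x1 = max(.data$x),
      .groups = "drop"
    )
  keep <- stats_tab$n_voxels >= size_bounds[1] &
    stats_tab$n_voxels <= size_bounds[2] &
    stats_tab$z_extent >= min_z_planes
  kept <- stats_tab[keep, , drop = FALSE]
  relab <- integer(n0)
  relab[kept$id] <- seq_len(nrow(kept))
  out_lab <- array(0L, dim = d)
  out_lab[idx] <- relab[ids]
  terminals <- tibble::tibble(
    id = seq_len(nrow(kept)),
    n_voxels = kept$n_voxels,
    z_extent = kept$z_extent,
    z = kept$zc, y = kept$yc, x = kept$xc,
    z_min = kept$z0, z_max = kept$z1,
    y_min = kept$y0, y_max = kept$y1,
    x_min = kept$x0, x_max = kept$x1
  )
  new_terminal_set(out_lab, terminals, threshold)
}

new_terminal_set <- function(labels, terminals, threshold = NA_real_) {
  structure(
    list(labels = labels, terminals = terminals, threshold = threshold),
    class = "terminal_set"
  )
}

empty_terminal_table <- function() {
  tibble::tibble(
    id = integer(), n_voxels = integer(), z_extent = integer(),
    z = double(), y = double(), x = double(),
    z_min = integer(), z_max = integer(),
    y_min = integer(), y_max = integer(),
    x_min = integer(), x_max = integer()
  )
}

#' @export
print.terminal_set <- function(x, ...) {
  cat(
    "<terminal_set> ", nrow(x$terminals), " terminal(s), ",
    sum(x$terminals$n_voxels), " voxels, threshold ",
    format(x$threshold, digits = 4), "\n",
    sep = ""
  )
  invisible(x)
}

#' Tidy a terminal set
#'
#' @param x A `terminal_set`.
#' @param ... Unused.
#' @return The per-terminal tibble.
#' @method tidy terminal_set
#' @export
tidy.terminal_set <- function(x, ...) x$terminals

#' Measure per-terminal mean channel intensities
#'
#' Computes the arithmetic mean of each named channel over each terminal's
#' voxels and appends `mean_<channel>` columns to the terminal table.
#'
#' @param terminal_set A `terminal_set`.
#' @param stack A [volume_stack()] congruent with the label grid.
#' @param channels Channel names to measure (default: all).
#' @return The `terminal_set`, with measurement columns added.
#' @export
measure_terminals <- function(terminal_set, stack, channels = NULL) {
  stopifnot(inherits(terminal_set, "terminal_set"), inherits(stack, "volume_stack"))
  if (!identical(dim(terminal_set$labels), dim(stack))) {
    stop("label grid and stack dimensions differ", call. = FALSE)
  }
  if (is.null(channels)) channels <- names(stack$channels)
  lab <- terminal_set$labels
  idx <- which(lab > 0)
  ids <- lab[idx]
  n <- nrow(terminal_set$terminals)
  for (ch in channels) {
    col <- paste0("mean_", ch)
    if (n == 0 || length(idx) == 0) {
      terminal_set$terminals[[col]] <- double(n)
      next
    }
    vals <- stack$channels[[ch]][idx]
    sums <- rowsum(vals, ids)
    counts <- rowsum(rep(1, length(ids)), ids)
    means <- rep(NA_real_, n)
    means[as.integer(rownames(sums))] <- sums[, 1] / counts[, 1]
    terminal_set$terminals[[col]] <- means
  }
  terminal_set
}

#' Binary mask of all terminal voxels
#'
#' @param terminal_set A `terminal_set`.
#' @return Logical 3D array, the union of all terminal voxels.
#' @export
mask_from_terminals <- function(terminal_set) {
  stopifnot(inherits(terminal_set, "terminal_set"))
  terminal_set$labels > 0L
}
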