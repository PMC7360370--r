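# FISH scoring: Renyi-entropy binarization, cell segmentation, per-cell
# percent coverage per probe, background-ROI positivity thresholds, and
# co-expression tables. FISH images are 2D; a z = 1 stack is accepted.

as_plane <- function(x) {
  if (is.array(x) && length(dim(x)) == 3) {
    stopifnot(dim(x)[1] == 1)
    return(x[1, , ])
  }
  stopifnot(is.matrix(x))
  x
}

#' Build a cellular mask from combined probe channels
#'
#' Sums the probe channels, binarizes the sum with the Renyi-entropy
#' threshold, closes the binary image with a 1-pixel ball (bridging the gaps
#' between transcript dots within a cell), fills holes, and removes
#' components below the minimum cell area. Touching cells merge into one
#' component (no watershed splitting).
#'
#' @param probe_channels List of 2D matrices (or z = 1 arrays), or a
#'   [volume_stack()] whose `fish_probe` channels are used.
#' @param min_area Minimum component area in pixels.
#' @return List with `mask` (logical matrix), `labels` (integer matrix) and
#'   `threshold`.
#' @export
build_cell_mask <- function(probe_channels, min_area = 50L) {
  if (inherits(probe_channels, "volume_stack")) {
    nms <- channels_with_role(probe_channels, "fish_probe")
    probe_channels <- lapply(nms, function(ch) get_channel(probe_channels, ch))
  }
  stopifnot(length(probe_channels) >= 1)
  planes <- lapply(probe_channels, as_plane)
  total <- Reduce(`+`, planes)
  if (max(total) - min(total) <= 0) {
    empty <- matrix(FALSE, nrow(total), ncol(total))
    return(list(mask = empty, labels = matrix(0L, nrow(total), ncol(total)),
      threshold = NA_real_))
  }
  thr <- renyi_entropy_threshold(as.numeric(total))
  mask <- total > thr
  m3 <- close_ball(array(mask, dim = c(1, nrow(mask), ncol(mask))))
  mask <- fill_holes(m3[1, , ])
  lab <- label_components(mask)
  if (max(lab) > 0) {
    sizes <- tabulate(lab[lab > 0])
    keep <- which(sizes >= min_area)
    mask <- matrix(lab %in% keep, nrow(mask), ncol(mask))
    lab <- label_components(mask)
  }
  list(mask = mask, labels = lab, threshold = thr)
}

#' Per-cell percent coverage of a probe
#'
#' Binarizes the probe channel at its threshold and reports, per cell,
#' `100 * (probe-positive pixels in the cell) / (cell pixels)`.
#'
#' @param cell_labels Integer matrix of cell labels (0 = background).
#' @param probe_channel 2D matrix (or z = 1 array).
#' @param probe_threshold Binarization threshold (`> threshold` is positive);
#'   default is the probe's own Renyi-entropy threshold.
#' @return Tibble `id`, `n_pixels`, `coverage` (percent, in `[0, 100]`).
#' @export
cell_coverage <- function(cell_labels, probe_channel, probe_threshold = NULL) {
  cell_labels <- as_plane(cell_labels)
  probe <- as_plane(probe_channel)
  stopifnot(identical(dim(cell_labels), dim(probe)))
  if (is.null(probe_threshold)) {
    probe_threshold <- renyi_entropy_threshold(as.numeric(probe))
  }
  pos <- probe > probe_threshold
  idx <- which(cell_labels > 0)
  n_cells <- max(cell_labels)
  if (n_cells == 0) {
    return(tibble::tibble(id = integer(), n_pixels = integer(), coverage = double()))
  }
  ids <- cell_labels[idx]
  npix <- rowsum(rep(1L, length(ids)), ids)
  npos <- rowsum(as.integer(pos[idx]), ids)
  tibble::tibble(
    id = as.integer(rownames(npix)),
    n_pixels = as.integer(unname(npix[, 1])),
    coverage = unname(100 * npos[, 1] / npix[, 1])
  )
}

#' Coverage of background regions of interest
#'
#' @param rois Tibble/data frame of rectangles with columns `y0`, `y1`, `x0`,
#'   `x1` (inclusive pixel bounds).
#' @param probe_channel 2D matrix.
#' @param probe_threshold Binarization threshold (default: probe's Renyi).
#' @return Numeric vector of percent coverages, one per ROI.
#' @export
background_coverage <- function(rois, probe_channel, probe_threshold = NULL) {
  probe <- as_plane(probe_channel)
  if (is.null(probe_threshold)) {
    probe_threshold <- renyi_entropy_threshold(as.numeric(probe))
  }
  pos <- probe > probe_threshold
  vapply(seq_len(nrow(rois)), function(i) {
    r <- rois[i, ]
    100 * mean(pos[r$y0:r$y1, r$x0:r$x1])
  }, numeric(1))
}

#' Positivity threshold from background coverages
#'
#' The threshold above the drawn background areas: their maximum percent
#' coverage. A cell is called positive when its coverage is strictly greater.
#'
#' @param background_coverages Numeric vector (typically ten values).
#' @param method `"max"` (default) or `"mean_2sd"` (mean + 2 sd).
#' @return The coverage threshold (percent).
#' @export
positivity_threshold <- function(background_coverages, method = c("max", "mean_2sd")) {
  stopifnot(length(background_coverages) >= 1)
  method <- match.arg(method)
  if (method == "max") {
    max(background_coverages)
  } else {
    mean(background_coverages) + 2 * stats::sd(background_coverages)
  }
}

#' Score a FISH image stack
#'
#' Full per-cell pipeline: build the cellular mask from the combined probe
#' channels, compute per-cell percent coverage of each probe (binarized at
#' its own Renyi-entropy threshold), derive each probe's positivity threshold
#' from the background ROIs, and call each cell positive or negative per
#' probe.
#'
#' @param stack A [volume_stack()] with `fish_probe` channels (z = 1).
#' @param background_rois Rectangles (`y0`,`y1`,`x0`,`x1`) in cell-free
#'   areas.
#' @param min_area Minimum cell area in pixels.
#' @return A `cell_table` tibble: per cell `id`, `n_pixels`, and per probe
#'   `coverage_<probe>` and `pos_<probe>`; probe thresholds are attributes.
#' @export
score_fish <- function(stack, background_rois, min_area = 50L) {
  stopifnot(inherits(stack, "volume_stack"))
  probes <- channels_with_role(stack, "fish_probe")
  stopifnot(length(probes) >= 1)
  cm <- build_cell_mask(stack, min_area = min_area)
  out <- NULL
  probe_thresholds <- numeric(0)
  coverage_thresholds <- numeric(0)
  for (p in probes) {
    img <- as_plane(get_channel(stack, p))
    thr <- renyi_entropy_threshold(as.numeric(img))
    cov <- cell_coverage(cm$labels, img, thr)
    bg <- background_coverage(background_rois, img, thr)
    cut <- positivity_threshold(bg)
    probe_thresholds[p] <- thr
    coverage_thresholds[p] <- cut
    cov_col <- stats::setNames(cov["coverage"], paste0("coverage_", p))
    pos_col <- stats::setNames(
      tibble::tibble(pos = cov$coverage > cut), paste0("pos_", p)
    )
    block <- dplyr::bind_cols(cov[c("id", "n_pixels")], cov_col, pos_col)
    out <- if (is.null(out)) block else dplyr::left_join(
      out, block,
      by = c("id", "n_pixels")
    )
  }
  attr(out, "probe_thresholds") <- probe_thresholds
  attr(out, "coverage_thresholds") <- coverage_thresholds
  attr(out, "cell_labels") <- cm$labels
  class(out) <- c("cell_table", class(out))
  out
}

#' Co-expression counts and proportions
#'
#' Counts each joint positivity pattern across the named probes and reports,
#' for each ordered probe pair, the proportion of cells positive for one
#' probe that are also positive for the other, rounded to integer percent
#' (the convention of published per-cell co-expression counts).
#'
#' @param cell_table A [score_fish()] result, or any tibble with logical
#'   `pos_<probe>` columns.
#' @param probes Probe names (default: every `pos_` column).
#' @return List with `patterns` (tibble of joint-pattern counts) and `pairs`
#'   (tibble: `denominator`, `numerator` probe, `n_denom`, `n_co`,
#'   `percent`).
#' @export
coexpression_table <- function(cell_table, probes = NULL) {
  if (is.null(probes)) {
    probes <- sub("^pos_", "", grep("^pos_", names(cell_table), value = TRUE))
  }
  cols <- paste0("pos_", probes)
  stopifnot(all(cols %in% names(cell_table)))
  if (nrow(cell_table) == 0) {
    return(list(
      patterns = tibble::tibble(pattern = character(), n = integer()),
      pairs = tibble::tibble(
        denominator = character(), numerator = character(),
        n_denom = integer(), n_co = integer(), percent = double()
      )
    ))
  }
  calls <- as.data.frame(cell_table[cols])
  pattern <- apply(calls, 1, function(r) {
    paste0(ifelse(r, paste0(probes, "+"), paste0(probes, "-")), collapse = "")
  })
  patterns <- tibble::as_tibble(as.data.frame(table(pattern), stringsAsFactors = FALSE))
  names(patterns) <- c("pattern", "n")
  grid <- expand.grid(i = seq_along(probes), j = seq_along(probes))
  grid <- grid[grid$i != grid$j, , drop = FALSE]
  pairs <- purrr::pmap_dfr(grid, function(i, j) {
    denom <- calls[[i]]
    co <- calls[[i]] & calls[[j]]
    tibble::tibble(
      denominator = probes[i],
      numerator = probes[j],
      n_denom = sum(denom),
      n_co = sum(co),
      percent = if (sum(denom) > 0) round(100 * sum(co) / sum(denom)) else NA_real_
    )
  })
  list(patterns = patterns, pairs = pairs)
}
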