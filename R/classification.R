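#' Classify terminals by vesicular-transporter positivity
#'
#' Calls each terminal positive for a channel when its mean intensity is
#' greater than or equal to that channel's threshold (typically the Otsu
#' threshold of the per-voxel intensities), and assigns the quadrant class:
#' `both`, `VGAT_only`, `VAChT_only`, or `neither`.
#'
#' @param terminals Tibble with per-terminal mean intensity columns (as
#'   produced by [measure_terminals()]), or a `terminal_set`.
#' @param vgat_col,vacht_col Names of the VGAT-like and VAChT-like mean
#'   intensity columns.
#' @param vgat_threshold,vacht_threshold Intensity thresholds.
#' @return A `terminal_class_table` tibble: input columns plus `vgat_pos`,
#'   `vacht_pos`, `class`, with the thresholds stored as attributes.
#' @export
classify_terminals <- function(terminals,
                               vgat_threshold, vacht_threshold,
                               vgat_col = "mean_VGAT",
                               vacht_col = "mean_VAChT") {
  if (inherits(terminals, "terminal_set")) terminals <- terminals$terminals
  stopifnot(all(c(vgat_col, vacht_col) %in% names(terminals)))
  out <- terminals
  out$vgat_pos <- out[[vgat_col]] >= vgat_threshold
  out$vacht_pos <- out[[vacht_col]] >= vacht_threshold
  out$class <- dplyr::case_when(
    out$vgat_pos & out$vacht_pos ~ "both",
    out$vgat_pos & !out$vacht_pos ~ "VGAT_only",
    !out$vgat_pos & out$vacht_pos ~ "VAChT_only",
    TRUE ~ "neither"
  )
  attr(out, "vgat_threshold") <- vgat_threshold
  attr(out, "vacht_threshold") <- vacht_threshold
  class(out) <- c("terminal_class_table", class(out))
  out
}

#' Quadrant counts of a classification
#'
#' @param class_table A [classify_terminals()] result.
#' @return Tibble of counts and proportions per class; counts sum to the
#'   terminal count.
#' @export
quadrant_counts <- function(class_table) {
  lv <- c("both", "VGAT_only", "VAChT_only", "neither")
  total <- nrow(class_table)
  tab <- as.integer(table(factor(class_table$class, levels = lv)))
  tibble::tibble(
    class = lv,
    n = tab,
    proportion = if (total > 0) tab / total else rep(NA_real_, 4)
  )
}

#' Rotated-mask negative control
#'
#' Rotates the terminal label grid 90 degrees in-plane (about the center of
#' the largest centered square) and re-measures per-terminal mean intensities
#' against the unrotated antibody channel. Because rotated labels land on
#' unrelated positions, the control distribution estimates the chance level
#' of per-terminal mean intensity.
#'
#' @param terminal_set A `terminal_set`.
#' @param antibody_channel 3D array, not rotated.
#' @param turns Number of 90-degree turns (default 1; 4 restores identity).
#' @return Tibble `id`, `control_mean` for terminals whose rotated voxels
#'   remain in the image.
#' @export
rotation_control <- function(terminal_set, antibody_channel, turns = 1L) {
  stopifnot(inherits(terminal_set, "terminal_set"))
  lab <- terminal_set$labels
  d <- dim(lab)
  stopifnot(identical(d, dim(antibody_channel)))
  s <- min(d[2], d[3])
  y_off <- (d[2] - s) %/% 2
  x_off <- (d[3] - s) %/% 2
  ys <- y_off + seq_len(s)
  xs <- x_off + seq_len(s)
  rot <- lab
  rot[] <- 0L
  sq <- lab[, ys, xs, drop = FALSE]
  turns <- ((turns %% 4) + 4) %% 4
  for (k in seq_len(turns)) {
    # 90 deg clockwise in (row, col): new[r, c] = old[s - c + 1, r]
    sq <- aperm(sq, c(1, 3, 2))[, , s:1, drop = FALSE]
  }
  rot[, ys, xs] <- sq
  idx <- which(rot > 0)
  n <- nrow(terminal_set$terminals)
  if (length(idx) == 0 || n == 0) {
    return(tibble::tibble(id = integer(), control_mean = double()))
  }
  ids <- rot[idx]
  sums <- rowsum(antibody_channel[idx], ids)
  counts <- rowsum(rep(1, length(ids)), ids)
  tibble::tibble(
    id = as.integer(rownames(sums)),
    control_mean = unname(sums[, 1] / counts[, 1])
  )
}

#' Squared Pearson correlation of transporter intensities
#'
#' R-squared of per-terminal (VGAT-like, VAChT-like) mean intensities,
#' overall and within each quadrant class (where at least 3 terminals and
#' nonzero variance permit it).
#'
#' @param class_table A [classify_terminals()] result (or any tibble with the
#'   two mean columns and optionally `class`).
#' @param vgat_col,vacht_col Intensity column names.
#' @return Tibble with `scope` (`"overall"` or a class), `n`, `r_squared`.
#' @export
intensity_correlation <- function(class_table,
                                  vgat_col = "mean_VGAT",
                                  vacht_col = "mean_VAChT") {
  r2 <- function(x, y) {
    if (length(x) < 3 || stats::sd(x) == 0 || stats::sd(y) == 0) {
      return(NA_real_)
    }
    stats::cor(x, y)^2
  }
  out <- tibble::tibble(
    scope = "overall",
    n = nrow(class_table),
    r_squared = r2(class_table[[vgat_col]], class_table[[vacht_col]])
  )
  if ("class" %in% names(class_table)) {
    per <- class_table |>
      dplyr::group_by(scope = .data$class) |>
      dplyr::summarise(
        n = dplyr::n(),
        r_squared = r2(.data[[vgat_col]], .data[[vacht_col]]),
        .groups = "drop"
      )
    out <- dplyr::bind_rows(out, per)
  }
  out
}

#' Threshold-sweep conditional positivity curve
#'
#' For each grid threshold `t` on channel A, the fraction of terminals with
#' A-mean `>= t` that are positive for channel B (B's call fixed at its own
#' threshold). Grid points whose conditioning set is empty are flagged.
#'
#' @param class_table A [classify_terminals()] result.
#' @param a_col Mean-intensity column swept (conditioning channel).
#' @param b_pos_col Logical call column for the other channel.
#' @param grid Numeric thresholds; default 25 points over the observed range
#'   of `a_col`.
#' @return A `sweep_curve` tibble: `threshold`, `n_conditioned`,
#'   `prop_b_positive`, `empty`.
#' @export
threshold_sweep <- function(class_table, a_col, b_pos_col, grid = NULL) {
  stopifnot(all(c(a_col, b_pos_col) %in% names(class_table)))
  a <- class_table[[a_col]]
  b <- class_table[[b_pos_col]]
  if (is.null(grid)) {
    grid <- seq(min(a), max(a), length.out = 25)
  }
  out <- purrr::map_dfr(grid, function(t) {
    sel <- a >= t
    n <- sum(sel)
    tibble::tibble(
      threshold = t,
      n_conditioned = n,
      prop_b_positive = if (n > 0) mean(b[sel]) else NA_real_,
      empty = n == 0
    )
  })
  structure(out, class = c("sweep_curve", class(out)))
}

#' End-to-end terminal classification pipeline
#'
#' Detects terminals in the reporter channel, measures per-terminal VGAT-like
#' and VAChT-like mean intensities, derives per-channel Otsu thresholds from
#' the per-voxel intensities within the tissue mask (or the whole image), and
#' classifies every terminal.
#'
#' @param stack A [volume_stack()] with a terminal-reporter channel and the
#'   two transporter antibody channels.
#' @param reporter,vgat,vacht Channel names; defaults are taken from roles
#'   (`terminal_reporter` and the first two `antibody` channels).
#' @param size_bounds,min_z_planes Passed to [detect_terminals()].
#' @param tissue_mask Optional logical array for threshold sampling.
#' @param threshold_on `"voxels"` (Otsu on per-voxel intensities, default) or
#'   `"terminal_means"` (Otsu on the per-terminal means).
#' @return A list with `terminal_set`, `class_table`, `quadrants`,
#'   `thresholds`.
#' @export
classify_pipeline <- function(stack,
                              reporter = NULL, vgat = NULL, vacht = NULL,
                              size_bounds = c(4L, 10000L),
                              min_z_planes = 2L,
                              tissue_mask = NULL,
                              threshold_on = c("voxels", "terminal_means")) {
  threshold_on <- match.arg(threshold_on)
  if (is.null(reporter)) reporter <- channels_with_role(stack, "terminal_reporter")[1]
  ab <- channels_with_role(stack, "antibody")
  if (is.null(vgat)) vgat <- ab[1]
  if (is.null(vacht)) vacht <- ab[2]
  tset <- detect_terminals(
    get_channel(stack, reporter),
    threshold = "auto",
    size_bounds = size_bounds,
    min_z_planes = min_z_planes,
    tissue_mask = tissue_mask
  )
  tset <- measure_terminals(tset, stack, channels = c(vgat, vacht))
  thr_sample <- function(ch) {
    if (threshold_on == "terminal_means") {
      return(tset$terminals[[paste0("mean_", ch)]])
    }
    img <- get_channel(stack, ch)
    if (is.null(tissue_mask)) as.numeric(img) else img[tissue_mask != 0]
  }
  thr_vgat <- otsu_threshold(thr_sample(vgat))
  thr_vacht <- otsu_threshold(thr_sample(vacht))
  ct <- classify_terminals(
    tset,
    vgat_threshold = thr_vgat, vacht_threshold = thr_vacht,
    vgat_col = paste0("mean_", vgat), vacht_col = paste0("mean_", vacht)
  )
  list(
    terminal_set = tset,
    class_table = ct,
    quadrants = quadrant_counts(ct),
    thresholds = c(vgat = thr_vgat, vacht = thr_vacht)
  )
}
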