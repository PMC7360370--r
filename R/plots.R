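# ggplot2 views of the main result types.

#' Plot per-channel enrichment z-scores
#'
#' Points per channel with the +/- 5 z-score reference band drawn as dashed
#' lines.
#'
#' @param object A `coloc_result`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot coloc_result
#' @export
autoplot.coloc_result <- function(object, ...) {
  ggplot2::ggplot(
    object$summary,
    ggplot2::aes(x = .data$channel, y = .data$z_score)
  ) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey60") +
    ggplot2::geom_hline(
      yintercept = c(-5, 5), linetype = "dashed", colour = "grey40"
    ) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(
      x = NULL, y = "Enrichment z-score",
      title = "Puncta enrichment within terminal mask"
    ) +
    ggplot2::theme_minimal()
}

#' Plot a shell density profile
#'
#' Observed puncta density per concentric shell (shell 0 = the terminal
#' mask) with the randomized-null mean overlaid.
#'
#' @param shells The `shells` tibble of a `coloc_result` (or compatible).
#' @return A ggplot.
#' @export
plot_shell_profile <- function(shells) {
  ggplot2::ggplot(shells, ggplot2::aes(x = .data$shell)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$density, colour = "observed")) +
    ggplot2::geom_point(ggplot2::aes(y = .data$density, colour = "observed")) +
    ggplot2::geom_line(
      ggplot2::aes(y = .data$null_mean, colour = "null mean"),
      linetype = "dashed"
    ) +
    ggplot2::facet_wrap(ggplot2::vars(.data$channel), scales = "free_y") +
    ggplot2::labs(
      x = "Shell (voxels from mask)", y = "Puncta density (per voxel)",
      colour = NULL
    ) +
    ggplot2::theme_minimal()
}

#' Plot a shift cross-covariance map
#'
#' @param object A [shift_covariance()] result.
#' @param ... Unused.
#' @return A ggplot tile map.
#' @method autoplot shift_covariance
#' @export
autoplot.shift_covariance <- function(object, ...) {
  ggplot2::ggplot(
    object,
    ggplot2::aes(x = .data$dc, y = .data$dr, fill = .data$covariance)
  ) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "Column shift (px)", y = "Row shift (px)") +
    ggplot2::theme_minimal()
}

#' Scatter plot of a terminal classification
#'
#' Per-terminal VGAT-like versus VAChT-like mean intensity, coloured by
#' quadrant class, with the thresholds drawn.
#'
#' @param object A [classify_terminals()] result.
#' @param vgat_col,vacht_col Intensity column names.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot terminal_class_table
#' @export
autoplot.terminal_class_table <- function(object,
                                          vgat_col = "mean_VGAT",
                                          vacht_col = "mean_VAChT", ...) {
  cols <- c(
    both = "magenta3", VGAT_only = "gold3",
    VAChT_only = "cyan3", neither = "grey30"
  )
  ggplot2::ggplot(
    object,
    ggplot2::aes(
      x = .data[[vgat_col]], y = .data[[vacht_col]], colour = .data$class
    )
  ) +
    ggplot2::geom_point(alpha = 0.6, size = 1) +
    ggplot2::geom_vline(
      xintercept = attr(object, "vgat_threshold"), linetype = "dashed"
    ) +
    ggplot2::geom_hline(
      yintercept = attr(object, "vacht_threshold"), linetype = "dashed"
    ) +
    ggplot2::scale_colour_manual(values = cols) +
    ggplot2::labs(
      x = "Mean VGAT-like intensity", y = "Mean VAChT-like intensity",
      colour = "Class"
    ) +
    ggplot2::theme_minimal()
}

#' Plot a threshold-sweep curve
#'
#' @param object A [threshold_sweep()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot sweep_curve
#' @export
autoplot.sweep_curve <- function(object, ...) {
  ggplot2::ggplot(
    object[!object$empty, ],
    ggplot2::aes(x = .data$threshold, y = .data$prop_b_positive)
  ) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(
      x = "Conditioning threshold", y = "Proportion positive for other channel"
    ) +
    ggplot2::theme_minimal()
}

#' Bar plot of survey response proportions per group
#'
#' @param summary A [survey_summary()] result.
#' @return A ggplot.
#' @export
plot_survey_summary <- function(summary) {
  ggplot2::ggplot(
    summary[summary$response != "none", ],
    ggplot2::aes(x = .data$group, y = .data$proportion, fill = .data$response)
  ) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = "Proportion of cells", fill = "Response") +
    ggplot2::theme_minimal()
}
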