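#' Clip-and-rescale intensity normalization
#'
#' Sets the bottom `clip_fraction` quantile of intensities to 0 and the top
#' `clip_fraction` quantile to 1 (default 0.1% at each end), rescaling
#' linearly in between. Quantiles use linear interpolation between order
#' statistics. The transform is monotone non-decreasing and preserves the
#' rank order of unclipped voxels.
#'
#' @param channel Numeric array (any shape).
#' @param clip_fraction Fraction clipped at each extreme, in `[0, 0.5)`.
#' @return Array of the same shape with values in `[0, 1]`.
#' @export
normalize_clip <- function(channel, clip_fraction = 0.001) {
  stopifnot(is.numeric(channel), length(channel) > 0)
  stopifnot(clip_fraction >= 0, clip_fraction < 0.5)
  q <- stats::quantile(
    channel, c(clip_fraction, 1 - clip_fraction),
    names = FALSE, type = 7
  )
  if (q[2] <= q[1]) {
    warning("channel has (near-)constant intensity; returning all zeros")
    out <- channel
    out[] <- 0
    return(out)
  }
  out <- (channel - q[1]) / (q[2] - q[1])
  out[out < 0] <- 0
  out[out > 1] <- 1
  out
}

#' Z-score a channel
#'
#' Standardizes so that voxels inside `mask` (or all voxels) have mean 0 and
#' standard deviation 1; voxels outside the mask receive the same affine
#' transform. The population (denominator n) standard deviation is used, so
#' the zero-shift autocovariance of a z-scored channel is exactly 1.
#'
#' @param channel Numeric array.
#' @param mask Optional logical array of the same shape.
#' @return Array of the same shape.
#' @export
zscore_channel <- function(channel, mask = NULL) {
  vals <- if (is.null(mask)) channel else channel[mask != 0]
  if (length(vals) < 2) stop("need at least 2 voxels to z-score", call. = FALSE)
  mu <- mean(vals)
  sdev <- sqrt(mean((vals - mu)^2))
  if (sdev == 0) stop("zero variance: cannot z-score", call. = FALSE)
  (channel - mu) / sdev
}

#' Nuclear mask from a DAPI channel
#'
#' Thresholds the normalized nuclear stain with Otsu's method and removes
#' components smaller than `min_voxels`. Used to exclude cell nuclei from
#' terminal detection and from the randomized puncta placements.
#'
#' @param dapi_channel Normalized (`[0,1]`) 3D array.
#' @param min_voxels Minimum component size kept.
#' @return Logical 3D array.
#' @export
make_nuclear_mask <- function(dapi_channel, min_voxels = 20L) {
  stopifnot(is.array(dapi_channel), length(dim(dapi_channel)) == 3)
  if (max(dapi_channel) - min(dapi_channel) <= 0) {
    return(array(FALSE, dim = dim(dapi_channel)))
  }
  thr <- otsu_threshold(as.numeric(dapi_channel))
  mask <- dapi_channel >= thr
  lab <- label_components(mask)
  if (max(lab) > 0) {
    sizes <- tabulate(lab[lab > 0])
    keep <- which(sizes >= min_voxels)
    mask <- array(lab %in% keep, dim = dim(lab))
  }
  mask
}

#' Tissue mask from the summed channels
#'
#' Marks voxels whose summed channel intensity exceeds a low threshold —
#' half the modal intensity of the summed channels, i.e. half the diffuse
#' in-tissue background — then closes the mask with a 1-voxel ball. Image
#' borders with no signal (slide edges outside the section) fall well below
#' that level and end up excluded, while tissue voxels, whose autofluorescent
#' background sits at the mode, are retained.
#'
#' @param stack A [volume_stack()].
#' @param mode_bins Histogram bins used to locate the modal intensity.
#' @return Logical 3D array.
#' @export
make_tissue_mask <- function(stack, mode_bins = 256L) {
  stopifnot(inherits(stack, "volume_stack"))
  total <- Reduce(`+`, stack$channels)
  rng <- range(total)
  if (rng[2] <= rng[1]) {
    return(array(total > 0, dim = dim(total)))
  }
  h <- graphics::hist(
    as.numeric(total),
    breaks = seq(rng[1], rng[2], length.out = mode_bins + 1L),
    plot = FALSE
  )
  modal <- h$mids[which.max(h$counts)]
  thr <- 0.5 * max(modal, .Machine$double.eps)
  raw <- total > thr
  # opening removes isolated off-tissue noise voxels, closing fills pinholes
  close_ball(dilate_ball(erode_ball(raw, 1L), 1L))
}

#' Bundle tissue and nuclear masks
#'
#' Enforces the containment `nuclei` within `tissue` and provides the
#' `allowed` region (tissue excluding nuclei) used by randomized placements.
#'
#' @param tissue,nuclei Logical 3D arrays of the same shape.
#' @return A list of class `mask_set` with elements `tissue`, `nuclei`,
#'   `allowed`.
#' @export
mask_set <- function(tissue, nuclei) {
  stopifnot(identical(dim(tissue), dim(nuclei)))
  tissue <- tissue != 0
  nuclei <- (nuclei != 0) & tissue
  structure(
    list(tissue = tissue, nuclei = nuclei, allowed = tissue & !nuclei),
    class = "mask_set"
  )
}

#' Normalize every channel of a stack
#'
#' Applies [normalize_clip()] channel-wise and flags the channels normalized.
#'
#' @param stack A [volume_stack()].
#' @param clip_fraction Passed to [normalize_clip()].
#' @return The normalized stack.
#' @export
normalize_stack <- function(stack, clip_fraction = 0.001) {
  stopifnot(inherits(stack, "volume_stack"))
  stack$channels <- lapply(stack$channels, normalize_clip, clip_fraction = clip_fraction)
  stack$normalized[] <- TRUE
  stack
}
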