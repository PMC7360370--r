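#' Cross-covariance over in-plane shifts
#'
#' For every in-plane shift `(dr, dc)` in `[-max_shift, max_shift]^2`,
#' computes the covariance between channel `a` and channel `b` shifted by
#' `(dr, dc)`, over the valid overlap only (no padding), pooled across
#' z-planes. Population (denominator n) covariance is used, so for a
#' z-scored channel against itself the zero-shift value is exactly 1.
#'
#' @param channel_a,channel_b Z-scored 3D arrays of identical shape.
#' @param max_shift Maximum shift in pixels (default 10).
#' @return A `shift_covariance` tibble with columns `dr`, `dc`, `covariance`.
#' @export
shift_covariance <- function(channel_a, channel_b, max_shift = 10L) {
  stopifnot(identical(dim(channel_a), dim(channel_b)))
  d <- dim(channel_a)
  if (d[2] < 2 * max_shift + 1 || d[3] < 2 * max_shift + 1) {
    stop("image smaller than 2*max_shift + 1 in-plane", call. = FALSE)
  }
  shifts <- expand.grid(dr = -max_shift:max_shift, dc = -max_shift:max_shift)
  cov_at <- function(dr, dc) {
    # overlap rows/cols in a; b is indexed at +(dr, dc)
    ra <- max(1, 1 - dr):min(d[2], d[2] - dr)
    ca <- max(1, 1 - dc):min(d[3], d[3] - dc)
    av <- channel_a[, ra, ca, drop = FALSE]
    bv <- channel_b[, ra + dr, ca + dc, drop = FALSE]
    mean(av * bv) - mean(av) * mean(bv)
  }
  out <- tibble::tibble(
    dr = shifts$dr,
    dc = shifts$dc,
    covariance = mapply(cov_at, shifts$dr, shifts$dc)
  )
  structure(out, class = c("shift_covariance", class(out)))
}

#' Covariance of two channels within a mask
#'
#' Channels must be z-scored over the whole stack (not within the mask);
#' the covariance is then computed only over mask voxels:
#' `mean(a*b) - mean(a) * mean(b)` within the mask. Because the global
#' z-scoring does not renormalize within the mask, values may exceed
#' `[-1, 1]` when a signal is concentrated in (or absent from) the mask.
#'
#' @param channel_a,channel_b Globally z-scored 3D arrays.
#' @param mask Logical array with at least 2 voxels set.
#' @return A one-row tibble: `covariance`, `n_voxels`.
#' @export
masked_covariance <- function(channel_a, channel_b, mask) {
  stopifnot(identical(dim(channel_a), dim(channel_b)),
    identical(dim(channel_a), dim(mask)))
  idx <- which(mask != 0)
  if (length(idx) < 2) stop("mask must contain at least 2 voxels", call. = FALSE)
  a <- channel_a[idx]
  b <- channel_b[idx]
  tibble::tibble(
    covariance = mean(a * b) - mean(a) * mean(b),
    n_voxels = length(idx)
  )
}

#' Pairwise channel covariance matrices
#'
#' Z-scores each requested channel over the whole stack and returns, for
#' every unordered channel pair, the zero-shift global covariance and
#' (optionally) the covariance restricted to a mask — the global
#' cross-correlation versus within-terminal covariance comparison.
#'
#' @param stack A [volume_stack()].
#' @param channels Channel names (default all).
#' @param mask Optional logical array (e.g. the terminal mask).
#' @return Tibble with `channel_a`, `channel_b`, `global_covariance` and,
#'   when `mask` is given, `masked_covariance`.
#' @export
channel_covariance_matrix <- function(stack, channels = NULL, mask = NULL) {
  stopifnot(inherits(stack, "volume_stack"))
  if (is.null(channels)) channels <- names(stack$channels)
  zs <- lapply(channels, function(ch) zscore_channel(get_channel(stack, ch)))
  names(zs) <- channels
  pairs <- expand.grid(
    i = seq_along(channels), j = seq_along(channels)
  )
  pairs <- pairs[pairs$i <= pairs$j, , drop = FALSE]
  out <- purrr::pmap_dfr(pairs, function(i, j) {
    a <- zs[[i]]
    b <- zs[[j]]
    row <- tibble::tibble(
      channel_a = channels[i],
      channel_b = channels[j],
      global_covariance = mean(a * b) - mean(a) * mean(b)
    )
    if (!is.null(mask)) {
      row$masked_covariance <- masked_covariance(a, b, mask)$covariance
    }
    row
  })
  out
}
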