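# Histogram-based automatic thresholds (Otsu; Renyi entropy).
#
# Both operate on a 256-bin histogram over the observed intensity range and
# return a threshold on the intensity scale: the upper edge of the last
# background bin, so "value >= threshold" (Otsu positivity) and
# "value > threshold" (binarization) behave as expected for well-separated
# modes. Ties in either criterion resolve to the lowest candidate bin.

hist_256 <- function(values, n_bins = 256L) {
  rng <- range(values)
  if (!(rng[2] > rng[1])) stop("constant sample: cannot threshold", call. = FALSE)
  edges <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  bin <- findInterval(values, edges, rightmost.closed = TRUE, all.inside = TRUE)
  counts <- tabulate(bin, nbins = n_bins)
  list(counts = counts, edges = edges, mids = (edges[-1] + edges[-(n_bins + 1L)]) / 2)
}

#' Otsu's threshold
#'
#' The intensity threshold that maximizes between-class variance (equivalently
#' minimizes intraclass variance) over a 256-bin histogram of the sample.
#'
#' @param values Numeric vector (or array) of intensities with at least two
#'   distinct values.
#' @param n_bins Number of histogram bins.
#' @return A single threshold on the intensity scale; classify as positive
#'   when a value is `>=` the threshold.
#' @export
otsu_threshold <- function(values, n_bins = 256L) {
  values <- as.numeric(values)
  h <- hist_256(values, n_bins)
  p <- h$counts / sum(h$counts)
  mids <- h$mids
  w0 <- cumsum(p)
  mu_cum <- cumsum(p * mids)
  mu_tot <- mu_cum[n_bins]
  t_cand <- seq_len(n_bins - 1L)
  w1 <- 1 - w0[t_cand]
  valid <- w0[t_cand] > 0 & w1 > 0
  crit <- rep(-Inf, length(t_cand))
  mu0 <- mu_cum[t_cand][valid] / w0[t_cand][valid]
  mu1 <- (mu_tot - mu_cum[t_cand][valid]) / w1[valid]
  crit[valid] <- w0[t_cand][valid] * w1[valid] * (mu0 - mu1)^2
  t_best <- which.max(crit) # lowest index on ties
  h$edges[t_best + 1L]
}

# Renyi entropy criterion for splitting a normalized histogram after bin t.
# alpha = 1 is the Shannon (Kapur) limit.
renyi_split_criterion <- function(p, t, alpha) {
  n <- length(p)
  P <- sum(p[seq_len(t)])
  if (P <= 0 || P >= 1) {
    return(-Inf)
  }
  pb <- p[seq_len(t)] / P
  pf <- p[(t + 1L):n] / (1 - P)
  if (abs(alpha - 1) < 1e-12) {
    hb <- -sum(pb[pb > 0] * log(pb[pb > 0]))
    hf <- -sum(pf[pf > 0] * log(pf[pf > 0]))
  } else {
    hb <- log(sum(pb[pb > 0]^alpha)) / (1 - alpha)
    hf <- log(sum(pf[pf > 0]^alpha)) / (1 - alpha)
  }
  hb + hf
}

renyi_bin_threshold <- function(p, alpha) {
  crit <- vapply(
    seq_len(length(p) - 1L),
    function(t) renyi_split_criterion(p, t, alpha),
    numeric(1)
  )
  which.max(crit)
}

#' Renyi-entropy threshold
#'
#' For each Renyi order `alpha`, finds the histogram split maximizing the sum
#' of the background and foreground Renyi entropies (the Shannon/Kapur
#' maximum-entropy threshold at `alpha = 1`). When the standard three orders
#' `(0.5, 1, 2)` are given, the per-order thresholds are combined with the
#' three-order weighting rule of the classic Renyi-entropy autothreshold; a
#' single `alpha` returns that order's threshold directly.
#'
#' @param values Numeric vector/array of intensities (>= 2 distinct values).
#' @param alphas Renyi orders; either one value or the standard three.
#' @param n_bins Number of histogram bins.
#' @return Threshold on the intensity scale; binarize as `value > threshold`.
#' @export
renyi_entropy_threshold <- function(values, alphas = c(0.5, 1, 2), n_bins = 256L) {
  values <- as.numeric(values)
  h <- hist_256(values, n_bins)
  p <- h$counts / sum(h$counts)
  if (length(alphas) == 1) {
    t_best <- renyi_bin_threshold(p, alphas)
    return(h$edges[t_best + 1L])
  }
  if (length(alphas) != 3) {
    stop("alphas must be a single order or the standard three", call. = FALSE)
  }
  ts <- sort(vapply(alphas, function(a) renyi_bin_threshold(p, a), integer(1)))
  t1 <- ts[1]; t2 <- ts[2]; t3 <- ts[3]
  P1 <- cumsum(p)
  if (abs(t1 - t2) <= 5) {
    if (abs(t2 - t3) <= 5) {
      b <- c(1, 2, 1)
    } else {
      b <- c(0, 1, 3)
    }
  } else {
    if (abs(t2 - t3) <= 5) {
      b <- c(3, 1, 0)
    } else {
      b <- c(1, 2, 1)
    }
  }
  omega <- P1[t3] - P1[t1]
  t_opt <- floor(
    t1 * (P1[t1] + 0.25 * omega * b[1]) +
      0.25 * t2 * omega * b[2] +
      t3 * (1 - P1[t3] + 0.25 * omega * b[3])
  )
  t_opt <- min(max(t_opt, 1L), n_bins - 1L)
  h$edges[t_opt + 1L]
}
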