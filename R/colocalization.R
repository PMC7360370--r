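#' Find candidate puncta regions in an antibody channel
#'
#' Candidates are local intensity maxima exceeding the background mean plus
#' `k` standard deviations (background statistics taken over the tissue mask,
#' or the whole image), each with its connected suprathreshold region. Two
#' maxima inside one suprathreshold component yield two candidates.
#'
#' @param antibody_channel Normalized 3D array.
#' @param tissue_mask Optional logical array for background statistics.
#' @param k Threshold in background standard deviations (default 2).
#' @return A list with `peaks` (tibble of seed voxels `z`,`y`,`x` and linear
#'   index) and `regions` (list of linear-index vectors, one per candidate)
#'   and the `threshold` used.
#' @export
detect_puncta_candidates <- function(antibody_channel, tissue_mask = NULL, k = 2) {
  stopifnot(is.array(antibody_channel), length(dim(antibody_channel)) == 3)
  d <- dim(antibody_channel)
  vals <- if (is.null(tissue_mask)) {
    as.numeric(antibody_channel)
  } else {
    antibody_channel[tissue_mask != 0]
  }
  thr <- mean(vals) + k * stats::sd(vals)
  seeds <- local_maxima(antibody_channel, thr)
  if (length(seeds) == 0) {
    return(list(
      peaks = tibble::tibble(z = integer(), y = integer(), x = integer(), index = integer()),
      regions = list(), threshold = thr
    ))
  }
  supra <- label_components(antibody_channel > thr)
  seed_comp <- supra[seeds]
  # assign each suprathreshold voxel to the nearest seed of its component
  idx_all <- which(supra > 0)
  co_all <- arrayInd(idx_all, d)
  co_seed <- arrayInd(seeds, d)
  regions <- vector("list", length(seeds))
  for (comp in unique(seed_comp)) {
    s_in <- which(seed_comp == comp)
    v_in <- which(supra[idx_all] == comp)
    if (length(s_in) == 1) {
      regions[[s_in]] <- idx_all[v_in]
    } else {
      dmat <- outer(rep(1, length(v_in)), rep(0, length(s_in)))
      for (j in seq_along(s_in)) {
        sc <- co_seed[s_in[j], ]
        dmat[, j] <- (co_all[v_in, 1] - sc[1])^2 +
          (co_all[v_in, 2] - sc[2])^2 + (co_all[v_in, 3] - sc[3])^2
      }
      assign <- max.col(-dmat, ties.method = "first")
      for (j in seq_along(s_in)) {
        regions[[s_in[j]]] <- idx_all[v_in[assign == j]]
      }
    }
  }
  co <- arrayInd(seeds, d)
  list(
    peaks = tibble::tibble(z = co[, 1], y = co[, 2], x = co[, 3], index = seeds),
    regions = regions,
    threshold = thr
  )
}

# least-squares 2D Gaussian + constant background on the brightest plane of a
# candidate region; fallback = brightest voxel of the region.
fit_punctum_peak_one <- function(channel, region, d) {
  co <- arrayInd(region, d)
  bright <- region[which.max(channel[region])]
  bright_co <- arrayInd(bright, d)
  if (length(region) < 5) {
    return(list(z = bright_co[1], y = bright_co[2], x = bright_co[3],
      fit_ok = FALSE, amplitude = channel[bright], sx = NA_real_,
      sy = NA_real_, background = NA_real_))
  }
  zi <- bright_co[1]
  in_plane <- co[co[, 1] == zi, , drop = FALSE]
  y0 <- max(min(in_plane[, 2]) - 2L, 1L)
  y1 <- min(max(in_plane[, 2]) + 2L, d[2])
  x0 <- max(min(in_plane[, 3]) - 2L, 1L)
  x1 <- min(max(in_plane[, 3]) + 2L, d[3])
  win <- channel[zi, y0:y1, x0:x1]
  yy <- rep(y0:y1, times = x1 - x0 + 1L)
  xx <- rep(x0:x1, each = y1 - y0 + 1L)
  vv <- as.numeric(win)
  w <- pmax(vv - min(vv), 0)
  cy <- sum(yy * w) / max(sum(w), .Machine$double.eps)
  cx <- sum(xx * w) / max(sum(w), .Machine$double.eps)
  fit <- tryCatch(
    stats::nls(
      vv ~ b + A * exp(-((yy - my)^2 / (2 * sy^2) + (xx - mx)^2 / (2 * sx^2))),
      start = list(
        b = min(vv), A = max(vv) - min(vv),
        my = cy, mx = cx, sy = 1, sx = 1
      ),
      control = stats::nls.control(maxiter = 100, warnOnly = FALSE),
      algorithm = "port",
      lower = c(b = -Inf, A = 0, my = y0 - 1, mx = x0 - 1, sy = 0.2, sx = 0.2),
      upper = c(b = Inf, A = Inf, my = y1 + 1, mx = x1 + 1, sy = 20, sx = 20)
    ),
    error = function(e) NULL
  )
  if (is.null(fit)) {
    return(list(z = bright_co[1], y = bright_co[2], x = bright_co[3],
      fit_ok = FALSE, amplitude = channel[bright], sx = NA_real_,
      sy = NA_real_, background = NA_real_))
  }
  cf <- stats::coef(fit)
  py <- as.integer(round(cf[["my"]]))
  px <- as.integer(round(cf[["mx"]]))
  peak_idx <- if (py >= 1 && py <= d[2] && px >= 1 && px <= d[3]) {
    coords_to_index(zi, py, px, d)
  } else {
    NA_integer_
  }
  if (is.na(peak_idx) || !(peak_idx %in% region)) {
    # fitted center left the candidate region: fall back to brightest voxel
    return(list(z = bright_co[1], y = bright_co[2], x = bright_co[3],
      fit_ok = FALSE, amplitude = channel[bright], sx = NA_real_,
      sy = NA_real_, background = NA_real_))
  }
  list(
    z = zi, y = py, x = px, fit_ok = TRUE,
    amplitude = unname(cf[["A"]]), sx = unname(cf[["sx"]]),
    sy = unname(cf[["sy"]]), background = unname(cf[["b"]])
  )
}

#' Localize one punctum by Gaussian fit
#'
#' Fits a 2D Gaussian plus constant background to the brightest z-plane of a
#' candidate region (least squares) and returns the voxel nearest the fitted
#' center. Regions with fewer than 5 voxels, failed fits, and fits whose
#' center leaves the region fall back to the brightest voxel, flagged
#' `fit_ok = FALSE`.
#'
#' @param channel 3D array.
#' @param region Integer vector of linear voxel indices of the candidate.
#' @return A one-row tibble with `z`, `y`, `x`, `fit_ok`, `amplitude`, `sx`,
#'   `sy`, `background`.
#' @export
fit_punctum_peak <- function(channel, region) {
  stopifnot(is.array(channel), length(dim(channel)) == 3, length(region) >= 1)
  res <- fit_punctum_peak_one(channel, region, dim(channel))
  tibble::as_tibble(res)
}

#' Detect and localize puncta in a channel
#'
#' Runs [detect_puncta_candidates()] then [fit_punctum_peak()] on each
#' candidate, giving one peak voxel per accepted punctum.
#'
#' @inheritParams detect_puncta_candidates
#' @param channel_name Name recorded in the output.
#' @return A `puncta_set`: tibble with `channel`, `z`, `y`, `x`, `index`,
#'   `fit_ok`, `amplitude`, `sx`, `sy`, `background`.
#' @export
detect_puncta <- function(antibody_channel, tissue_mask = NULL, k = 2,
                          channel_name = "antibody") {
  cand <- detect_puncta_candidates(antibody_channel, tissue_mask, k)
  d <- dim(antibody_channel)
  if (length(cand$regions) == 0) {
    out <- tibble::tibble(
      channel = character(), z = integer(), y = integer(), x = integer(),
      index = integer(), fit_ok = logical(), amplitude = double(),
      sx = double(), sy = double(), background = double()
    )
    return(structure(out, class = c("puncta_set", class(out))))
  }
  fits <- lapply(cand$regions, function(r) fit_punctum_peak_one(antibody_channel, r, d))
  out <- dplyr::bind_rows(lapply(fits, tibble::as_tibble))
  out <- dplyr::mutate(
    out,
    channel = channel_name,
    index = coords_to_index(.data$z, .data$y, .data$x, d),
    .before = 1
  )
  out <- dplyr::relocate(out, "channel", "z", "y", "x", "index")
  structure(out, class = c("puncta_set", class(out)))
}

#' Colocalization density of puncta in a mask
#'
#' Number of puncta peak voxels falling inside the mask, divided by the mask
#' voxel count.
#'
#' @param puncta A puncta table with `z`, `y`, `x` (or `index`) columns.
#' @param mask Logical 3D array (non-empty).
#' @return Density in puncta per mask voxel.
#' @export
coloc_density <- function(puncta, mask) {
  m <- sum(mask != 0)
  if (m == 0) stop("empty mask", call. = FALSE)
  if (nrow(puncta) == 0) {
    return(0)
  }
  idx <- puncta_indices(puncta, dim(mask))
  sum(mask[idx] != 0) / m
}

puncta_indices <- function(puncta, d) {
  if ("index" %in% names(puncta) && !anyNA(puncta$index)) {
    return(puncta$index)
  }
  coords_to_index(puncta$z, puncta$y, puncta$x, d)
}

#' Concentric shell masks around a terminal mask
#'
#' Shell `k` is the mask dilated `k` single-voxel steps minus the mask dilated
#' `k - 1` steps (26-neighbourhood ball); shell 0 is the mask itself. Nuclei
#' voxels are excluded from shells.
#'
#' @param mask Logical 3D array.
#' @param n_shells Number of shells.
#' @param nuclei Optional logical array excluded from shells.
#' @return List of logical arrays, names `"0"`, `"1"`, ..., `"n_shells"`.
#' @export
shell_masks <- function(mask, n_shells, nuclei = NULL) {
  stopifnot(n_shells >= 1)
  mask <- mask != 0
  shells <- list("0" = mask)
  prev <- mask
  for (k in seq_len(n_shells)) {
    cur <- dilate_ball(prev, 1L)
    shell <- cur & !prev
    if (!is.null(nuclei)) shell <- shell & !(nuclei != 0)
    shells[[as.character(k)]] <- shell
    prev <- cur
  }
  shells
}

#' Shell profile of puncta densities
#'
#' Puncta density (peaks per voxel) in the mask and in each expanding
#' single-voxel concentric shell around it.
#'
#' @inheritParams coloc_density
#' @param n_shells Number of shells.
#' @param nuclei Optional logical array excluded from shells.
#' @return Tibble with `shell` (0 = mask), `n_voxels`, `n_puncta`, `density`;
#'   zero-volume shells have `NA` density and are flagged `degenerate`.
#' @export
shell_profile <- function(puncta, mask, n_shells = 10L, nuclei = NULL) {
  shells <- shell_masks(mask, n_shells, nuclei)
  idx <- if (nrow(puncta) > 0) puncta_indices(puncta, dim(mask)) else integer(0)
  purrr::imap_dfr(shells, function(sh, nm) {
    nv <- sum(sh)
    np <- if (length(idx) > 0) sum(sh[idx]) else 0L
    tibble::tibble(
      shell = as.integer(nm),
      n_voxels = nv,
      n_puncta = np,
      density = if (nv > 0) np / nv else NA_real_,
      degenerate = nv == 0
    )
  })
}

#' Randomized-placement null densities
#'
#' Relocates every punctum independently and uniformly over the allowed
#' region (tissue excluding nuclei) `n_randomizations` times, preserving the
#' puncta count, and recomputes the density in the mask (and optionally each
#' shell) for each round.
#'
#' @param puncta Puncta table (its row count sets the number of points) or a
#'   single integer count.
#' @param allowed_mask Logical 3D array of permitted voxels.
#' @param mask Logical 3D array, the terminal mask.
#' @param n_randomizations Number of rounds (default 1000).
#' @param seed Integer seed; identical seeds give identical nulls.
#' @param shells Optional list from [shell_masks()] for per-shell nulls.
#' @return A list with `null_density` (numeric vector, one per round) and,
#'   when `shells` is given, `null_shell_density` (matrix rounds x shells).
#' @export
randomized_null <- function(puncta, allowed_mask, mask,
                            n_randomizations = 1000L, seed = 1L,
                            shells = NULL) {
  n_pts <- if (is.numeric(puncta) && length(puncta) == 1) {
    as.integer(puncta)
  } else {
    nrow(puncta)
  }
  if (n_pts < 1) stop("need at least one punctum", call. = FALSE)
  allowed_idx <- which(allowed_mask != 0)
  if (length(allowed_idx) == 0) stop("no allowed voxels", call. = FALSE)
  m <- sum(mask != 0)
  if (m == 0) stop("empty mask", call. = FALSE)
  withr::with_seed(as.integer(seed), {
    draws <- matrix(
      sample(allowed_idx, n_pts * n_randomizations, replace = TRUE),
      nrow = n_pts
    )
    in_mask <- array(mask[draws] != 0, dim = dim(draws))
    out <- list(null_density = colSums(in_mask) / m)
    if (!is.null(shells)) {
      shell_names <- names(shells)
      nsd <- matrix(NA_real_, nrow = n_randomizations, ncol = length(shells),
        dimnames = list(NULL, shell_names))
      for (j in seq_along(shells)) {
        sv <- sum(shells[[j]])
        if (sv > 0) {
          hit <- array(shells[[j]][draws] != 0, dim = dim(draws))
          nsd[, j] <- colSums(hit) / sv
        }
      }
      out$null_shell_density <- nsd
    }
    out
  })
}

#' Enrichment z-score against a randomized null
#'
#' `z = (observed - mean(null)) / sd(null)` with the sample (n-1) standard
#' deviation of the null densities.
#'
#' @param observed Observed density.
#' @param null_values Numeric vector of null densities (length >= 2).
#' @return The z-score.
#' @export
coloc_zscore <- function(observed, null_values) {
  if (length(null_values) < 2) {
    stop("need at least 2 null values", call. = FALSE)
  }
  s <- stats::sd(null_values)
  if (s == 0) stop("zero null spread: z-score undefined", call. = FALSE)
  (observed - mean(null_values)) / s
}

#' Full colocalization analysis of one or more antibody channels
#'
#' For each antibody channel: detect and localize puncta, compute the
#' observed density in the terminal mask and its shell profile, build the
#' randomized-placement null (puncta relocated uniformly over tissue
#' excluding nuclei), and convert to an enrichment z-score.
#'
#' @param stack A normalized [volume_stack()].
#' @param terminal_mask Logical 3D array (the reporter terminal mask).
#' @param masks A [mask_set()].
#' @param channels Antibody channel names (default: all `role == "antibody"`).
#' @param n_randomizations Null rounds.
#' @param n_shells Shells in the profile.
#' @param seed Integer seed (one independent substream per channel).
#' @param k Candidate threshold in background sds.
#' @return A `coloc_result`: list with `summary` (tibble: channel, n_puncta,
#'   observed_density, null_mean, null_sd, z_score, n_randomizations),
#'   `shells` (tibble of per-shell observed and null mean densities) and
#'   `puncta` (combined puncta table).
#' @export
coloc_analysis <- function(stack, terminal_mask, masks,
                           channels = NULL,
                           n_randomizations = 1000L,
                           n_shells = 10L,
                           seed = 1L, k = 2) {
  stopifnot(inherits(stack, "volume_stack"), inherits(masks, "mask_set"))
  if (is.null(channels)) channels <- channels_with_role(stack, "antibody")
  shells <- shell_masks(terminal_mask, n_shells, nuclei = masks$nuclei)
  summaries <- list()
  shell_rows <- list()
  puncta_all <- list()
  for (i in seq_along(channels)) {
    ch <- channels[i]
    puncta <- detect_puncta(
      get_channel(stack, ch),
      tissue_mask = masks$tissue, k = k, channel_name = ch
    )
    puncta_all[[ch]] <- puncta
    obs <- coloc_density(puncta, terminal_mask)
    prof <- shell_profile(puncta, terminal_mask, n_shells, nuclei = masks$nuclei)
    nul <- randomized_null(
      puncta, masks$allowed, terminal_mask,
      n_randomizations = n_randomizations,
      seed = as.integer(seed) + i - 1L,
      shells = shells
    )
    summaries[[ch]] <- tibble::tibble(
      channel = ch,
      n_puncta = nrow(puncta),
      observed_density = obs,
      null_mean = mean(nul$null_density),
      null_sd = stats::sd(nul$null_density),
      z_score = coloc_zscore(obs, nul$null_density),
      n_randomizations = n_randomizations
    )
    prof$null_mean <- colMeans(nul$null_shell_density)
    prof$null_sd <- apply(nul$null_shell_density, 2, stats::sd)
    prof$channel <- ch
    shell_rows[[ch]] <- prof
  }
  structure(
    list(
      summary = dplyr::bind_rows(summaries),
      shells = dplyr::bind_rows(shell_rows),
      puncta = dplyr::bind_rows(puncta_all)
    ),
    class = "coloc_result"
  )
}

#' @export
print.coloc_result <- function(x, ...) {
  cat("<coloc_result>\n")
  print(x$summary)
  invisible(x)
}

#' Tidy a colocalization result
#'
#' @param x A `coloc_result`.
#' @param ... Unused.
#' @return The per-channel summary tibble.
#' @method tidy coloc_result
#' @export
tidy.coloc_result <- function(x, ...) x$summary

#' One-row overview of a colocalization result
#'
#' @param x A `coloc_result`.
#' @param ... Unused.
#' @return A one-row tibble: channels analyzed, randomization rounds, and the
#'   range of z-scores.
#' @method glance coloc_result
#' @export
glance.coloc_result <- function(x, ...) {
  tibble::tibble(
    n_channels = nrow(x$summary),
    n_randomizations = x$summary$n_randomizations[1],
    min_z = min(x$summary$z_score),
    max_z = max(x$summary$z_score)
  )
}
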