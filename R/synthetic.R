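#' Parameters for synthetic scenes
#'
#' Bundles the generating parameters for ground-truth-labeled synthetic
#' image stacks. Defaults describe an array-tomography-like field: sparse
#' ellipsoidal reporter-labeled terminals spanning several 70 nm planes, a few
#' nuclei, and punctate antibody channels. Terminals are a two-population
#' mixture: a fraction `fraction_dual` carry both GABA- and ACh-release
#' machinery, the rest GABA only; the ACh-like channel is enriched only in
#' dual terminals.
#'
#' @param shape Image shape `(z, rows, cols)`.
#' @param border_px In-plane width, in pixels, of the dark off-section border
#'   (no tissue background, no structures); 0 means the whole field is
#'   tissue.
#' @param n_terminals Number of terminals placed.
#' @param fraction_dual Probability a terminal is dual (GABA + ACh).
#' @param terminal_radius_z,terminal_radius_xy Mean ellipsoid semi-axes
#'   (voxels); each terminal jitters around these.
#' @param channels Named list describing antibody channels. Each element is a
#'   list with `inside_rate` (expected puncta per terminal voxel),
#'   `outside_rate` (expected puncta per non-terminal tissue voxel) and
#'   `dual_only` (restrict inside placement to dual terminals).
#' @param n_nuclei,nucleus_radius Nuclei count and in-plane radius (voxels).
#' @param psf_sd In-plane Gaussian spot standard deviation (voxels).
#' @param psf_sd_z Axial spot standard deviation (voxels).
#' @param noise_sd Additive Gaussian noise standard deviation.
#' @param background_level Mean background intensity of antibody channels.
#' @param reporter_level Mean terminal intensity in the reporter channel.
#' @param intensity_mean,intensity_sd Per-terminal mean VGAT/VAChT-like
#'   intensities (confocal scenes): means and sds of the bivariate draw for
#'   dual terminals.
#' @param rho Correlation between VGAT-like and VAChT-like per-terminal
#'   intensities within dual terminals; the default reproduces an overall
#'   squared correlation near the 0.33 reported for real terminal pairs.
#' @param n_background_blobs Reporter-channel distractor blobs (low
#'   intensity), default 0.
#' @param n_offtarget_vacht Confocal scenes: VAChT-positive structures that do
#'   not belong to the reporter-labeled population (cholinergic afferent
#'   terminals from other sources are present throughout real cortex).
#'   Painted only into the VAChT-like channel; they anchor the per-image
#'   Otsu threshold even when no reporter terminal carries VAChT. The
#'   default scales with the tissue volume (one per 6000 voxels), since
#'   afferent density is a property of the tissue, not of the reporter.
#' @param n_offtarget_vgat Confocal scenes: VGAT-positive structures outside
#'   the reporter-labeled population (most GABAergic terminals in cortex
#'   belong to other interneuron classes). Painted only into the VGAT-like
#'   channel; they keep the global channel correlation low relative to the
#'   within-mask covariance, as in real tissue. Default: one per 1500
#'   voxels.
#' @param n_cells Cells in FISH scenes.
#' @param cell_radius Mean FISH cell radius (pixels).
#' @param coverage_pos,coverage_neg,background_dot_rate Per-pixel dot rates
#'   for positive cells, negative cells and extracellular background in FISH
#'   scenes. Nonspecific binding is the same inside and outside cells, so
#'   `coverage_neg` defaults to the background rate.
#' @param diffuse_level Diffuse cytoplasmic signal painted across cells
#'   positive for a probe (RNAscope-positive cells show diffuse signal under
#'   their transcript dots); keeps the combined-channel cell mask solid.
#' @param probes Probe names for FISH scenes.
#' @param pattern_probs Named probabilities of joint positivity patterns for
#'   FISH scenes; names are strings like `"+-"` aligned with `probes`.
#' @return A list of class `scene_params`.
#' @export
scene_params <- function(shape = c(8, 192, 192),
                         border_px = 0,
                         n_terminals = 60,
                         fraction_dual = 0.75,
                         terminal_radius_z = 1.2,
                         terminal_radius_xy = 2.6,
                         channels = list(
                           VGAT = list(inside_rate = 0.05, outside_rate = 2e-4, dual_only = FALSE),
                           VAChT = list(inside_rate = 0.05, outside_rate = 2e-4, dual_only = TRUE),
                           PSD95 = list(inside_rate = 0, outside_rate = 2e-3, dual_only = FALSE)
                         ),
                         n_nuclei = 4,
                         nucleus_radius = 12,
                         psf_sd = 1.0,
                         psf_sd_z = 0.6,
                         noise_sd = 0.02,
                         background_level = 0.05,
                         reporter_level = 0.8,
                         intensity_mean = c(0.6, 0.6),
                         intensity_sd = c(0.12, 0.12),
                         rho = sqrt(0.33),
                         n_background_blobs = 0,
                         n_offtarget_vacht = round(prod(shape) / 6000),
                         n_offtarget_vgat = round(prod(shape) / 1500),
                         n_cells = 40,
                         cell_radius = 11,
                         coverage_pos = 0.5,
                         coverage_neg = 0.003,
                         background_dot_rate = 0.003,
                         diffuse_level = 0.15,
                         probes = c("Chat", "Cre"),
                         pattern_probs = c("++" = 0.90, "+-" = 0.03, "-+" = 0.03, "--" = 0.04)) {
  stopifnot(
    length(shape) == 3, all(shape >= 1),
    border_px >= 0, 2 * border_px < min(shape[2:3]),
    n_terminals >= 1,
    fraction_dual >= 0, fraction_dual <= 1,
    rho > -1, rho < 1,
    noise_sd > 0,
    coverage_pos >= 0, coverage_neg >= 0, background_dot_rate >= 0
  )
  rates <- unlist(lapply(channels, function(ch) c(ch$inside_rate, ch$outside_rate)))
  stopifnot(all(rates >= 0))
  structure(as.list(environment()), class = "scene_params")
}

# voxels of an axis-aligned ellipsoid clipped to the image; linear indices
ellipsoid_voxels <- function(center, radii, d) {
  lo <- pmax(ceiling(center - radii), 1)
  hi <- pmin(floor(center + radii), d)
  if (any(lo > hi)) {
    return(integer(0))
  }
  g <- expand.grid(
    z = lo[1]:hi[1], y = lo[2]:hi[2], x = lo[3]:hi[3],
    KEEP.OUT.ATTRS = FALSE
  )
  keep <- ((g$z - center[1]) / radii[1])^2 +
    ((g$y - center[2]) / radii[2])^2 +
    ((g$x - center[3]) / radii[3])^2 <= 1
  g <- g[keep, , drop = FALSE]
  coords_to_index(g$z, g$y, g$x, d)
}

# place n disjoint ellipsoids (`halo`-voxel separation), avoiding `occupied`
place_blobs <- function(n, radii_fun, d, occupied, margin = 2, max_tries = 200L,
                        what = "blob", halo = 1.5) {
  centers <- vector("list", n)
  voxels <- vector("list", n)
  for (i in seq_len(n)) {
    placed <- FALSE
    for (try in seq_len(max_tries)) {
      radii <- radii_fun()
      rand_between <- function(lo, hi, mid) {
        if (lo > hi) mid else stats::runif(1, lo, hi)
      }
      center <- c(
        rand_between(1 + radii[1], d[1] - radii[1], (1 + d[1]) / 2),
        rand_between(1 + margin + radii[2], d[2] - margin - radii[2], (1 + d[2]) / 2),
        rand_between(1 + margin + radii[3], d[3] - margin - radii[3], (1 + d[3]) / 2)
      )
      vox <- ellipsoid_voxels(center, radii, d)
      if (length(vox) == 0) next
      # halo keeps neighbouring blobs from touching under 26-connectivity
      guard <- ellipsoid_voxels(center, radii + halo, d)
      if (any(occupied[guard])) next
      occupied[guard] <- TRUE
      centers[[i]] <- center
      voxels[[i]] <- vox
      placed <- TRUE
      break
    }
    if (!placed) {
      stop(
        "infeasible placement: could not place ", what, " ", i, " of ", n,
        " (volume too crowded)",
        call. = FALSE
      )
    }
  }
  list(centers = centers, voxels = voxels, occupied = occupied)
}

# 3x3 in-plane box blur (single z-plane arrays); emulates diffraction softening
blur_plane <- function(img) {
  out <- img * 0
  cnt <- img * 0
  for (dy in -1:1) for (dx in -1:1) {
    out <- out + shift_array(img, 0, dy, dx, fill = 0)
    cnt <- cnt + shift_array(img * 0 + 1, 0, dy, dx, fill = 0)
  }
  out / cnt
}

# paint a 3D Gaussian spot (additive) around a voxel center
paint_spot <- function(arr, center, amplitude, sd_xy, sd_z) {
  d <- dim(arr)
  r <- ceiling(c(3 * sd_z, 3 * sd_xy, 3 * sd_xy))
  lo <- pmax(center - r, 1)
  hi <- pmin(center + r, d)
  zz <- lo[1]:hi[1]
  yy <- lo[2]:hi[2]
  xx <- lo[3]:hi[3]
  gz <- exp(-((zz - center[1])^2) / (2 * sd_z^2))
  gy <- exp(-((yy - center[2])^2) / (2 * sd_xy^2))
  gx <- exp(-((xx - center[3])^2) / (2 * sd_xy^2))
  spot <- amplitude * outer(gz, outer(gy, gx))
  arr[zz, yy, xx] <- arr[zz, yy, xx, drop = FALSE] + spot
  arr
}

place_nuclei <- function(params, d, occupied) {
  if (params$n_nuclei < 1) {
    return(list(
      centers = list(), voxels = list(), occupied = occupied
    ))
  }
  place_blobs(
    params$n_nuclei,
    function() {
      c(
        max(1.2, d[1] / 4),
        params$nucleus_radius * stats::runif(1, 0.85, 1.15),
        params$nucleus_radius * stats::runif(1, 0.85, 1.15)
      )
    },
    d, occupied,
    margin = 2 + params$border_px,
    what = "nucleus"
  )
}

place_terminals <- function(params, d, occupied) {
  place_blobs(
    params$n_terminals,
    function() {
      c(
        max(1.0, params$terminal_radius_z * stats::runif(1, 0.8, 1.3)),
        params$terminal_radius_xy * stats::runif(1, 0.75, 1.3),
        params$terminal_radius_xy * stats::runif(1, 0.75, 1.3)
      )
    },
    d, occupied,
    margin = 2 + params$border_px,
    what = "terminal"
  )
}

# logical array of in-tissue voxels (in-plane border excluded)
tissue_extent_mask <- function(params, d) {
  b <- params$border_px
  ext <- array(FALSE, dim = d)
  ext[, (b + 1):(d[2] - b), (b + 1):(d[3] - b)] <- TRUE
  ext
}

truth_terminal_table <- function(placement, classes, d) {
  n <- length(placement$centers)
  cent <- do.call(rbind, placement$centers)
  tibble::tibble(
    id = seq_len(n),
    z = cent[, 1], y = cent[, 2], x = cent[, 3],
    n_voxels = vapply(placement$voxels, length, integer(1)),
    class = classes,
    voxels = placement$voxels
  )
}

#' Generate a synthetic array-tomography scene
#'
#' Builds a stack with a terminal-reporter channel (ellipsoidal blobs, each
#' spanning multiple z-planes), a nuclear channel, and punctate antibody
#' channels whose puncta fall inside terminals at channel-specific rates and
#' uniformly in the remaining tissue at a background rate. Ground-truth
#' terminal classes and puncta positions (with parent terminal) are returned
#' alongside the stack.
#'
#' @param params A [scene_params()].
#' @param seed Integer seed; identical `(params, seed)` give identical scenes.
#' @return A list of class `synthetic_scene` with elements `stack`
#'   ([volume_stack()]), `truth_terminals`, `truth_puncta`, `truth_nuclei`,
#'   and `params`.
#' @export
generate_array_tomography_scene <- function(params = scene_params(), seed = 1L) {
  stopifnot(inherits(params, "scene_params"))
  d <- as.integer(params$shape)
  if (d[1] < 4 || d[2] < 64 || d[3] < 64) {
    stop("scene shape must be at least (4, 64, 64)", call. = FALSE)
  }
  withr::with_seed(as.integer(seed), {
    occupied <- array(FALSE, dim = d)
    nuc <- place_nuclei(params, d, occupied)
    term <- place_terminals(params, d, nuc$occupied)
    classes <- ifelse(
      stats::runif(params$n_terminals) < params$fraction_dual,
      "GABA_and_ACh", "GABA_only"
    )
    truth_terminals <- truth_terminal_table(term, classes, d)

    reporter <- array(0, dim = d)
    for (i in seq_len(params$n_terminals)) {
      reporter[term$voxels[[i]]] <- params$reporter_level * stats::runif(1, 0.85, 1.1)
    }
    if (params$n_background_blobs > 0) {
      bb <- place_blobs(
        params$n_background_blobs,
        function() c(1, 2, 2) * stats::runif(1, 0.8, 1.2),
        d, term$occupied,
        what = "background blob"
      )
      for (v in bb$voxels) reporter[v] <- 0.3
    }
    dapi <- array(0, dim = d)
    for (v in nuc$voxels) dapi[v] <- 0.85

    tissue_ext <- tissue_extent_mask(params, d)
    terminal_mask <- array(FALSE, dim = d)
    terminal_mask[unlist(term$voxels)] <- TRUE
    nuclear_mask <- array(FALSE, dim = d)
    for (v in nuc$voxels) nuclear_mask[v] <- TRUE
    outside_idx <- which(!terminal_mask & !nuclear_mask & tissue_ext)

    puncta <- list()
    ab_channels <- list()
    for (ch_name in names(params$channels)) {
      ch <- params$channels[[ch_name]]
      eligible <- if (isTRUE(ch$dual_only)) {
        which(classes == "GABA_and_ACh")
      } else {
        seq_len(params$n_terminals)
      }
      rows <- list()
      for (i in eligible) {
        vox <- term$voxels[[i]]
        k <- stats::rpois(1, ch$inside_rate * length(vox))
        if (k > 0) {
          at <- sample(vox, k, replace = TRUE)
          rows[[length(rows) + 1L]] <- cbind(at, i)
        }
      }
      k_out <- stats::rpois(1, ch$outside_rate * length(outside_idx))
      if (k_out > 0) {
        at <- sample(outside_idx, k_out, replace = TRUE)
        rows[[length(rows) + 1L]] <- cbind(at, NA_integer_)
      }
      img <- array(0, dim = d)
      if (length(rows) > 0) {
        m <- do.call(rbind, rows)
        co <- arrayInd(m[, 1], d)
        for (j in seq_len(nrow(m))) {
          img <- paint_spot(
            img, co[j, ], stats::runif(1, 0.55, 0.85),
            params$psf_sd, params$psf_sd_z
          )
        }
        puncta[[ch_name]] <- tibble::tibble(
          channel = ch_name,
          z = co[, 1], y = co[, 2], x = co[, 3],
          parent = m[, 2]
        )
      } else {
        puncta[[ch_name]] <- tibble::tibble(
          channel = character(), z = integer(), y = integer(), x = integer(),
          parent = integer()
        )
      }
      ab_channels[[ch_name]] <- img
    }

    noisy <- function(img, base = 0) {
      out <- img + base * tissue_ext + stats::rnorm(length(img), 0, params$noise_sd)
      pmin(pmax(out, 0), 1)
    }
    channels <- c(
      list(
        YFP = noisy(reporter),
        DAPI = noisy(dapi)
      ),
      lapply(ab_channels, noisy, base = params$background_level)
    )
    roles <- channel_roles(
      names(channels),
      c("terminal_reporter", "nuclear", rep("antibody", length(ab_channels)))
    )
    stack <- volume_stack(channels, roles = roles, voxel_size_nm = c(70, 100, 100))
    nuc_cent <- if (length(nuc$centers) > 0) do.call(rbind, nuc$centers) else
      matrix(numeric(0), ncol = 3)
    structure(
      list(
        stack = stack,
        truth_terminals = truth_terminals,
        truth_puncta = dplyr::bind_rows(puncta),
        truth_nuclei = tibble::tibble(
          id = seq_len(nrow(nuc_cent)),
          z = nuc_cent[, 1], y = nuc_cent[, 2], x = nuc_cent[, 3]
        ),
        params = params
      ),
      class = "synthetic_scene"
    )
  })
}

#' Generate a synthetic confocal terminal scene
#'
#' Reporter-labeled terminals whose per-terminal mean VGAT-like and VAChT-like
#' intensities follow a two-component mixture: dual terminals draw from a
#' bivariate normal with correlation `rho`; GABA-only terminals draw VGAT-like
#' intensity from the same marginal but VAChT-like intensity at background
#' level. Intensities are painted over terminal voxels and Gaussian noise is
#' added.
#'
#' @inheritParams generate_array_tomography_scene
#' @return A `synthetic_scene`; `truth_terminals` carries `vgat_true` and
#'   `vacht_true` per-terminal intensities and the terminal class.
#' @export
generate_confocal_terminal_scene <- function(params = scene_params(), seed = 1L) {
  stopifnot(inherits(params, "scene_params"))
  d <- as.integer(params$shape)
  withr::with_seed(as.integer(seed), {
    occupied <- array(FALSE, dim = d)
    term <- place_terminals(params, d, occupied)
    n <- params$n_terminals
    classes <- ifelse(
      stats::runif(n) < params$fraction_dual, "GABA_and_ACh", "GABA_only"
    )
    mu <- params$intensity_mean
    sd <- params$intensity_sd
    rho <- params$rho
    z1 <- stats::rnorm(n)
    z2 <- rho * z1 + sqrt(1 - rho^2) * stats::rnorm(n)
    vgat <- mu[1] + sd[1] * z1
    vacht <- mu[2] + sd[2] * z2
    bg_i <- classes == "GABA_only"
    # GABA-only terminals carry no VAChT above the diffuse background
    vacht[bg_i] <- pmax(stats::rnorm(sum(bg_i), 0, 0.01), 0)
    vgat <- pmin(pmax(vgat, 0.02), 1)
    vacht <- pmin(pmax(vacht, 0), 1)

    reporter <- array(0, dim = d)
    vgat_img <- array(0, dim = d)
    vacht_img <- array(0, dim = d)
    for (i in seq_len(n)) {
      vox <- term$voxels[[i]]
      reporter[vox] <- params$reporter_level * stats::runif(1, 0.85, 1.1)
      vgat_img[vox] <- vgat[i]
      vacht_img[vox] <- vacht[i]
    }
    # off-target structures avoid the reporter-labeled terminals but may
    # overlap one another, as dense neuropil does
    for (spec_off in list(
      list(n = params$n_offtarget_vacht, img = "vacht"),
      list(n = params$n_offtarget_vgat, img = "vgat")
    )) {
      if (spec_off$n < 1) next
      off <- place_blobs(
        spec_off$n,
        function() {
          c(
            max(1.0, params$terminal_radius_z * stats::runif(1, 0.8, 1.3)),
            params$terminal_radius_xy * stats::runif(1, 0.75, 1.3),
            params$terminal_radius_xy * stats::runif(1, 0.75, 1.3)
          )
        },
        d, term$occupied,
        margin = 2 + params$border_px,
        what = paste("off-target", spec_off$img, "terminal"),
        halo = 1
      )
      for (v in off$voxels) {
        val <- pmin(pmax(stats::rnorm(1, mu[2], sd[2]), 0), 1)
        if (spec_off$img == "vacht") vacht_img[v] <- val else vgat_img[v] <- val
      }
    }
    tissue_ext <- tissue_extent_mask(params, d)
    noisy <- function(img, base) {
      out <- img + base * tissue_ext + stats::rnorm(length(img), 0, params$noise_sd)
      pmin(pmax(out, 0), 1)
    }
    channels <- list(
      mCherry = noisy(reporter, 0),
      VGAT = noisy(vgat_img, params$background_level),
      VAChT = noisy(vacht_img, params$background_level)
    )
    roles <- channel_roles(
      names(channels), c("terminal_reporter", "antibody", "antibody")
    )
    truth <- truth_terminal_table(term, classes, d)
    truth$vgat_true <- vgat
    truth$vacht_true <- vacht
    structure(
      list(
        stack = volume_stack(channels, roles = roles, voxel_size_nm = c(300, 100, 100)),
        truth_terminals = truth,
        truth_puncta = NULL,
        params = params
      ),
      class = "synthetic_scene"
    )
  })
}

#' Generate a synthetic FISH scene
#'
#' Disjoint round cells on a dark background; each probe channel paints
#' small transcript dots (5-pixel clusters) inside cells, at a density giving
#' roughly `coverage_pos` pixel coverage in positive cells and
#' `coverage_neg` in negative cells, plus sparse single-pixel background
#' dots. The joint positivity pattern of each cell is drawn from
#' `params$pattern_probs`.
#' Ten cell-free background rectangles are returned for threshold derivation.
#'
#' @inheritParams generate_array_tomography_scene
#' @return A `synthetic_scene` with `truth_cells` (per-cell true positivity
#'   per probe) and `background_rois`.
#' @export
generate_fish_scene <- function(params = scene_params(
                                  shape = c(1, 256, 256), n_cells = 40
                                ),
                                seed = 1L) {
  stopifnot(inherits(params, "scene_params"), params$n_cells >= 1)
  d <- as.integer(params$shape)
  probs <- params$pattern_probs / sum(params$pattern_probs)
  pat_names <- names(probs)
  n_probes <- length(params$probes)
  stopifnot(all(nchar(pat_names) == n_probes))
  withr::with_seed(as.integer(seed), {
    occupied <- array(FALSE, dim = d)
    cells <- tryCatch(
      place_blobs(
        params$n_cells,
        function() {
          r <- params$cell_radius * stats::runif(1, 0.8, 1.2)
          c(0.6, r, r)
        },
        d, occupied,
        margin = 3, what = "cell", halo = 4
      ),
      error = function(e) stop("overlapping-cell placement failure: ",
        conditionMessage(e),
        call. = FALSE
      )
    )
    pattern <- sample(pat_names, params$n_cells, replace = TRUE, prob = probs)
    pos <- do.call(rbind, lapply(strsplit(pattern, ""), function(s) s == "+"))
    colnames(pos) <- params$probes

    cell_mask <- array(FALSE, dim = d)
    for (v in cells$voxels) cell_mask[v] <- TRUE
    bg_idx <- which(!cell_mask)

    # 3x3 transcript dots; diffraction blur softens their edges
    dot_offsets <- as.matrix(expand.grid(dy = -1:1, dx = -1:1))
    paint_dots <- function(img, at_idx, rate) {
      n_dots <- stats::rpois(1, length(at_idx) * rate / 9)
      if (n_dots > 0) {
        centers <- arrayInd(sample(at_idx, n_dots, replace = TRUE), d)
        amps <- stats::runif(n_dots, 0.45, 0.95)
        for (k in seq_len(n_dots)) {
          py <- centers[k, 2] + dot_offsets[, "dy"]
          px <- centers[k, 3] + dot_offsets[, "dx"]
          ok <- py >= 1 & py <= d[2] & px >= 1 & px <= d[3]
          img[cbind(1L, py[ok], px[ok])] <- pmax(
            img[cbind(1L, py[ok], px[ok])], amps[k]
          )
        }
      }
      img
    }
    channels <- list()
    for (pi in seq_len(n_probes)) {
      img <- array(0, dim = d)
      for (ci in seq_len(params$n_cells)) {
        vox <- cells$voxels[[ci]]
        if (pos[ci, pi]) {
          img[vox] <- params$diffuse_level
          img <- paint_dots(img, vox, params$coverage_pos)
        } else {
          img <- paint_dots(img, vox, params$coverage_neg)
        }
      }
      if (params$background_dot_rate > 0) {
        img <- paint_dots(img, bg_idx, params$background_dot_rate)
      }
      img <- blur_plane(img)
      img <- pmin(pmax(img + stats::rnorm(length(img), 0.03, 0.015), 0), 1)
      channels[[params$probes[pi]]] <- img
    }
    roles <- channel_roles(names(channels), "fish_probe")
    cent <- do.call(rbind, cells$centers)
    truth_cells <- tibble::tibble(
      id = seq_len(params$n_cells),
      y = cent[, 2], x = cent[, 3],
      n_pixels = vapply(cells$voxels, length, integer(1)),
      voxels = cells$voxels
    )
    for (pi in seq_len(n_probes)) {
      truth_cells[[paste0("pos_", params$probes[pi])]] <- pos[, pi]
    }
    # ten cell-free rectangles (cell-sized) for background coverage
    rois <- list()
    guard <- dilate_ball(cell_mask, 2L)
    tries <- 0
    while (length(rois) < 10 && tries < 4000) {
      tries <- tries + 1
      h <- 17L
      y0 <- sample.int(d[2] - h, 1)
      x0 <- sample.int(d[3] - h, 1)
      if (!any(guard[1, y0:(y0 + h - 1L), x0:(x0 + h - 1L)])) {
        rois[[length(rois) + 1L]] <- c(y0 = y0, y1 = y0 + h - 1L, x0 = x0, x1 = x0 + h - 1L)
      }
    }
    structure(
      list(
        stack = volume_stack(channels, roles = roles, voxel_size_nm = c(1000, 200, 200)),
        truth_cells = truth_cells,
        background_rois = tibble::as_tibble(do.call(rbind, rois)),
        params = params
      ),
      class = "synthetic_scene"
    )
  })
}

#' Simulate a connectivity survey
#'
#' Draws, for each recorded group, a multinomial sample of per-cell synaptic
#' response categories (GABA_A R response, nAChR response, both, or none).
#'
#' @param proportions Named list (one element per group) of named response
#'   probabilities, e.g. `list(mPFC = c(nAChR = 20/131, GABA_A_R = 9/131))`;
#'   the remainder of each group is "none".
#' @param n_cells Named integer vector of group sizes (same names).
#' @param seed Integer seed.
#' @return A tibble with columns `group`, `response`, `n` (counts).
#' @export
generate_connectivity_survey <- function(proportions, n_cells, seed = 1L) {
  stopifnot(length(proportions) == length(n_cells))
  groups <- names(proportions)
  stopifnot(!is.null(groups), identical(sort(groups), sort(names(n_cells))))
  withr::with_seed(as.integer(seed), {
    out <- lapply(groups, function(g) {
      p <- proportions[[g]]
      stopifnot(all(p >= 0), sum(p) <= 1 + 1e-12)
      n <- n_cells[[g]]
      stopifnot(n >= 0)
      pr <- c(p, none = max(0, 1 - sum(p)))
      counts <- as.integer(stats::rmultinom(1, n, pr))
      tibble::tibble(group = g, response = names(pr), n = counts)
    })
    dplyr::bind_rows(out)
  })
}
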