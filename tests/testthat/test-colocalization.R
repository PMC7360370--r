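test_that("puncta candidate detection: blank images and resolvable twin peaks", {
  expect_length(detect_puncta_candidates(array(0.01, c(2, 16, 16)))$regions, 0)

  arr <- array(0, c(1, 24, 24))
  arr <- synaptoquant:::paint_spot(arr, c(1, 12, 9), 1.0, 0.8, 0.5)
  arr <- synaptoquant:::paint_spot(arr, c(1, 12, 11), 0.9, 0.8, 0.5)
  cand <- detect_puncta_candidates(arr, k = 2)
  expect_equal(length(cand$regions), 2)
  # oracle: exhaustive strict local-maximum scan above the same threshold
  expect_setequal(cand$peaks$index, local_max_oracle(arr, cand$threshold))
})

test_that("candidate counts track truth at high SNR", {
  p <- scene_params(
    shape = c(6, 128, 128), n_terminals = 10, n_nuclei = 1, nucleus_radius = 8,
    channels = list(
      sparse = list(inside_rate = 0, outside_rate = 3.5e-4, dual_only = FALSE)
    ),
    noise_sd = 0.01
  )
  scene <- generate_array_tomography_scene(p, seed = 21)
  st <- normalize_stack(scene$stack)
  m_truth <- nrow(scene$truth_puncta)
  cand <- detect_puncta_candidates(get_channel(st, "sparse"), k = 2)
  expect_lt(abs(length(cand$regions) - m_truth) / m_truth, 0.1)
})

test_that("Gaussian peak fitting localizes puncta to the nearest voxel", {
  d <- c(3, 32, 40)
  on_voxel <- synaptoquant:::paint_spot(array(0, d), c(2, 15, 22), 1, 1.5, 0.5)
  reg <- which(on_voxel > 0.05)
  fit <- fit_punctum_peak(on_voxel, reg)
  expect_true(fit$fit_ok)
  expect_equal(c(fit$z, fit$y, fit$x), c(2, 15, 22))

  off <- array(0, d)
  yy <- matrix(rep(1:d[2], d[3]), d[2])
  xx <- matrix(rep(1:d[3], each = d[2]), d[2])
  off[2, , ] <- exp(-((yy - 10.4)^2 + (xx - 20.6)^2) / (2 * 1.5^2))
  reg2 <- which(off > 0.05)
  fit2 <- fit_punctum_peak(off, reg2)
  expect_true(fit2$fit_ok)
  expect_equal(c(fit2$y, fit2$x), c(10, 21))

  speck <- array(0, d)
  speck[2, 5, 5] <- 0.5
  speck[2, 5, 6] <- 0.9
  speck[2, 5, 7] <- 0.4
  fit3 <- fit_punctum_peak(speck, which(speck > 0))
  expect_false(fit3$fit_ok)
  expect_equal(c(fit3$z, fit3$y, fit3$x), c(2, 5, 6))
})

test_that("colocalization density equals the brute-force membership count", {
  d <- c(4, 20, 20)
  mask <- array(FALSE, d)
  mask[1:2, 1:10, 1:5] <- TRUE
  expect_equal(coloc_density(tibble::tibble(z = integer(), y = integer(),
    x = integer()), mask), 0)

  # arithmetic contract: 50 of 50 puncta inside a 1000-voxel mask
  mask2 <- array(FALSE, c(10, 10, 10))
  mask2[1:10, 1:10, 1:10] <- TRUE
  pts <- tibble::tibble(
    z = sample(1:10, 50, TRUE), y = sample(1:10, 50, TRUE),
    x = sample(1:10, 50, TRUE)
  )
  expect_equal(coloc_density(pts, mask2), 0.05)

  set.seed(33)
  d3 <- c(6, 30, 30)
  mask3 <- array(runif(prod(d3)) < 0.2, d3)
  pts3 <- tibble::tibble(
    z = sample(1:6, 80, TRUE), y = sample(1:30, 80, TRUE),
    x = sample(1:30, 80, TRUE)
  )
  inside <- 0
  for (i in 1:80) inside <- inside + as.integer(mask3[pts3$z[i], pts3$y[i], pts3$x[i]])
  expect_equal(coloc_density(pts3, mask3), inside / sum(mask3))
  expect_error(coloc_density(pts3, array(FALSE, d3)), "empty mask")
})

test_that("shell masks match a brute-force dilation oracle", {
  d <- c(7, 9, 9)
  mask <- array(FALSE, d)
  mask[4, 5, 5] <- TRUE
  shells <- shell_masks(mask, n_shells = 2)
  oracle1 <- dilate_oracle(mask) & !mask
  expect_identical(shells[["1"]], oracle1)
  expect_equal(sum(shells[["1"]]), 26)
  oracle2 <- dilate_oracle(dilate_oracle(mask)) & !dilate_oracle(mask)
  expect_identical(shells[["2"]], oracle2)
})

test_that("shell profiles behave for interior-only and uniform puncta", {
  d <- c(6, 40, 40)
  mask <- array(FALSE, d)
  mask[2:4, 15:25, 15:25] <- TRUE
  inside_pts <- index_to_coords_df(which(mask)[1:30], d)
  prof <- shell_profile(inside_pts, mask, n_shells = 3)
  expect_equal(prof$density[prof$shell > 0], c(0, 0, 0))

  set.seed(44)
  n <- 4000
  pts <- tibble::tibble(
    z = sample(1:6, n, TRUE), y = sample(1:40, n, TRUE),
    x = sample(1:40, n, TRUE)
  )
  prof2 <- shell_profile(pts, mask, n_shells = 4)
  rate <- n / prod(d)
  for (k in 0:4) {
    row <- prof2[prof2$shell == k, ]
    se <- sqrt(rate * (1 - rate) / row$n_voxels)
    expect_lt(abs(row$density - rate), 4 * se)
  }
})

test_that("randomized nulls are seeded, uniform, and have the closed-form mean", {
  d <- c(6, 40, 40)
  allowed <- array(TRUE, d)
  mask <- array(FALSE, d)
  mask[2:4, 10:20, 10:20] <- TRUE
  n_pts <- 120
  nul <- randomized_null(n_pts, allowed, mask, n_randomizations = 400, seed = 5)
  nul2 <- randomized_null(n_pts, allowed, mask, n_randomizations = 400, seed = 5)
  expect_identical(nul$null_density, nul2$null_density)
  # uniform relocation: E[density] = n_pts / allowed voxels
  expected <- n_pts / sum(allowed)
  se <- sd(nul$null_density) / sqrt(length(nul$null_density))
  expect_lt(abs(mean(nul$null_density) - expected), 3 * se)
  expect_error(
    coloc_zscore(0.5, randomized_null(n_pts, allowed, mask, 1, seed = 1)$null_density),
    "at least 2"
  )
})

test_that("z-scores follow the subtract-mean-over-sd rule", {
  expect_equal(coloc_zscore(3, c(1, 2, 3, 4, 5)), 0)
  expect_equal(coloc_zscore(6, c(1, 2, 3, 4, 5)), 3 / sqrt(2.5))
  expect_error(coloc_zscore(1, c(2, 2, 2)), "zero null spread")
})

test_that("enrichment z-scores rise with the inside/outside rate ratio", {
  z_for_ratio <- function(inside_rate, seed) {
    p <- scene_params(
      shape = c(6, 96, 96), n_terminals = 20, n_nuclei = 1, nucleus_radius = 8,
      channels = list(
        probe = list(inside_rate = inside_rate, outside_rate = 4e-4,
          dual_only = FALSE)
      )
    )
    scene <- generate_array_tomography_scene(p, seed = seed)
    fe <- run_imaging_front_end(scene)
    res <- coloc_analysis(
      fe$stack, mask_from_terminals(fe$terminals), fe$masks,
      channels = "probe", n_randomizations = 150, seed = seed
    )
    res$summary$z_score
  }
  for (seed in 1:3) {
    ladder <- c(
      z_for_ratio(4e-4, seed), # ratio 1: no enrichment
      z_for_ratio(8e-3, seed),
      z_for_ratio(4e-2, seed)
    )
    expect_true(all(diff(ladder) > 0))
    expect_lt(abs(ladder[1]), 4)
    expect_gt(ladder[3], 5)
  }
})
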