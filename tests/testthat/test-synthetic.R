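test_that("scene generation is deterministic in (params, seed)", {
  p <- scene_params(shape = c(4, 64, 64), n_terminals = 6, n_nuclei = 1,
    nucleus_radius = 7)
  a <- generate_array_tomography_scene(p, seed = 5)
  b <- generate_array_tomography_scene(p, seed = 5)
  c <- generate_array_tomography_scene(p, seed = 6)
  expect_identical(a$stack$channels, b$stack$channels)
  expect_identical(a$truth_puncta, b$truth_puncta)
  expect_false(identical(a$stack$channels$YFP, c$stack$channels$YFP))
})

test_that("puncta placement rates match the configured binomial expectations", {
  scene <- small_at_scene(seed = 7)
  p <- scene$params
  truth <- scene$truth_terminals
  dual_vox <- sum(truth$n_voxels[truth$class == "GABA_and_ACh"])
  outside_vox <- prod(p$shape) - sum(truth$n_voxels) -
    sum(scene$stack$channels$DAPI > 0.5) # nuclei are excluded from placement
  # oracle: count truth puncta with a parent terminal, directly from the lists
  vacht <- scene$truth_puncta[scene$truth_puncta$channel == "VAChT", ]
  n_in <- sum(!is.na(vacht$parent))
  exp_in <- p$channels$VAChT$inside_rate * dual_vox
  exp_out <- p$channels$VAChT$outside_rate * outside_vox
  frac_expected <- exp_in / (exp_in + exp_out)
  frac_obs <- n_in / nrow(vacht)
  se <- sqrt(frac_expected * (1 - frac_expected) / nrow(vacht))
  expect_lt(abs(frac_obs - frac_expected), 3 * se)

  # point-in-mask oracle agrees with the recorded parent assignments
  mask <- array(FALSE, dim = p$shape)
  mask[unlist(truth$voxels)] <- TRUE
  idx <- coords_to_index_oracle(vacht$z, vacht$y, vacht$x, p$shape)
  expect_equal(sum(mask[idx]), n_in)
})

test_that("fraction_dual = 0 leaves the ACh-like channel without terminal parents", {
  p <- scene_params(shape = c(4, 96, 96), n_terminals = 15, fraction_dual = 0,
    n_nuclei = 1, nucleus_radius = 7)
  scene <- generate_array_tomography_scene(p, seed = 2)
  vacht <- scene$truth_puncta[scene$truth_puncta$channel == "VAChT", ]
  expect_true(all(is.na(vacht$parent)))
})

test_that("equal inside/outside rates give spatially uniform puncta", {
  p <- scene_params(
    shape = c(6, 128, 128), n_terminals = 30, n_nuclei = 1, nucleus_radius = 8,
    channels = list(
      unif = list(inside_rate = 8e-4, outside_rate = 8e-4, dual_only = FALSE)
    )
  )
  scene <- generate_array_tomography_scene(p, seed = 9)
  truth <- scene$truth_terminals
  term_vox <- sum(truth$n_voxels)
  pu <- scene$truth_puncta
  share <- term_vox / (prod(p$shape)) # nuclei are a small correction
  frac_in <- mean(!is.na(pu$parent))
  se <- sqrt(share * (1 - share) / nrow(pu))
  expect_lt(abs(frac_in - share), 4 * se + 0.01)
})

test_that("confocal intensity mixture honours rho and fraction_dual", {
  p0 <- scene_params(shape = c(10, 320, 320), n_terminals = 500,
    fraction_dual = 1, rho = 0)
  s0 <- generate_confocal_terminal_scene(p0, seed = 3)
  r <- cor(s0$truth_terminals$vgat_true, s0$truth_terminals$vacht_true)
  expect_lt(abs(r), 0.15)

  s1 <- confocal_500(seed = 1)
  n_dual <- sum(s1$truth_terminals$class == "GABA_and_ACh")
  expect_lt(abs(n_dual - 0.75 * 500), 3 * sqrt(500 * 0.75 * 0.25))
})

test_that("a single-terminal confocal scene still classifies", {
  p <- scene_params(shape = c(4, 64, 64), n_terminals = 1, fraction_dual = 1,
    n_offtarget_vacht = 3)
  s <- generate_confocal_terminal_scene(p, seed = 1)
  cp <- classify_pipeline(s$stack)
  expect_equal(nrow(cp$class_table), nrow(cp$terminal_set$terminals))
  expect_equal(sum(quadrant_counts(cp$class_table)$n), nrow(cp$class_table))
})

test_that("FISH truth co-expression follows the configured pattern matrix", {
  p <- scene_params(
    shape = c(1, 384, 384), n_cells = 60, cell_radius = 9,
    probes = c("A", "B", "C"),
    pattern_probs = c(
      "+++" = 0.4, "++-" = 0.2, "+--" = 0.2, "-+-" = 0.1, "---" = 0.1
    )
  )
  s <- generate_fish_scene(p, seed = 4)
  tc <- s$truth_cells
  # pairwise truth proportions vs configuration, 3 binomial sds
  p_ab <- 0.4 + 0.2
  obs <- mean(tc$pos_A & tc$pos_B)
  expect_lt(abs(obs - p_ab), 3 * sqrt(p_ab * (1 - p_ab) / 60))
  p_ac <- 0.4
  obs_ac <- mean(tc$pos_A & tc$pos_C)
  expect_lt(abs(obs_ac - p_ac), 3 * sqrt(p_ac * (1 - p_ac) / 60))
})

test_that("disjoint probe patterns give zero truth co-expression", {
  p <- scene_params(
    shape = c(1, 192, 192), n_cells = 20, cell_radius = 9,
    probes = c("A", "B"),
    pattern_probs = c("+-" = 1)
  )
  s <- generate_fish_scene(p, seed = 1)
  expect_true(all(s$truth_cells$pos_A))
  expect_false(any(s$truth_cells$pos_B))
})

test_that("connectivity surveys obey degenerate and large-sample behaviour", {
  all_none <- generate_connectivity_survey(
    list(g = c(GABA_A_R = 0, nAChR = 0)), c(g = 25), seed = 1
  )
  expect_equal(all_none$n[all_none$response == "none"], 25L)

  one <- generate_connectivity_survey(
    list(g = c(nAChR = 0.5)), c(g = 10), seed = 2
  )
  expect_true(all(one$n >= 0 & one$n <= 10))
  expect_equal(sum(one$n), 10L)

  # law of large numbers: mean simulated nAChR counts approach (20, 1)
  props <- list(mPFC = c(nAChR = 20 / 131), M1 = c(nAChR = 1 / 43))
  sizes <- c(mPFC = 131, M1 = 43)
  counts <- vapply(1:1000, function(s) {
    out <- generate_connectivity_survey(props, sizes, seed = s)
    c(
      out$n[out$group == "mPFC" & out$response == "nAChR"],
      out$n[out$group == "M1" & out$response == "nAChR"]
    )
  }, numeric(2))
  expect_lt(abs(mean(counts[1, ]) - 20), 3 * sqrt(131 * (20 / 131) * (111 / 131) / 1000))
  expect_lt(abs(mean(counts[2, ]) - 1), 3 * sqrt(43 * (1 / 43) * (42 / 43) / 1000))
})

test_that("infeasible placement is reported, not silently truncated", {
  p <- scene_params(shape = c(4, 64, 64), n_terminals = 5000)
  expect_error(generate_array_tomography_scene(p, seed = 1), "infeasible")
})
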