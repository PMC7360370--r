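fish_params_no_silent <- function(n_cells = 30) {
  scene_params(
    shape = c(1, 256, 256), n_cells = n_cells, cell_radius = 10,
    probes = c("Chat", "Cre"),
    pattern_probs = c("++" = 0.6, "+-" = 0.2, "-+" = 0.2)
  )
}

component_centroids <- function(labels) {
  idx <- which(labels > 0)
  ids <- labels[idx]
  co <- arrayInd(idx, dim(labels))
  tibble::tibble(
    id = as.integer(names(tapply(co[, 1], ids, mean))),
    y = as.numeric(tapply(co[, 1], ids, mean)),
    x = as.numeric(tapply(co[, 2], ids, mean))
  )
}

# nearest detected component per truth cell (0 = no component nearby)
match_truth_cells <- function(labels, truth, max_dist) {
  cc <- component_centroids(labels)
  vapply(seq_len(nrow(truth)), function(i) {
    if (nrow(cc) == 0) return(0L)
    dd <- (cc$y - truth$y[i])^2 + (cc$x - truth$x[i])^2
    j <- which.min(dd)
    if (dd[j] <= max_dist^2) cc$id[j] else 0L
  }, integer(1))
}

test_that("cell masks recover generated cells one-to-one", {
  blank <- list(matrix(0.01, 64, 64), matrix(0.01, 64, 64))
  cm0 <- build_cell_mask(blank)
  expect_false(any(cm0$mask))

  scene <- cached("fish30", generate_fish_scene(fish_params_no_silent(), seed = 1))
  cm <- build_cell_mask(scene$stack)
  expect_equal(max(cm$labels), nrow(scene$truth_cells))
  matches <- match_truth_cells(cm$labels, scene$truth_cells, max_dist = 8)
  expect_true(all(matches > 0))
  expect_false(anyDuplicated(matches) > 0) # one component per cell

  # a silent probe does not break the sum rule
  probes <- lapply(
    channels_with_role(scene$stack, "fish_probe"),
    function(ch) get_channel(scene$stack, ch)
  )
  probes[[2]] <- array(0.01, dim(scene$stack))
  cm_partial <- build_cell_mask(probes)
  expect_gt(max(cm_partial$labels), 0)
})

test_that("percent coverage counts probe pixels exactly", {
  lab <- matrix(0L, 20, 20)
  lab[3:16, 4:14] <- 1L # one cell
  n_cell <- sum(lab == 1L) # 14 x 11 = 154 pixels; trim to 148
  lab[3, 4:9] <- 0L
  expect_equal(sum(lab == 1L), 148)
  probe <- matrix(0, 20, 20)
  idx <- which(lab == 1L)[1:37]
  probe[idx] <- 1
  cov <- cell_coverage(lab, probe, probe_threshold = 0.5)
  expect_equal(cov$coverage, 100 * 37 / 148)
  expect_equal(cov$coverage, 25.0)

  full <- matrix(1, 20, 20)
  expect_equal(cell_coverage(lab, full, 0.5)$coverage, 100)
  expect_equal(cell_coverage(lab, matrix(0, 20, 20), 0.5)$coverage, 0)
})

test_that("coverage is additive under cell splitting", {
  lab <- matrix(0L, 30, 30)
  lab[5:20, 5:20] <- 1L
  set.seed(9)
  probe <- matrix(as.numeric(matrix(runif(900), 30, 30) < 0.3), 30, 30)
  whole <- cell_coverage(lab, probe, 0.5)
  split <- lab
  split[5:20, 13:20] <- 2L
  parts <- cell_coverage(split, probe, 0.5)
  whole_pos <- whole$coverage * whole$n_pixels / 100
  parts_pos <- sum(parts$coverage * parts$n_pixels / 100)
  expect_equal(whole_pos, parts_pos)
})

test_that("positivity thresholds implement the above-background rule", {
  expect_equal(positivity_threshold(c(1.2, 0.8, 2.1, 0.5)), 2.1)
  expect_equal(positivity_threshold(rep(0, 10)), 0)
  expect_true(0.1 > positivity_threshold(rep(0, 10))) # any nonzero is positive
  expect_equal(
    positivity_threshold(c(1, 2, 3), method = "mean_2sd"), 2 + 2 * 1
  )
})

test_that("per-cell calls recover truth with >= 95% accuracy across seeds", {
  ok <- 0L
  n <- 0L
  for (seed in 1:5) {
    scene <- generate_fish_scene(fish_params_no_silent(), seed = seed)
    ct <- score_fish(scene$stack, scene$background_rois)
    cm_labels <- attr(ct, "cell_labels")
    truth <- scene$truth_cells
    matches <- match_truth_cells(cm_labels, truth, max_dist = 8)
    for (i in seq_len(nrow(truth))) {
      if (matches[i] == 0) next
      row <- ct[ct$id == matches[i], ]
      n <- n + 2L
      ok <- ok + (row$pos_Chat == truth$pos_Chat[i]) +
        (row$pos_Cre == truth$pos_Cre[i])
    }
  }
  expect_gte(ok / n, 0.95)
})

test_that("zero background dot rate yields zero background coverage", {
  p <- scene_params(
    shape = c(1, 192, 192), n_cells = 10, cell_radius = 9,
    probes = c("A", "B"), pattern_probs = c("++" = 1),
    background_dot_rate = 0
  )
  scene <- generate_fish_scene(p, seed = 3)
  img <- get_channel(scene$stack, "A")
  # at any threshold above the noise floor there are no dots to find outside
  # cells: the painted background is exactly empty
  bg <- background_coverage(scene$background_rois, img, probe_threshold = 0.4)
  expect_equal(bg, rep(0, length(bg)))
})

test_that("co-expression tables report joint patterns and integer percents", {
  ct <- tibble::tibble(
    id = 1:33,
    pos_Chat = rep(TRUE, 33),
    pos_Cre = c(rep(TRUE, 32), FALSE)
  )
  cx <- coexpression_table(ct, probes = c("Chat", "Cre"))
  chat_row <- cx$pairs[cx$pairs$denominator == "Chat", ]
  cre_row <- cx$pairs[cx$pairs$denominator == "Cre", ]
  expect_equal(chat_row$percent, 97)
  expect_equal(cre_row$percent, 100)
  expect_equal(sum(cx$patterns$n), 33)

  empty <- coexpression_table(ct[0, ], probes = c("Chat", "Cre"))
  expect_equal(nrow(empty$pairs), 0)
})
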