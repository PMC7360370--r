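test_that("response amplitudes use a 990 ms baseline and signed extremum", {
  t <- seq(0, 1100, by = 0.1) # 10 kHz sampling
  onset <- 1000
  flat <- tibble::tibble(
    time_ms = rep(t, 2), sweep = rep(1:2, each = length(t)), value = 0
  )
  expect_equal(response_amplitude(flat, onset)$amplitude, 0)

  # synthetic inward PSC: -120 pA peak exactly 9 ms after stimulation
  bump <- -120 * exp(-((t - onset - 9)^2) / (2 * 2^2))
  psc <- tibble::tibble(time_ms = t, sweep = 1L, value = bump)
  amp <- response_amplitude(psc, onset)
  expect_equal(amp$amplitude, -120, tolerance = 1e-6)
  expect_equal(amp$peak_time_ms, onset + 9)

  # averaging happens before the extremum
  pm <- tibble::tibble(
    time_ms = rep(t, 2), sweep = rep(1:2, each = length(t)),
    value = rep(c(10, -10), each = length(t))
  )
  expect_equal(response_amplitude(pm, onset)$amplitude, 0)
  expect_error(response_amplitude(psc, onset_ms = 2000), "outside")
})

test_that("Fisher exact handles degenerate margins and matches references", {
  expect_equal(fisher_exact_2x2(matrix(c(0, 10, 0, 12), 2, byrow = TRUE))$p_value, 1)

  printed <- matrix(c(20, 111, 1, 42), 2, byrow = TRUE)
  p <- fisher_exact_2x2(printed)$p_value
  expect_equal(p, stats::fisher.test(printed)$p.value, tolerance = 1e-12)

  gaba <- matrix(c(9, 122, 13, 30), 2, byrow = TRUE)
  expect_equal(
    fisher_exact_2x2(gaba)$p_value,
    stats::fisher.test(gaba)$p.value,
    tolerance = 1e-12
  )
})

test_that("Fisher p equals exhaustive enumeration for all tables with N <= 60", {
  set.seed(20)
  for (i in 1:60) {
    n <- sample(8:60, 1)
    a <- sample(0:min(n, 12), 1)
    b <- sample(0:(min(n - a, 12)), 1)
    cc <- sample(0:max(0, min(n - a - b, 12)), 1)
    dd <- n - a - b - cc
    if (dd < 0) next
    tab <- matrix(c(a, b, cc, dd), 2, byrow = TRUE)
    expect_equal(
      fisher_exact_2x2(tab)$p_value, fisher_enum_oracle(tab),
      tolerance = 1e-10
    )
  }
})

test_that("Fisher p is invariant under transposition and row/column swaps", {
  set.seed(21)
  for (i in 1:20) {
    tab <- matrix(sample(0:15, 4, TRUE), 2)
    p <- fisher_exact_2x2(tab)$p_value
    expect_equal(fisher_exact_2x2(t(tab))$p_value, p, tolerance = 1e-12)
    expect_equal(fisher_exact_2x2(tab[2:1, ])$p_value, p, tolerance = 1e-12)
    expect_equal(fisher_exact_2x2(tab[, 2:1])$p_value, p, tolerance = 1e-12)
  }
})

test_that("the exact test is conservative under the multinomial null", {
  set.seed(22)
  rejections <- vapply(1:2000, function(i) {
    g1 <- rbinom(1, 30, 0.3)
    g2 <- rbinom(1, 30, 0.3)
    tab <- matrix(c(g1, 30 - g1, g2, 30 - g2), 2, byrow = TRUE)
    fisher_exact_2x2(tab)$p_value < 0.05
  }, logical(1))
  expect_lte(mean(rejections), 0.05)
})

test_that("Pearson chi-squared matches the closed form and is calibrated", {
  same <- matrix(c(10, 20, 10, 20), 2, byrow = TRUE)
  res <- pearson_chisq(same)
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1)

  worked <- matrix(c(10, 20, 20, 10), 2, byrow = TRUE)
  # all expected counts are 15: statistic = 4 * 25 / 15 = 20/3
  res2 <- pearson_chisq(worked)
  expect_equal(res2$statistic, 20 / 3, tolerance = 1e-12)
  expect_equal(res2$df, 1)
  expect_equal(res2$p_value, stats::pchisq(20 / 3, 1, lower.tail = FALSE),
    tolerance = 1e-12)
  expect_error(pearson_chisq(matrix(c(0, 0, 1, 2), 2)), "zero margin")

  # null calibration: equal proportions in a 4x2 survey -> uniform p
  set.seed(23)
  ps <- vapply(1:1000, function(i) {
    counts <- rbinom(4, 50, 0.5)
    tab <- cbind(counts, 50 - counts)
    pearson_chisq(tab)$p_value
  }, numeric(1))
  ks <- suppressWarnings(stats::ks.test(ps, "punif"))
  expect_lt(unname(ks$statistic), 0.06)
})

test_that("survey summaries track categories, 'both' separately", {
  calls <- tibble::tibble(
    group = "L1",
    response = c(rep("GABA_A_R", 30), rep("nAChR", 17), rep("both", 2),
      rep("none", 10))
  )
  s <- survey_summary(calls)
  responsive <- sum(s$n[s$response != "none"])
  expect_equal(responsive, 49)
  expect_equal(s$n[s$response == "both"] / responsive, 2 / 49)

  all_none <- survey_summary(
    tibble::tibble(group = "g", response = rep("none", 5))
  )
  expect_equal(all_none$proportion[all_none$response != "none"], rep(0, 3))
  expect_error(
    survey_summary(tibble::tibble(group = "g", response = "weird")),
    "unknown response"
  )

  # generator survey recovered within 3 binomial sds
  surv <- generate_connectivity_survey(
    list(A = c(GABA_A_R = 0.3, nAChR = 0.1)), c(A = 400), seed = 31
  )
  ss <- survey_summary(surv)
  p_gaba <- ss$proportion[ss$response == "GABA_A_R"]
  expect_lt(abs(p_gaba - 0.3), 3 * sqrt(0.3 * 0.7 / 400))
})

test_that("per-response 2x2 tables count 'both' cells as responders", {
  counts <- dplyr::bind_rows(
    tibble::tibble(group = "mPFC", response = c("nAChR", "GABA_A_R", "both", "none"),
      n = c(18, 8, 2, 103)),
    tibble::tibble(group = "M1", response = c("nAChR", "GABA_A_R", "both", "none"),
      n = c(1, 13, 0, 29))
  )
  s <- survey_summary(counts)
  tab <- response_table_2x2(s, "nAChR", c("mPFC", "M1"))
  expect_equal(unname(tab[, "responder"]), c(20, 1))
  expect_equal(unname(rowSums(tab)), c(131, 43))
})

test_that("count tallies report integer percents", {
  out <- tally_proportions(c(bipolar = 207, multipolar = 107))
  expect_equal(out$percent, c(66, 34))
  out2 <- tally_proportions(rep(c("a", "b"), c(3, 1)))
  expect_equal(out2$percent, c(75, 25))
})
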