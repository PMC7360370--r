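#' Synaptic response amplitude from voltage-clamp sweeps
#'
#' Averages the sweeps, takes the mean of a baseline window before stimulus
#' onset (default 990 ms), and subtracts it from the extremum (maximum-
#' magnitude deviation, sign preserved) within the response window (default
#' 5-20 ms after onset).
#'
#' @param sweeps Tibble/data frame with columns `time_ms`, `sweep`, `value`
#'   (one row per sample per sweep), or a numeric matrix (rows = samples,
#'   columns = sweeps) with `time_ms` supplied separately.
#' @param onset_ms Stimulus onset time (ms).
#' @param baseline_ms Baseline window length before onset (default 990).
#' @param response_window_ms Length-2 window after onset (default `c(5, 20)`).
#' @param time_ms Sample times when `sweeps` is a matrix.
#' @return A one-row tibble: `baseline`, `amplitude`, `peak_time_ms`,
#'   `n_sweeps`.
#' @export
response_amplitude <- function(sweeps, onset_ms,
                               baseline_ms = 990,
                               response_window_ms = c(5, 20),
                               time_ms = NULL) {
  if (is.matrix(sweeps)) {
    stopifnot(!is.null(time_ms), length(time_ms) == nrow(sweeps))
    trace <- rowMeans(sweeps)
    n_sweeps <- ncol(sweeps)
    t <- time_ms
  } else {
    stopifnot(all(c("time_ms", "sweep", "value") %in% names(sweeps)))
    avg <- sweeps |>
      dplyr::group_by(.data$time_ms) |>
      dplyr::summarise(value = mean(.data$value), .groups = "drop") |>
      dplyr::arrange(.data$time_ms)
    trace <- avg$value
    t <- avg$time_ms
    n_sweeps <- length(unique(sweeps$sweep))
  }
  base_sel <- t >= onset_ms - baseline_ms & t < onset_ms
  resp_sel <- t >= onset_ms + response_window_ms[1] &
    t <= onset_ms + response_window_ms[2]
  if (!any(base_sel) || !any(resp_sel)) {
    stop("baseline or response window falls outside the record", call. = FALSE)
  }
  baseline <- mean(trace[base_sel])
  dev <- trace[resp_sel] - baseline
  k <- which.max(abs(dev))
  tibble::tibble(
    baseline = baseline,
    amplitude = dev[k],
    peak_time_ms = t[resp_sel][k],
    n_sweeps = n_sweeps
  )
}

#' Two-sided Fisher's exact test for a 2x2 table
#'
#' Exact hypergeometric test with the probability-ordering two-sided rule:
#' the p-value sums the probabilities of all tables with the same margins
#' whose probability does not exceed that of the observed table (relative
#' tolerance 1e-7 on the comparison). Probabilities are computed in
#' log-space. A zero row or column margin gives p = 1.
#'
#' @param table 2x2 matrix (or 4 counts, row-wise) of non-negative integers.
#' @param alternative `"two.sided"` (default), `"greater"`, or `"less"`
#'   (tail of the top-left cell).
#' @return A one-row tibble: `p_value`, `odds_ratio` (sample odds ratio),
#'   `method`.
#' @export
fisher_exact_2x2 <- function(table, alternative = c("two.sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  x <- as.integer(round(as.matrix(table)))
  if (length(x) == 4 && !is.matrix(table)) x <- matrix(x, 2, byrow = TRUE)
  dim(x) <- c(2, 2)
  stopifnot(all(x >= 0))
  a <- x[1, 1]
  m <- sum(x[1, ]) # row 1 margin
  n <- sum(x[2, ])
  k <- sum(x[, 1]) # column 1 margin
  or <- (x[1, 1] * x[2, 2]) / (x[1, 2] * x[2, 1])
  if (m == 0 || n == 0 || k == 0 || sum(x[, 2]) == 0) {
    return(tibble::tibble(
      p_value = 1, odds_ratio = or, method = "fisher_exact_2x2"
    ))
  }
  support <- max(0L, k - n):min(k, m)
  logp <- stats::dhyper(support, m, n, k, log = TRUE)
  logp_obs <- stats::dhyper(a, m, n, k, log = TRUE)
  p <- switch(alternative,
    two.sided = sum(exp(logp[logp <= logp_obs + log(1 + 1e-7)])),
    greater = sum(exp(logp[support >= a])),
    less = sum(exp(logp[support <= a]))
  )
  tibble::tibble(
    p_value = min(p, 1), odds_ratio = or, method = "fisher_exact_2x2"
  )
}

#' Pearson's chi-squared test for an R x C table
#'
#' Statistic `sum((observed - expected)^2 / expected)` with expected counts
#' from the margins, `df = (R-1)(C-1)`, p from the upper chi-squared tail,
#' without continuity correction. Flags tables with any expected count
#' below 5.
#'
#' @param table R x C matrix of non-negative counts (R, C >= 2).
#' @return One-row tibble: `statistic`, `df`, `p_value`, `min_expected`,
#'   `low_expected` (logical).
#' @export
pearson_chisq <- function(table) {
  x <- as.matrix(table)
  stopifnot(nrow(x) >= 2, ncol(x) >= 2, all(x >= 0))
  if (any(rowSums(x) == 0) || any(colSums(x) == 0)) {
    stop("zero margin in contingency table", call. = FALSE)
  }
  expected <- outer(rowSums(x), colSums(x)) / sum(x)
  res <- suppressWarnings(stats::chisq.test(x, correct = FALSE))
  if (any(expected < 5)) {
    warning("chi-squared approximation: expected count below 5")
  }
  tibble::tibble(
    statistic = unname(res$statistic),
    df = unname(res$parameter),
    p_value = res$p.value,
    min_expected = min(expected),
    low_expected = any(expected < 5)
  )
}

#' Summarize a connectivity survey
#'
#' Per-group counts and proportions of response categories. Cells responding
#' with both a GABA_A R and an nAChR current are tracked as their own
#' category.
#'
#' @param calls Tibble with one row per cell: columns `group` and `response`
#'   (each one of `"GABA_A_R"`, `"nAChR"`, `"both"`, `"none"`); or a counts
#'   tibble with columns `group`, `response`, `n`.
#' @return Tibble `group`, `response`, `n`, `n_group`, `proportion`.
#' @export
survey_summary <- function(calls) {
  categories <- c("GABA_A_R", "nAChR", "both", "none")
  stopifnot(all(c("group", "response") %in% names(calls)))
  bad <- setdiff(unique(calls$response), categories)
  if (length(bad) > 0) {
    stop("unknown response category: ", paste(bad, collapse = ", "), call. = FALSE)
  }
  counts <- if ("n" %in% names(calls)) {
    calls |>
      dplyr::group_by(.data$group, .data$response) |>
      dplyr::summarise(n = sum(.data$n), .groups = "drop")
  } else {
    calls |>
      dplyr::count(.data$group, .data$response, name = "n")
  }
  counts |>
    tidyr::complete(
      group = unique(counts$group),
      response = categories,
      fill = list(n = 0L)
    ) |>
    dplyr::group_by(.data$group) |>
    dplyr::mutate(
      n_group = sum(.data$n),
      proportion = .data$n / .data$n_group
    ) |>
    dplyr::ungroup() |>
    dplyr::mutate(response = factor(.data$response, levels = categories)) |>
    dplyr::arrange(.data$group, .data$response)
}

#' Build a per-response 2x2 table from two groups
#'
#' For one response category, counts responders versus non-responders in two
#' groups (cells with both response types count as responders for each
#' category separately).
#'
#' @param summary A [survey_summary()] result.
#' @param response `"GABA_A_R"` or `"nAChR"`.
#' @param groups Length-2 character vector of group names (rows).
#' @return 2x2 integer matrix (rows = groups, cols = responder/non).
#' @export
response_table_2x2 <- function(summary, response, groups) {
  stopifnot(length(groups) == 2)
  get_n <- function(g, r) {
    sum(summary$n[summary$group == g & summary$response %in% r])
  }
  resp <- vapply(groups, function(g) get_n(g, c(response, "both")), numeric(1))
  tot <- vapply(groups, function(g) {
    summary$n_group[summary$group == g][1]
  }, numeric(1))
  m <- cbind(responder = resp, non_responder = tot - resp)
  rownames(m) <- groups
  storage.mode(m) <- "integer"
  m
}

#' Counts and integer-percent proportions of categorical calls
#'
#' @param x Character/factor vector of per-observation categories, or a named
#'   integer vector of counts.
#' @return Tibble `category`, `n`, `percent` (rounded to integer percent).
#' @export
tally_proportions <- function(x) {
  counts <- if (!is.null(names(x)) && is.numeric(x)) {
    tibble::tibble(category = names(x), n = as.integer(x))
  } else {
    tibble::as_tibble(as.data.frame(table(category = x), stringsAsFactors = FALSE)) |>
      stats::setNames(c("category", "n"))
  }
  counts$percent <- round(100 * counts$n / sum(counts$n))
  counts
}
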