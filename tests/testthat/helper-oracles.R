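# Independent oracles used to freeze expected values.

# exhaustive Fisher oracle: enumerate all tables with the observed margins,
# probability from the factorial formula (valid for N <= 170 in doubles)
fisher_enum_oracle <- function(tab) {
  tab <- as.matrix(tab)
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ])
  c1 <- sum(tab[, 1]); c2 <- sum(tab[, 2])
  N <- r1 + r2
  p_of <- function(a) {
    b <- r1 - a; cc <- c1 - a; dd <- r2 - cc
    if (b < 0 || cc < 0 || dd < 0) return(0)
    (factorial(r1) * factorial(r2) * factorial(c1) * factorial(c2)) /
      (factorial(N) * factorial(a) * factorial(b) * factorial(cc) * factorial(dd))
  }
  p_obs <- p_of(tab[1, 1])
  total <- 0
  for (a in 0:min(r1, c1)) {
    p <- p_of(a)
    if (p > 0 && p <= p_obs * (1 + 1e-7)) total <- total + p
  }
  total
}

# brute-force Otsu: minimise intraclass variance over the same 256-bin grid
otsu_oracle <- function(values, n_bins = 256L) {
  rng <- range(values)
  edges <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  mids <- (edges[-1] + edges[-(n_bins + 1L)]) / 2
  bin <- findInterval(values, edges, rightmost.closed = TRUE, all.inside = TRUE)
  counts <- tabulate(bin, nbins = n_bins)
  p <- counts / sum(counts)
  best_t <- NA_integer_
  best_crit <- Inf
  for (t in 1:(n_bins - 1L)) {
    w0 <- sum(p[1:t]); w1 <- 1 - w0
    if (w0 == 0 || w1 == 0) next
    mu0 <- sum(p[1:t] * mids[1:t]) / w0
    mu1 <- sum(p[(t + 1):n_bins] * mids[(t + 1):n_bins]) / w1
    v0 <- sum(p[1:t] * (mids[1:t] - mu0)^2) / w0
    v1 <- sum(p[(t + 1):n_bins] * (mids[(t + 1):n_bins] - mu1)^2) / w1
    crit <- w0 * v0 + w1 * v1
    if (crit < best_crit - 1e-15) {
      best_crit <- crit
      best_t <- t
    }
  }
  edges[best_t + 1L]
}

# brute-force Renyi criterion search for one order
renyi_oracle <- function(values, alpha, n_bins = 256L) {
  rng <- range(values)
  edges <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  bin <- findInterval(values, edges, rightmost.closed = TRUE, all.inside = TRUE)
  p <- tabulate(bin, nbins = n_bins) / length(values)
  best_t <- NA_integer_
  best <- -Inf
  for (t in 1:(n_bins - 1L)) {
    P <- sum(p[1:t])
    if (P <= 0 || P >= 1) next
    pb <- p[1:t][p[1:t] > 0] / P
    pf <- p[(t + 1):n_bins][p[(t + 1):n_bins] > 0] / (1 - P)
    if (abs(alpha - 1) < 1e-12) {
      crit <- -sum(pb * log(pb)) - sum(pf * log(pf))
    } else {
      crit <- (log(sum(pb^alpha)) + log(sum(pf^alpha))) / (1 - alpha)
    }
    if (crit > best) {
      best <- crit
      best_t <- t
    }
  }
  edges[best_t + 1L]
}

# exhaustive strict local-maximum scan (26-neighbourhood) above a threshold
local_max_oracle <- function(arr, threshold) {
  d <- dim(arr)
  hits <- integer(0)
  for (z in 1:d[1]) for (y in 1:d[2]) for (x in 1:d[3]) {
    v <- arr[z, y, x]
    if (v <= threshold) next
    ok <- TRUE
    for (dz in -1:1) for (dy in -1:1) for (dx in -1:1) {
      if (dz == 0 && dy == 0 && dx == 0) next
      zz <- z + dz; yy <- y + dy; xx <- x + dx
      if (zz < 1 || zz > d[1] || yy < 1 || yy > d[2] || xx < 1 || xx > d[3]) next
      if (arr[zz, yy, xx] > v) ok <- FALSE
    }
    if (ok) hits <- c(hits, z + (y - 1) * d[1] + (x - 1) * d[1] * d[2])
  }
  hits
}

# brute-force single-step 26-neighbourhood dilation
dilate_oracle <- function(mask) {
  d <- dim(mask)
  out <- array(FALSE, dim = d)
  for (z in 1:d[1]) for (y in 1:d[2]) for (x in 1:d[3]) {
    if (!mask[z, y, x]) next
    for (dz in -1:1) for (dy in -1:1) for (dx in -1:1) {
      zz <- z + dz; yy <- y + dy; xx <- x + dx
      if (zz >= 1 && zz <= d[1] && yy >= 1 && yy <= d[2] && xx >= 1 && xx <= d[3]) {
        out[zz, yy, xx] <- TRUE
      }
    }
  }
  out
}

# independent (z, y, x) -> column-major linear index arithmetic
coords_to_index_oracle <- function(z, y, x, d) {
  z + (y - 1) * d[1] + (x - 1) * d[1] * d[2]
}

index_to_coords_df <- function(idx, d) {
  co <- arrayInd(idx, d)
  tibble::tibble(z = co[, 1], y = co[, 2], x = co[, 3])
}
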