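# Independent brute-force oracles. These deliberately avoid the package's
# code paths: U by direct pair counting, Friedman by explicit loops, ROI
# means by exhaustive pixel enumeration.

# Mann-Whitney U by counting (x_i, y_j) pairs, not via rank sums
oracle_mw_u <- function(x, y) {
  wins <- 0
  for (xi in x) for (yj in y)
    wins <- wins + (xi > yj) + 0.5 * (xi == yj)
  min(wins, length(x) * length(y) - wins)
}

# exact two-sided MW p by direct enumeration over pair-count statistics
oracle_mw_p <- function(x, y) {
  nx <- length(x); ny <- length(y)
  pooled <- c(x, y)
  combos <- utils::combn(nx + ny, nx)
  u_obs <- oracle_mw_u(x, y)
  # lower tail of the one-group pair-count statistic, doubled
  ux <- apply(combos, 2, function(ix) {
    wins <- 0
    for (xi in pooled[ix]) for (yj in pooled[-ix])
      wins <- wins + (xi > yj) + 0.5 * (xi == yj)
    wins
  })
  min(1, 2 * mean(ux <= u_obs + 1e-12))
}

# Friedman chi-squared via explicit per-subject loops
oracle_friedman_chi2 <- function(tab) {
  N <- nrow(tab); k <- ncol(tab)
  R <- numeric(k)
  for (i in seq_len(N)) {
    r <- rank(tab[i, ])
    for (j in seq_len(k)) R[j] <- R[j] + r[j]
  }
  s <- 0
  for (j in seq_len(k)) s <- s + R[j]^2
  12 * s / (N * k * (k + 1)) - 3 * N * (k + 1)
}

# mean over an ROI by checking every pixel centre one by one
oracle_roi_mean <- function(map, roi) {
  tot <- 0; cnt <- 0
  for (i in seq_len(nrow(map$values))) {
    for (j in seq_len(ncol(map$values))) {
      x <- map$origin_um[1] + (j - 1) * map$pixel_um
      y <- map$origin_um[2] + (i - 1) * map$pixel_um
      if (x >= roi$x_um && x < roi$x_um + roi$width_um &&
          y >= roi$y_um && y < roi$y_um + roi$height_um) {
        tot <- tot + map$values[i, j]; cnt <- cnt + 1
      }
    }
  }
  tot / cnt
}

# small deterministic contrast map for quantify tests
toy_contrast_map <- function(values, pixel_um = 2) {
  contrast_map(values, pixel_um = pixel_um,
               origin_um = c(pixel_um / 2, pixel_um / 2))
}
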