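# Independent brute-force oracles used to validate the analysis pipeline.
# These are deliberately written as plain loops, separate from the package's
# vectorised implementations.

# ray-casting point-in-polygon test
oracle_point_in_polygon <- function(px, py, poly) {
  n <- nrow(poly)
  inside <- FALSE
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    if ((yi > py) != (yj > py) &&
        px < (xj - xi) * (py - yi) / (yj - yi) + xi) {
      inside <- !inside
    }
    j <- i
  }
  inside
}

# per-bin mean firing rate by explicit accumulation
oracle_binned_means <- function(headings, rates, bins = 60) {
  width <- 360 / bins
  sums <- numeric(bins)
  counts <- integer(bins)
  for (k in seq_along(headings)) {
    b <- floor((headings[k] %% 360) / width) + 1
    if (b > bins) b <- bins
    sums[b] <- sums[b] + rates[k]
    counts[b] <- counts[b] + 1L
  }
  ifelse(counts > 0, sums / pmax(counts, 1), NA_real_)
}

# term-by-term rate-weighted vector sum
oracle_pfd <- function(bin_centers, rates) {
  s <- 0; c_ <- 0
  for (i in seq_along(rates)) {
    s <- s + rates[i] * sin(bin_centers[i] * pi / 180)
    c_ <- c_ + rates[i] * cos(bin_centers[i] * pi / 180)
  }
  (atan2(s, c_) * 180 / pi) %% 360
}

# explicit shift-and-correlate loop
oracle_autocorr <- function(rates) {
  n <- length(rates)
  out <- numeric(n)
  for (k in 0:(n - 1)) {
    shifted <- numeric(n)
    for (i in seq_len(n)) {
      shifted[i] <- rates[((i - 1 - k) %% n) + 1]
    }
    out[k + 1] <- stats::cor(rates, shifted)
  }
  out
}

# synthetic tuning curve: mixture of circular Gaussians on the 60-bin grid
synth_curve <- function(centers_deg, heights, sigma = 20, bins = 60) {
  bc <- seq(360 / bins / 2, 360 - 360 / bins / 2, by = 360 / bins)
  r <- numeric(bins)
  for (k in seq_along(centers_deg)) {
    d <- ((bc - centers_deg[k] + 180) %% 360) - 180
    r <- r + heights[k] * exp(-d^2 / (2 * sigma^2))
  }
  structure(list(bin_centers = bc, rates = r, raw = r,
                 n_samples = rep(1L, bins), empty_bins = integer(0),
                 smoothed = FALSE), class = "tuning_curve")
}
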