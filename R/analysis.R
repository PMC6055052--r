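# Measurement pipeline: 6-degree-binned tuning curves, preferred firing
# directions (rate-weighted circular mean), rotational autocorrelation and
# peak counting, per-compartment splitting, cell classification, weight
# development correlation, ADN drift reports, and the Gaussian-overlap
# capacity analysis.

#' Build a head-direction tuning curve
#'
#' Bins heading into 60 bins of 6 degrees, takes the mean firing rate per
#' bin, and smooths with a circular 5-bin moving average. Empty bins are
#' filled by circular linear interpolation before smoothing and flagged in
#' the result (the fixed-rotation test protocol leaves no bin empty).
#'
#' @param headings heading time series, degrees.
#' @param rates firing-rate series, same length.
#' @param bins number of bins (default 60).
#' @param smooth apply the 5-bin circular moving average.
#' @return a `tuning_curve`: list with `bin_centers`, `rates` (smoothed),
#'   `raw` (per-bin means before smoothing), `n_samples`, `empty_bins`,
#'   `smoothed`.
#' @export
make_tuning_curve <- function(headings, rates, bins = 60, smooth = TRUE) {
  stopifnot(length(headings) == length(rates))
  if (length(headings) == 0) stop("empty input series")
  width <- 360 / bins
  bin <- pmin(floor(wrap_angle(headings) / width) + 1, bins)
  n_samples <- tabulate(bin, nbins = bins)
  if (all(n_samples == 0)) stop("all tuning-curve bins are empty")
  sums <- numeric(bins)
  agg <- rowsum(rates, bin)
  sums[as.integer(rownames(agg))] <- agg[, 1]
  raw <- ifelse(n_samples > 0, sums / pmax(n_samples, 1), NA_real_)
  empty <- which(n_samples == 0)
  if (length(empty)) raw <- fill_circular(raw)
  sm <- if (smooth) circular_ma(raw, 5) else raw
  structure(list(bin_centers = seq(width / 2, 360 - width / 2, by = width),
                 rates = sm, raw = raw, n_samples = n_samples,
                 empty_bins = empty, smoothed = smooth),
            class = "tuning_curve")
}

# circular moving average, odd window
circular_ma <- function(x, window) {
  as.numeric(stats::filter(x, rep(1 / window, window), method = "convolution",
                           sides = 2, circular = TRUE))
}

# fill NA entries by linear interpolation between circular neighbours
fill_circular <- function(x) {
  n <- length(x)
  ok <- which(!is.na(x))
  if (length(ok) == 0) stop("all tuning-curve bins are empty")
  if (length(ok) == n) return(x)
  for (i in which(is.na(x))) {
    dl <- (i - ok) %% n     # distance to previous non-empty bin
    dr <- (ok - i) %% n     # distance to next non-empty bin
    l <- ok[which.min(dl)]; r <- ok[which.min(dr)]
    wl <- min(dl); wr <- min(dr)
    x[i] <- (wr * x[l] + wl * x[r]) / (wl + wr)
  }
  x
}

#' Preferred firing direction of a tuning curve
#'
#' Rate-weighted circular mean of the bin centres:
#' `atan2(sum(r * sin(x)), sum(r * cos(x)))`, wrapped to `[0, 360)`. Errors
#' when the resultant vector is (numerically) zero, e.g. for a uniform curve
#' or a perfectly balanced bimodal curve, in which case no preferred
#' direction exists.
#'
#' @param curve a `tuning_curve` (or any list with `bin_centers`, `rates`).
#' @param tol undefined-PFD threshold on the mean resultant length.
#' @return degrees in `[0, 360)`.
#' @export
pfd <- function(curve, tol = 1e-6) {
  r <- curve$rates
  tot <- sum(abs(r))
  if (tot <= 0) stop("preferred firing direction undefined: curve is zero")
  x <- curve$bin_centers * pi / 180
  s <- sum(r * sin(x)); c_ <- sum(r * cos(x))
  if (sqrt(s^2 + c_^2) / tot < tol) {
    stop("preferred firing direction undefined: resultant length near zero")
  }
  wrap_angle(atan2(s, c_) * 180 / pi)
}

#' Rotational autocorrelation of a tuning curve
#'
#' Pearson correlation of the curve with itself rotated by each multiple of
#' the bin width (0 to 354 degrees for 60 bins). The number of peaks of this
#' autocorrelation is the number of peaks of the tuning curve.
#'
#' @param curve a `tuning_curve`.
#' @return an `autocorr`: list with `rotations` (degrees) and `correlation`.
#' @export
rotational_autocorrelation <- function(curve) {
  r <- curve$rates
  n <- length(r)
  if (stats::sd(r) == 0) stop("autocorrelation undefined for a constant curve")
  ac <- vapply(0:(n - 1), function(k) {
    stats::cor(r, r[((seq_len(n) - 1 - k) %% n) + 1])
  }, numeric(1))
  structure(list(rotations = (0:(n - 1)) * 360 / n, correlation = ac),
            class = "autocorr")
}

#' Average autocorrelations across cells
#'
#' @param acs list of `autocorr` objects on a common rotation grid.
#' @return an `autocorr` with the element-wise mean correlation.
#' @export
mean_autocorr <- function(acs) {
  m <- rowMeans(vapply(acs, `[[`, numeric(length(acs[[1]]$correlation)),
                       "correlation"))
  structure(list(rotations = acs[[1]]$rotations, correlation = m),
            class = "autocorr")
}

#' Count peaks of a circular profile
#'
#' Local maxima of the (circular) correlation-vs-rotation profile whose
#' topographic prominence exceeds `min_prominence` times the profile range.
#' Ties on plateaus count once.
#'
#' @param ac an `autocorr` (or any list with `rotations`, `correlation`).
#' @param min_prominence prominence threshold as a fraction of the range.
#' @return list with `n_peaks` and `rotations` (peak locations, degrees).
#' @export
count_peaks <- function(ac, min_prominence = 0.1) {
  y <- ac$correlation
  n <- length(y)
  rng <- diff(range(y))
  if (rng == 0) return(list(n_peaks = 0L, rotations = numeric(0)))
  prv <- y[c(n, 1:(n - 1))]
  nxt <- y[c(2:n, 1)]
  cand <- which(y > prv & y >= nxt)
  prom <- vapply(cand, function(i) peak_prominence(y, i), numeric(1))
  keep <- prom >= min_prominence * rng
  list(n_peaks = sum(keep), rotations = ac$rotations[cand[keep]])
}

# circular topographic prominence: on each side, walk until a strictly higher
# value is met (or all the way round), tracking the minimum; prominence is
# peak height minus the larger of the two side minima
peak_prominence <- function(y, i) {
  n <- length(y)
  side_min <- function(step) {
    m <- Inf
    j <- i
    for (k in seq_len(n - 1)) {
      j <- ((j - 1 + step) %% n) + 1
      if (y[j] > y[i]) break
      m <- min(m, y[j])
    }
    m
  }
  l <- side_min(-1L); r <- side_min(1L)
  y[i] - min(max(l, r), y[i])
}

#' Split test-phase samples by compartment
#'
#' Partitions the test-phase timesteps of a simulation record by compartment
#' id, returning heading/rate pairs for the whole apparatus and for each
#' compartment. Compartments with zero test samples are flagged and excluded.
#'
#' @param record a `simulation_record`.
#' @param layer layer name (`"adn"`, `"rsc"`, `"conj"`, `"env"`).
#' @return list with `whole` (list of `headings`, `rates` step x cell matrix)
#'   and `comps` (named list per compartment id), plus `empty` (excluded ids).
#' @export
split_by_compartment <- function(record, layer = "conj") {
  if (length(record$test_idx) == 0) stop("record has no test phase")
  R <- record$rates_test[[layer]]
  h <- record$path$heading[record$test_idx]
  cmp <- record$path$compartment[record$test_idx]
  ids <- sort(unique(record$path$compartment))
  comps <- list()
  empty <- integer(0)
  for (id in ids) {
    sel <- cmp == id
    if (!any(sel)) { empty <- c(empty, id); next }
    comps[[as.character(id)]] <- list(headings = h[sel],
                                      rates = R[sel, , drop = FALSE])
  }
  list(whole = list(headings = h, rates = R), comps = comps, empty = empty)
}

#' Classify a cell's directional response
#'
#' Operationalises the experimentally observed categories from the whole and
#' per-compartment tuning curves: `HD_like` (unimodal everywhere, stable
#' PFD), `BC_like` (unimodal per compartment, multimodal over the whole
#' apparatus because the per-compartment PFD rotates), `WC_like` (multimodal
#' within compartments, dominant pole rotating), `untuned` (no stable peak or
#' modulation depth below threshold).
#'
#' @param whole `tuning_curve` over the whole apparatus.
#' @param per_comp list of per-compartment `tuning_curve`s (>= 2).
#' @param mod_depth_min minimum modulation depth `(max - min) / max`.
#' @param pfd_tol tolerance (deg) for "same PFD across compartments".
#' @param min_prominence peak-counting prominence threshold.
#' @return one of `"HD_like"`, `"BC_like"`, `"WC_like"`, `"untuned"`.
#' @export
classify_cell <- function(whole, per_comp, mod_depth_min = 0.4, pfd_tol = 30,
                          min_prominence = 0.1) {
  depth <- function(cv) {
    mx <- max(cv$rates)
    if (mx <= 0) 0 else (mx - min(cv$rates)) / mx
  }
  npk <- function(cv) {
    if (stats::sd(cv$rates) == 0) return(0L)
    count_peaks(rotational_autocorrelation(cv), min_prominence)$n_peaks
  }
  if (depth(whole) < mod_depth_min || any(vapply(per_comp, depth, 1) < mod_depth_min)) {
    return("untuned")
  }
  nw <- npk(whole)
  nc <- vapply(per_comp, npk, integer(1))
  if (nw == 0 || any(nc == 0)) return("untuned")
  multi <- sum(nc >= 2)
  if (multi >= ceiling(length(per_comp) / 2)) return("WC_like")
  if (all(nc == 1) && nw >= 2) return("BC_like")
  if (all(nc == 1) && nw == 1) {
    pfds <- vapply(per_comp, function(cv) tryCatch(pfd(cv), error = function(e) NA_real_),
                   numeric(1))
    if (anyNA(pfds)) return("untuned")
    spread <- max(abs(circular_diff(pfds, pfds[1])))
    if (spread <= pfd_tol) return("HD_like")
    return("BC_like")
  }
  "untuned"
}

#' Peak asymmetry of a multimodal tuning curve
#'
#' Height of the second-highest peak divided by the dominant peak height.
#' Conjunctive (within-compartment) cells show a ratio below 1 in each
#' compartment: the dominant pole is driven by vision plus learned HD input,
#' the weaker pole by the learned HD input alone.
#'
#' @param curve a `tuning_curve` with at least two peaks.
#' @param min_prominence peak-detection prominence threshold.
#' @return ratio in `(0, 1]`.
#' @export
peak_asymmetry <- function(curve, min_prominence = 0.1) {
  y <- curve$rates
  n <- length(y)
  prv <- y[c(n, 1:(n - 1))]
  nxt <- y[c(2:n, 1)]
  cand <- which(y > prv & y >= nxt)
  if (length(cand)) {
    prom <- vapply(cand, function(i) peak_prominence(y, i), numeric(1))
    cand <- cand[prom >= min_prominence * diff(range(y))]
  }
  if (length(cand) < 2) stop("peak asymmetry requires a multimodal curve")
  hts <- sort(y[cand], decreasing = TRUE)
  hts[2] / hts[1]
}

#' Correlation between two weight matrices
#'
#' Pearson correlation over all (flattened) entries; used to track how
#' quickly a developing weight profile approaches its final state.
#'
#' @param W_t,W_ref matrices (or `weight_matrix` objects) of equal shape.
#' @return scalar in `[-1, 1]`.
#' @export
weight_profile_correlation <- function(W_t, W_ref) {
  a <- if (inherits(W_t, "weight_matrix")) W_t$values else W_t
  b <- if (inherits(W_ref, "weight_matrix")) W_ref$values else W_ref
  if (!all(dim(a) == dim(b))) stop("weight matrices differ in shape")
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    stop("weight correlation undefined for a zero-variance matrix")
  }
  stats::cor(as.vector(a), as.vector(b))
}

#' ADN drift report
#'
#' Compares test-phase ADN preferred firing directions against the PFDs the
#' cells are expected to have from their pre-learning arrangement, overall,
#' per spatial quadrant, and per 30-s time window. Deviations are signed
#' circular differences in `(-180, 180]`; layer means are circular means of
#' the per-cell deviations, expressed signed.
#'
#' @param record an attractor-mode `simulation_record` with a test phase.
#' @param expected_pfds expected PFD per ADN cell (defaults to the ring
#'   arrangement the simulation started from).
#' @param window window length, seconds.
#' @return a `drift_report`: list with `per_cell`, `quadrants`, `windows`
#'   data frames, `layer_mean`, `layer_mean_abs`, `window_summary`,
#'   `quadrant_summary`.
#' @export
drift_report <- function(record, expected_pfds = record$pfds$adn, window = 30) {
  if (length(record$test_idx) == 0) stop("record has no test phase")
  R <- record$rates_test$adn
  idx <- record$test_idx
  h <- record$path$heading[idx]
  tt <- record$path$time[idx]
  n_cells <- ncol(R)

  cell_dev <- function(sel) {
    vapply(seq_len(n_cells), function(i) {
      m <- tryCatch(pfd(make_tuning_curve(h[sel], R[sel, i])),
                    error = function(e) NA_real_)
      if (is.na(m)) NA_real_ else circular_diff(m, expected_pfds[i])
    }, numeric(1))
  }

  dev_all <- cell_dev(rep(TRUE, length(idx)))
  per_cell <- data.frame(cell = seq_len(n_cells), expected = expected_pfds,
                         deviation = dev_all)

  signed_mean <- function(d) {
    d <- d[!is.na(d)]
    if (!length(d)) return(NA_real_)
    m <- circular_mean(d)
    if (m > 180) m - 360 else m
  }

  # spatial quadrants (NE, SE, SW, NW)
  q <- quadrant_of(list(center = record$env_center %||% c(0, 0)),
                   record$path$x[idx], record$path$y[idx])
  quad_rows <- list()
  for (qq in 1:4) {
    sel <- q == qq
    dev <- if (any(sel)) cell_dev(sel) else rep(NA_real_, n_cells)
    quad_rows[[qq]] <- data.frame(cell = seq_len(n_cells), quadrant = qq,
                                  deviation = dev,
                                  covered = any(sel))
  }
  quadrants <- do.call(rbind, quad_rows)

  # 30-s windows
  w_id <- floor((tt - tt[1]) / window) + 1
  win_rows <- list()
  for (wv in sort(unique(w_id))) {
    sel <- w_id == wv
    win_rows[[length(win_rows) + 1]] <-
      data.frame(cell = seq_len(n_cells), window = wv, deviation = cell_dev(sel))
  }
  windows <- do.call(rbind, win_rows)

  win_sum <- do.call(rbind, lapply(split(windows, windows$window), function(d)
    data.frame(window = d$window[1], mean_dev = signed_mean(d$deviation),
               mean_abs_dev = mean(abs(d$deviation), na.rm = TRUE))))
  quad_sum <- do.call(rbind, lapply(split(quadrants, quadrants$quadrant), function(d)
    data.frame(quadrant = d$quadrant[1], mean_dev = signed_mean(d$deviation),
               mean_abs_dev = mean(abs(d$deviation), na.rm = TRUE))))

  structure(list(per_cell = per_cell, quadrants = quadrants, windows = windows,
                 layer_mean = signed_mean(dev_all),
                 layer_mean_abs = mean(abs(dev_all), na.rm = TRUE),
                 window_summary = win_sum, quadrant_summary = quad_sum),
            class = "drift_report")
}

#' @export
print.drift_report <- function(x, ...) {
  cat(sprintf("<drift_report: layer mean deviation %.2f deg (|.| %.2f deg)>\n",
              x$layer_mean, x$layer_mean_abs))
  invisible(x)
}

#' Multi-peak capacity tuning curve
#'
#' Tuning curve of a cell that has learned `n_peaks` evenly spaced
#' compartment directions: the sum of `n_peaks` circular Gaussians spread
#' through 360 degrees. Specificity is the modulation depth
#' `(max - min) / max`; it decreases with the number of peaks and with their
#' width, which is the theoretical limit on how many visually identical
#' compartments the network can distinguish.
#'
#' @param n_peaks number of learned directions (>= 1).
#' @param sigma Gaussian width, degrees.
#' @param bins curve resolution.
#' @return list with `curve` (a `tuning_curve`) and `specificity`.
#' @export
capacity_tuning <- function(n_peaks, sigma, bins = 60) {
  stopifnot(n_peaks >= 1, sigma > 0)
  width <- 360 / bins
  centers <- seq(width / 2, 360 - width / 2, by = width)
  peaks <- 360 * (seq_len(n_peaks) - 1) / n_peaks
  r <- rowSums(vapply(peaks, function(p0) circular_gaussian(p0, sigma, centers),
                      numeric(bins)))
  curve <- structure(list(bin_centers = centers, rates = r, raw = r,
                          n_samples = rep(1L, bins), empty_bins = integer(0),
                          smoothed = FALSE), class = "tuning_curve")
  list(curve = curve, specificity = (max(r) - min(r)) / max(r))
}
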