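# Independent reference implementations used as oracles. These deliberately
# use different code paths (explicit loops, lm(), stats::mad) from the
# package implementations they check.

# One-way effect size via the R-squared of lm(counts ~ bin factor):
# algebraically SS_between / SS_total for a grand-mean decomposition.
oracle_eta_squared <- function(angles, counts, n_bins = 12) {
  bin <- factor(floor((angles %% 360) / (360 / n_bins)))
  if (nlevels(droplevels(bin)) < 2) return(NA_real_)
  suppressWarnings(summary(lm(counts ~ bin))$r.squared)  # perfect fits warn
}

# Brute-force scaled-MAD outlier rule with explicit loops.
oracle_mad_mask <- function(x, factor = 3) {
  med <- sort(x)[ceiling(length(x) / 2)]
  if (length(x) %% 2 == 0) {
    s <- sort(x)
    med <- (s[length(x) / 2] + s[length(x) / 2 + 1]) / 2
  }
  devs <- numeric(length(x))
  for (i in seq_along(x)) devs[i] <- abs(x[i] - med)
  smad <- 1.4826 * {
    s <- sort(devs)
    if (length(s) %% 2 == 1) s[(length(s) + 1) / 2]
    else (s[length(s) / 2] + s[length(s) / 2 + 1]) / 2
  }
  out <- logical(length(x))
  for (i in seq_along(x)) out[i] <- devs[i] > factor * smad
  out
}

# Step-by-step width-at-half-height on a 10 ms binned trace: 5-bin
# edge-renormalized moving average (explicit loop), linear interpolation to
# a 1 ms grid (manual lerp), affine normalization, rle-based run count.
oracle_whh <- function(trace, centers, baseline = c(-3, -0.5), bins = 5L) {
  n <- length(trace)
  half <- (bins - 1L) %/% 2L
  sm <- numeric(n)
  for (i in seq_len(n)) {
    lo <- max(1L, i - half); hi <- min(n, i + half)
    sm[i] <- mean(trace[lo:hi])
  }
  grid <- seq(centers[1], centers[n], by = 0.001)
  up <- numeric(length(grid))
  for (g in seq_along(grid)) {
    j <- max(which(centers <= grid[g] + 1e-12))
    if (j == n) { up[g] <- sm[n]; next }
    w <- (grid[g] - centers[j]) / (centers[j + 1] - centers[j])
    up[g] <- (1 - w) * sm[j] + w * sm[j + 1]
  }
  b <- mean(up[grid >= baseline[1] & grid < baseline[2]])
  pk <- max(up)
  stopifnot(pk > b)
  y <- (up - b) / (pk - b)
  r <- rle(y > 0.5)
  ends <- cumsum(r$lengths)
  starts <- c(1, head(ends, -1) + 1)
  ipk <- which.max(y)
  run <- which(r$values & starts <= ipk & ends >= ipk)
  if (!length(run)) 0L else r$lengths[run]
}

# Analytic perievent mean trace for a Gaussian response bump on a flat
# baseline, sampled at the standard 10 ms bin centers.
analytic_peth_trace <- function(latency_s, sigma_s, gain, baseline_rate,
                                window = c(-3, 3), bin = 0.01) {
  centers <- seq(window[1] + bin / 2, window[2] - bin / 2, by = bin)
  baseline_rate * bin + gain * bin * dnorm(centers, latency_s, sigma_s)
}

# Wrap an analytic trace as a minimal peth object.
fake_peth <- function(trace, window = c(-3, 3), bin = 0.01,
                      n_events = 100L, id = "fake") {
  nb <- length(trace)
  edges <- window[1] + bin * (0:nb)
  structure(list(counts = matrix(rep(trace, each = n_events), n_events, nb),
                 bin_edges = edges, bin_centers = edges[-1] - bin / 2,
                 mean_rate_trace = trace, window = window, bin = bin,
                 n_events = n_events, neuron_id = id,
                 baseline_mean = NA_real_, baseline_sd = NA_real_,
                 z_trace = NULL), class = "peth")
}
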