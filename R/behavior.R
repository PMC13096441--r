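# Movement detection from ROI pixel-change series, event-selection rules
# (twitch isolation, wake-bout quiescence), rule-based behavioral-state
# scoring, and EMG inclusion rules.

# Centered moving-average smoothing that preserves constants at the edges
# (partial windows are renormalized). Shared by behavior and metrics.
boxcar_smooth <- function(x, bins) {
  bins <- as.integer(bins)
  if (bins <= 1) return(x)
  n <- length(x)
  half <- (bins - 1) / 2
  lo <- pmax(1, ceiling(seq_len(n) - half))
  hi <- pmin(n, floor(seq_len(n) + half))
  cs <- cumsum(c(0, x))
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}

#' Gaussian-smooth and downsample a wide-band signal
#'
#' Smooths with a moving Gaussian kernel of the given half-width (half-width
#' at half maximum, 0.5 ms by default) and decimates to the target rate.
#'
#' @param raw Numeric samples.
#' @param fs Input sampling rate in Hz (must be at least the target rate).
#' @param target_fs Output rate (default 1000 Hz).
#' @param half_width_s Kernel half-width at half maximum, seconds.
#' @return Numeric vector of length `floor(length(raw) * target_fs / fs)`.
#' @export
preprocess_lfp <- function(raw, fs, target_fs = 1000, half_width_s = 0.0005) {
  if (fs < target_fs)
    stop_invalid("input rate %g Hz is below the target %g Hz", fs, target_fs)
  sigma <- half_width_s / sqrt(2 * log(2)) * fs      # samples
  half <- max(1L, ceiling(4 * sigma))
  kern <- exp(-((-half):half)^2 / (2 * sigma^2))
  kern <- kern / sum(kern)
  n <- length(raw)
  padded <- c(rep(raw[1], half), raw, rep(raw[n], half))
  sm <- as.numeric(stats::filter(padded, kern, sides = 2))[(half + 1):(half + n)]
  m <- floor(n * target_fs / fs)
  idx <- floor((seq_len(m) - 1) * fs / target_fs) + 1
  sm[idx]
}

#' Detect candidate movement bouts in a pixel-change series
#'
#' A candidate starts at each upward threshold crossing — the first frame
#' whose count exceeds the threshold — and ends when the series falls back
#' below it.
#'
#' @param series A [pixel_change_series()].
#' @param onset_threshold Counts; defaults to the series median plus
#'   `mads` scaled MADs (the automatic stand-in for manual video
#'   confirmation; the value used is logged).
#' @param mads MAD multiplier for the automatic threshold.
#' @return Data frame of candidates: `onset`, `offset` (seconds), `peak`
#'   (max counts in the bout). All-zero or all-subthreshold series yield an
#'   empty frame.
#' @export
detect_movement_bouts <- function(series, onset_threshold = NULL, mads = 3) {
  v <- as.numeric(series$values)
  if (is.null(onset_threshold)) {
    med <- median(v)
    onset_threshold <- med + mads * 1.4826 * median(abs(v - med))
    mp_log("info", sprintf("ROI %s: automatic onset threshold %.2f counts",
                           series$roi_label, onset_threshold))
  }
  if (onset_threshold <= 0) stop_invalid("onset threshold must be positive")
  above <- v > onset_threshold
  if (!any(above))
    return(data.frame(onset = numeric(0), offset = numeric(0),
                      peak = numeric(0)))
  d <- diff(c(FALSE, above))
  starts <- which(d == 1)
  stops <- which(d == -1) - 1L
  if (length(stops) < length(starts)) stops <- c(stops, length(v))
  tt <- series_times(series)
  data.frame(onset = tt[starts], offset = tt[stops],
             peak = vapply(seq_along(starts), function(i)
               max(v[starts[i]:stops[i]]), 0))
}

#' Apply the wake-bout quiescence rule
#'
#' Only the first movement of a bout is kept; a later candidate is retained
#' only when separated from the end of the previously retained bout by at
#' least `quiescence_gap` of sub-threshold series (inclusive at the
#' boundary). Retention is greedy from the left, so the retained set is
#' maximal: adding back any removed candidate violates the gap rule.
#'
#' @param candidates Data frame from [detect_movement_bouts()] (sorted).
#' @param quiescence_gap Seconds of required quiescence (default 0.5).
#' @return The retained subset of `candidates`.
#' @export
mark_wake_movement_onsets <- function(candidates, quiescence_gap = 0.5) {
  if (!nrow(candidates)) return(candidates)
  if (is.unsorted(candidates$onset)) stop_invalid("candidates must be sorted")
  keep <- logical(nrow(candidates))
  keep[1] <- TRUE
  last_off <- candidates$offset[1]
  for (i in seq_len(nrow(candidates))[-1]) {
    if (candidates$onset[i] - last_off >= quiescence_gap) {
      keep[i] <- TRUE
      last_off <- candidates$offset[i]
    } else {
      last_off <- max(last_off, candidates$offset[i])
    }
  }
  candidates[keep, , drop = FALSE]
}

#' Select temporally isolated twitches
#'
#' `cross_bodypart` mode keeps a twitch only when no twitch of a *different*
#' body part falls within `window` of it (the rule used for somatotopic
#' preference); `same_bodypart` mode additionally requires the same spacing
#' to same-body-part neighbors (the rule used for displacement profiles).
#' Boundary spacing exactly equal to `window` counts as isolated.
#'
#' @param events A [movement_events()] table (twitches; other classes are
#'   passed through untouched in the comparison set but only twitches are
#'   returned).
#' @param window Isolation window in seconds (default 0.1).
#' @param mode `"cross_bodypart"` or `"same_bodypart"`.
#' @return The isolated subset of the twitch events (a subset of the input).
#' @export
isolate_twitches <- function(events, window = 0.1,
                             mode = c("cross_bodypart", "same_bodypart")) {
  mode <- match.arg(mode)
  tw <- events[events$class == "twitch", , drop = FALSE]
  if (!nrow(tw)) return(tw)
  keep <- vapply(seq_len(nrow(tw)), function(i) {
    dt <- abs(tw$onset_s - tw$onset_s[i])
    other <- tw$body_part != tw$body_part[i]
    ok <- all(dt[other] >= window)
    if (ok && mode == "same_bodypart") {
      same <- !other & seq_len(nrow(tw)) != i
      ok <- all(dt[same] >= window)
    }
    ok
  }, TRUE)
  tw[keep, , drop = FALSE]
}

#' Merge whisker twitch series into their first member
#'
#' Whisker protraction/retraction series lack clear boundaries; successive
#' whisker candidates closer than `gap` are collapsed into the first.
#'
#' @param events A [movement_events()] table.
#' @param gap Merge gap in seconds (default 0.1).
#' @return The events with redundant whisker twitches removed.
#' @export
merge_whisker_twitches <- function(events, gap = 0.1) {
  wi <- which(events$body_part == "whiskers" & events$class == "twitch")
  if (length(wi) < 2) return(events)
  tt <- events$onset_s[wi]
  keep <- c(TRUE, diff(tt) >= gap)
  # collapse runs: a candidate is kept only if >= gap after the last kept one
  last <- tt[1]
  for (i in seq_along(tt)[-1]) {
    keep[i] <- (tt[i] - last) >= gap
    if (keep[i]) last <- tt[i]
  }
  drop <- wi[!keep]
  if (length(drop)) events <- events[-drop, , drop = FALSE]
  events
}

#' Rule-based behavioral state scoring
#'
#' Scores the session from nuchal-EMG tone and cortical delta power:
#' atonia bouts (tone below the atonia threshold) containing at least one
#' movement are REM; samples with delta power above the delta threshold
#' during behavioral quiescence are NREM; everything else is wake, split
#' into active wake (within `active_wake_s` after a movement) and quiet
#' wake. Because absolute trace scales vary between preparations, each
#' threshold sits at a configurable fraction (`atonia_fraction`,
#' `delta_fraction`) of the trace's robust dynamic range (5th..95th
#' percentile), which lands between the low and high clusters regardless of
#' state occupancy.
#'
#' @param tone,delta Data frames `(time, value)` on a shared time base.
#' @param movement_times Numeric onset times of detected movements
#'   (candidates from ROI detection; used for the REM twitching
#'   requirement, the NREM quiescence requirement and active wake).
#' @param config An `mp_config` (see [default_config()]).
#' @param smooth_s Pre-threshold smoothing window in seconds (state
#'   transitions are slow relative to trace noise).
#' @return A [state_timeline()] covering the sampled span.
#' @export
classify_states <- function(tone, delta, movement_times = numeric(0),
                            config = default_config(), smooth_s = 1) {
  bc <- config$behavior
  if (nrow(tone) != nrow(delta) ||
      max(abs(tone$time - delta$time)) > 1e-9)
    stop_invalid("tone and delta traces must share one time base")
  tt <- tone$time
  fs <- 1 / median(diff(tt))
  k <- max(1L, round(smooth_s * fs))
  tone_v <- boxcar_smooth(tone$value, k)
  delta_v <- boxcar_smooth(delta$value, k)
  # Thresholds sit at a fraction of each trace's robust dynamic range
  # (5th..95th percentile), so they fall between the low and high clusters
  # regardless of how much time a session spends in each state.
  range_thr <- function(v, frac) {
    q <- quantile(v, c(0.05, 0.95), names = FALSE)
    q[1] + frac * (q[2] - q[1])
  }
  atonia <- tone_v < range_thr(tone_v, bc$atonia_fraction)
  high_delta <- delta_v > range_thr(delta_v, bc$delta_fraction)
  moving <- rep(FALSE, length(tt))
  for (m in movement_times) {
    moving[tt >= m & tt < m + bc$active_wake_s] <- TRUE
  }
  st <- rep("quiet_wake", length(tt))
  # REM: atonia bouts that contain twitching (>= 1 movement)
  runs <- rle(atonia)
  ends <- cumsum(runs$lengths)
  starts <- c(1, utils::head(ends, -1) + 1)
  for (r in which(runs$values)) {
    idx <- starts[r]:ends[r]
    has_move <- any(movement_times >= tt[idx[1]] &
                    movement_times <= tt[idx[length(idx)]] + 1 / fs)
    if (has_move) st[idx] <- "REM"
  }
  nrem <- st != "REM" & high_delta & !moving
  st[nrem] <- "NREM"
  st[st == "quiet_wake" & moving] <- "active_wake"
  # collapse samples into intervals; sample i covers [t_i, t_{i+1})
  bounds <- c(tt, tt[length(tt)] + 1 / fs)
  runs <- rle(st)
  ends <- cumsum(runs$lengths)
  starts <- c(1, utils::head(ends, -1) + 1)
  state_timeline(bounds[starts], bounds[ends + 1], runs$values)
}

#' EMG-based event inclusion mask
#'
#' An event is included only when its peri-event rectified EMG reaches the
#' z threshold (inclusive) relative to its own pre-onset baseline.
#'
#' @param emg Data frame `(time, value)` of rectified EMG.
#' @param events A [movement_events()] table.
#' @param z_threshold Inclusion threshold (default 2.0).
#' @param baseline_window,response_window Windows relative to onset
#'   (seconds) for the baseline statistics and the peak search.
#' @return Logical inclusion mask, one entry per event. Events with zero
#'   baseline SD are excluded with a warning.
#' @export
emg_event_inclusion <- function(emg, events, z_threshold = 2,
                                baseline_window = c(-1, -0.2),
                                response_window = c(-0.05, 0.15)) {
  vapply(seq_len(nrow(events)), function(i) {
    on <- events$onset_s[i]
    base <- emg$value[emg$time >= on + baseline_window[1] &
                      emg$time < on + baseline_window[2]]
    resp <- emg$value[emg$time >= on + response_window[1] &
                      emg$time < on + response_window[2]]
    if (!length(base) || !length(resp)) return(FALSE)
    s <- sd(base)
    if (!is.finite(s) || s == 0) {
      warning(sprintf("event at %.3f s: zero baseline SD; excluded", on),
              call. = FALSE)
      return(FALSE)
    }
    (max(resp) - mean(base)) / s >= z_threshold
  }, TRUE)
}

#' Grand mean EMG profile across animals
#'
#' Two-stage average: the mean profile within each animal, then the
#' unweighted mean across animals, so animals with many events do not
#' dominate.
#'
#' @param per_animal Named list with one element per animal: either a
#'   numeric profile (that animal's mean) or an events-by-time matrix of
#'   per-event profiles.
#' @return Numeric grand-mean profile.
#' @export
grand_mean_emg <- function(per_animal) {
  if (!length(per_animal)) stop_invalid("no animals with included events")
  means <- lapply(per_animal, function(p) {
    if (is.matrix(p)) colMeans(p) else as.numeric(p)
  })
  len <- unique(vapply(means, length, 0L))
  if (length(len) != 1) stop_invalid("animal profiles differ in length")
  Reduce(`+`, means) / length(means)
}
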