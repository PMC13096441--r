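# Per-movement amplitude/angle from limb trajectories, direction and
# amplitude selectivity of single neurons, and the preferred/non-preferred
# movement split.

# Circular mean of angles in degrees.
circ_mean_deg <- function(deg) {
  th <- deg * pi / 180
  (atan2(mean(sin(th)), mean(cos(th))) * 180 / pi) %% 360
}

#' Amplitude and angle of one movement
#'
#' The movement origin is the limb position on the frame of movement onset
#' (the last frame at or before the onset time). Displacement is tracked
#' for 150 ms (twitch) or 500 ms (wake movement): amplitude is the peak
#' Euclidean displacement converted to mm via the calibration, and the
#' angle is the direction of the onset-to-peak vector in math convention
#' (counterclockwise from +x, y up), with the image y axis flipped. With
#' `angle_method = "path_mean"` the angle is instead the circular mean of
#' the per-frame onset-to-position vectors up to the peak.
#'
#' @param traj A [trajectory()].
#' @param onset Onset time in seconds.
#' @param class `"twitch"` or `"wake"`.
#' @param config An `mp_config` (windows, angle method).
#' @return One-row data frame: `onset_s`, `class`, `amplitude_mm`,
#'   `angle_deg` (`NA` at zero amplitude), `peak_time_s`. A trajectory gap
#'   inside the window yields all-`NA` kinematics.
#' @export
compute_kinematics <- function(traj, onset, class = c("twitch", "wake"),
                               config = default_config()) {
  class <- match.arg(class)
  kc <- config$kinematics
  w <- if (class == "twitch") kc$twitch_window_s else kc$wake_window_s
  cal <- attr(traj, "calibration")
  na_row <- data.frame(onset_s = onset, class = class,
                       amplitude_mm = NA_real_, angle_deg = NA_real_,
                       peak_time_s = NA_real_)
  i0 <- findInterval(onset + 1e-9, traj$time)
  if (i0 < 1) return(na_row)
  sel <- which(traj$time >= traj$time[i0] & traj$time <= onset + w)
  if (length(sel) < 2 || traj$time[max(sel)] < onset + w - 1.5 / frame_step(traj))
    return(na_row)
  if (max(diff(traj$time[sel])) > 1.5 * median(diff(traj$time[sel])))
    return(na_row)                                   # gap inside the window
  dx <- traj$x[sel] - traj$x[i0]
  dy <- traj$y[sel] - traj$y[i0]
  disp <- sqrt(dx^2 + dy^2)
  ipk <- which.max(disp)
  amp_mm <- disp[ipk] / cal
  if (amp_mm == 0) {
    return(data.frame(onset_s = onset, class = class, amplitude_mm = 0,
                      angle_deg = NA_real_, peak_time_s = traj$time[sel[ipk]]))
  }
  ang <- if (kc$angle_method == "path_mean") {
    ii <- 2:ipk
    ii <- ii[disp[ii] > 0]
    circ_mean_deg(atan2(-dy[ii], dx[ii]) * 180 / pi)
  } else {
    (atan2(-dy[ipk], dx[ipk]) * 180 / pi) %% 360     # image y flipped
  }
  data.frame(onset_s = onset, class = class, amplitude_mm = amp_mm,
             angle_deg = ang, peak_time_s = traj$time[sel[ipk]])
}

frame_step <- function(traj) 1 / median(diff(traj$time))

#' Kinematics for a table of movements
#' @param traj A [trajectory()].
#' @param events A [movement_events()] table.
#' @param config An `mp_config`.
#' @return Data frame with one row per event.
#' @export
movement_kinematics <- function(traj, events, config = default_config()) {
  rows <- lapply(seq_len(nrow(events)), function(i)
    compute_kinematics(traj, events$onset_s[i], events$class[i], config))
  do.call(rbind, rows)
}

#' Spikes in a movement's activity window
#'
#' Count of spikes in the half-open window `[onset + lo, onset + hi)`;
#' -70..70 ms for twitches and -100..500 ms for wake movements.
#'
#' @param spikes A [spike_train()].
#' @param events Events or numeric onsets.
#' @param class `"twitch"` or `"wake"`.
#' @param config An `mp_config`.
#' @return Integer counts per event.
#' @export
spike_count_in_activity_window <- function(spikes, events,
                                           class = c("twitch", "wake"),
                                           config = default_config()) {
  class <- match.arg(class)
  win <- if (class == "twitch") config$metrics$fano_twitch_window_s
         else config$metrics$fano_wake_window_s
  spike_counts_in_window(spikes, events, win)
}

#' Variance in firing explained by movement direction
#'
#' Movements are grouped into `n_bins` equal directional bins over
#' `[0, 360)`; eta-squared is the between-bin sum of squares over the total
#' sum of squares of the per-movement spike counts (grand-mean one-way
#' decomposition, empty bins dropped).
#'
#' @param angles Movement angles in degrees.
#' @param counts Per-movement spike counts (same length).
#' @param n_bins Number of directional bins (default 12).
#' @return Eta-squared in `[0, 1]`; 0 when all counts are identical; `NA`
#'   when fewer than two bins are occupied.
#' @export
direction_eta_squared <- function(angles, counts, n_bins = 12) {
  if (length(angles) != length(counts))
    stop_invalid("angles and counts must have equal length")
  ok <- is.finite(angles) & is.finite(counts)
  angles <- angles[ok] %% 360
  counts <- counts[ok]
  bin <- floor(angles / (360 / n_bins)) + 1
  groups <- split(counts, bin)
  if (length(groups) < 2) return(NA_real_)
  grand <- mean(counts)
  ss_total <- sum((counts - grand)^2)
  if (ss_total == 0) return(0)
  ss_between <- sum(vapply(groups, function(g)
    length(g) * (mean(g) - grand)^2, 0))
  ss_between / ss_total
}

#' Variance in firing explained by movement amplitude
#'
#' Squared Pearson correlation between amplitude and spike count
#' (identical to the R-squared of the simple linear regression).
#'
#' @param amplitudes Movement amplitudes in mm (at least 3, with variance).
#' @param counts Per-movement spike counts.
#' @return r-squared in `[0, 1]`; 0 for zero count variance; `NA` for zero
#'   amplitude variance.
#' @export
amplitude_r_squared <- function(amplitudes, counts) {
  ok <- is.finite(amplitudes) & is.finite(counts)
  amplitudes <- amplitudes[ok]; counts <- counts[ok]
  if (length(amplitudes) < 3) stop_invalid("need at least 3 movements")
  if (var(amplitudes) == 0) return(NA_real_)
  if (var(counts) == 0) return(0)
  stats::cor(amplitudes, counts)^2
}

#' Selectivity class from tuning statistics
#'
#' Strict comparisons against the threshold: a neuron is selective only
#' when the statistic exceeds 0.1.
#'
#' @param eta_sq Direction eta-squared.
#' @param r_sq Amplitude r-squared.
#' @param threshold Selectivity threshold (default 0.1).
#' @return One of `"none"`, `"amplitude_only"`, `"direction_only"`,
#'   `"both"`; `NA` when either statistic is undefined.
#' @export
classify_selectivity <- function(eta_sq, r_sq, threshold = 0.1) {
  if (!is.finite(eta_sq) || !is.finite(r_sq)) return(NA_character_)
  d <- eta_sq > threshold
  a <- r_sq > threshold
  if (d && a) "both" else if (d) "direction_only"
  else if (a) "amplitude_only" else "none"
}

#' Direction and amplitude tuning of one neuron
#'
#' @param spikes A [spike_train()].
#' @param kin Kinematics table from [movement_kinematics()] for one class.
#' @param class `"twitch"` or `"wake"`.
#' @param config An `mp_config`.
#' @return One-row data frame: `neuron_id`, `eta_sq_direction`,
#'   `r_sq_amplitude`, `direction_selective`, `amplitude_selective`,
#'   `selectivity`, `n_movements`.
#' @export
neuron_tuning <- function(spikes, kin, class = c("twitch", "wake"),
                          config = default_config()) {
  class <- match.arg(class)
  thr <- config$kinematics$selectivity_threshold
  counts <- spike_count_in_activity_window(spikes, kin$onset_s, class, config)
  ok <- is.finite(kin$amplitude_mm) & is.finite(kin$angle_deg)
  eta <- direction_eta_squared(kin$angle_deg[ok], counts[ok],
                               config$kinematics$n_direction_bins)
  r2 <- amplitude_r_squared(kin$amplitude_mm[ok], counts[ok])
  data.frame(neuron_id = spikes$neuron_id,
             eta_sq_direction = eta, r_sq_amplitude = r2,
             direction_selective = is.finite(eta) && eta > thr,
             amplitude_selective = is.finite(r2) && r2 > thr,
             selectivity = classify_selectivity(eta, r2, thr),
             n_movements = sum(ok), stringsAsFactors = FALSE)
}

#' Split movements by evoked spike count
#'
#' Movements with at least 50% fewer spikes than expected from baseline
#' alone are non-preferred, movements with at least 50% more are preferred,
#' and the remainder stays unassigned. Both boundaries are inclusive, so
#' the reported integer thresholds are the largest integer at or below
#' `0.5 * expected` and the smallest integer at or above `1.5 * expected`
#' (2 and 6 for an expected count of 4).
#'
#' @param counts Per-movement spike counts in the post-onset window
#'   (conventionally 300 ms).
#' @param expected_count Expected baseline count in that window (> 0),
#'   i.e. baseline rate times window length.
#' @return List with integer indices `preferred`, `non_preferred`,
#'   `middle`, and the integer `non_preferred_threshold` /
#'   `preferred_threshold`.
#' @export
split_preferred_movements <- function(counts, expected_count) {
  if (!is.finite(expected_count) || expected_count <= 0)
    stop_invalid("expected_count must be positive")
  lo <- 0.5 * expected_count
  hi <- 1.5 * expected_count
  list(preferred = which(counts >= hi),
       non_preferred = which(counts <= lo),
       middle = which(counts > lo & counts < hi),
       non_preferred_threshold = as.integer(floor(lo)),
       preferred_threshold = as.integer(ceiling(hi)))
}
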