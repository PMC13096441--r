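# Synthetic-session generator: every downstream stage is testable by
# parameter recovery against the ground truth this module emits.

#' Simulation parameters
#'
#' Bundles all constants of the session generator. Defaults describe a
#' realistic infant-rat recording: sleep/wake cycling with roughly one-minute
#' dwell times, state-dependent baseline firing (13.1 spikes/s in REM vs
#' 7.2 spikes/s in wake, the regime reported for midbrain motor neurons at
#' this age), Poisson twitching confined to REM, spaced wake movements,
#' von Mises movement angles, log-normal amplitudes (twitches ~1 mm, wake
#' movements ~7 mm), 100 frames/s video with an LED pulse every 3 s, and a
#' small independent dropped-frame probability.
#'
#' @param session_duration Session length in seconds (> 0).
#' @param state_mean_durations Named numeric vector of mean exponential dwell
#'   times (s) per state; states cycle in the given order. Use a single entry
#'   for a one-state session.
#' @param baseline_rate Named numeric vector, baseline firing (spikes/s) per
#'   state. Missing states inherit the vector's mean.
#' @param twitch_rate Twitch rate (events/s) during REM, per body part.
#' @param wake_move_rate Wake-movement rate (events/s) during wake states.
#' @param twitch_body_parts Body parts that twitch.
#' @param angle_distribution List `list(mu_deg, kappa)` of the von Mises
#'   movement-angle distribution (math convention: degrees counterclockwise
#'   from +x, y up).
#' @param amplitude_distribution List with per-class log-normal parameters,
#'   `list(twitch = c(meanlog, sdlog), wake = c(meanlog, sdlog))` in mm.
#' @param response_kernel Per-class movement-locked rate kernels,
#'   `list(twitch = kernel, wake = kernel)` where a kernel is
#'   `list(latency_ms, sigma_ms, gain, premove_fraction)`: the kernel is a
#'   two-piece Gaussian with mode at `latency_ms`, right-hand width
#'   `sigma_ms`, total area `gain` (expected extra spikes per event) and
#'   fraction `premove_fraction` of its area before the event onset.
#' @param frame_rate Video frame rate (frames/s).
#' @param pulse_interval LED pulse interval (s).
#' @param dropped_frame_prob Independent per-frame drop probability in `[0, 1)`.
#' @param calibration_px_per_mm Video calibration (5.75 px/mm by default).
#' @param trajectory_noise_px SD of per-frame tracking jitter (pixels).
#' @param roi_noise_lambda Mean of the Poisson pixel-change noise floor.
#' @param roi_pulse_counts Pixel-change counts added during a movement.
#' @param seed Integer RNG seed; identical seed and parameters reproduce the
#'   session exactly.
#' @return A validated list of class `sim_params`.
#' @export
sim_params <- function(session_duration = 3600,
                       state_mean_durations = c(NREM = 120, REM = 45, quiet_wake = 75),
                       baseline_rate = c(NREM = 9, REM = 13.1,
                                         quiet_wake = 7.2, active_wake = 7.2),
                       twitch_rate = 0.2,
                       wake_move_rate = 0.1,
                       twitch_body_parts = c("forelimb", "hindlimb", "whiskers", "tail"),
                       angle_distribution = list(mu_deg = 0, kappa = 0.5),
                       amplitude_distribution = list(
                         twitch = c(meanlog = log(0.96) - 0.5 * 0.25, sdlog = 0.5),
                         wake = c(meanlog = log(6.95) - 0.5 * 0.36, sdlog = 0.6)),
                       response_kernel = list(
                         twitch = list(latency_ms = 30, sigma_ms = 20, gain = 10,
                                       premove_fraction = 0.15),
                         wake = list(latency_ms = 100, sigma_ms = 150, gain = 15,
                                     premove_fraction = 0.1)),
                       frame_rate = 100,
                       pulse_interval = 3,
                       dropped_frame_prob = 0.001,
                       calibration_px_per_mm = 5.75,
                       trajectory_noise_px = 0.3,
                       roi_noise_lambda = 2,
                       roi_pulse_counts = 50,
                       seed = 1L) {
  p <- list(session_duration = session_duration,
            state_mean_durations = state_mean_durations,
            baseline_rate = baseline_rate,
            twitch_rate = twitch_rate, wake_move_rate = wake_move_rate,
            twitch_body_parts = twitch_body_parts,
            angle_distribution = angle_distribution,
            amplitude_distribution = amplitude_distribution,
            response_kernel = response_kernel,
            frame_rate = frame_rate, pulse_interval = pulse_interval,
            dropped_frame_prob = dropped_frame_prob,
            calibration_px_per_mm = calibration_px_per_mm,
            trajectory_noise_px = trajectory_noise_px,
            roi_noise_lambda = roi_noise_lambda,
            roi_pulse_counts = roi_pulse_counts,
            seed = as.integer(seed))
  validate_sim_params(p)
}

validate_sim_params <- function(p) {
  if (!is.numeric(p$session_duration) || p$session_duration <= 0)
    stop_invalid("session_duration must be > 0")
  if (is.null(names(p$state_mean_durations)) ||
      any(!names(p$state_mean_durations) %in% STATE_LEVELS))
    stop_invalid("state_mean_durations must be named with states among: %s",
                 paste(STATE_LEVELS, collapse = ", "))
  if (any(p$state_mean_durations <= 0))
    stop_invalid("state mean durations must be > 0")
  for (r in c(p$baseline_rate, p$twitch_rate, p$wake_move_rate))
    if (!is.finite(r) || r < 0) stop_invalid("all rates must be finite and >= 0")
  for (k in p$response_kernel) {
    if (k$gain < 0) stop_invalid("kernel gain must be >= 0")
    if (k$sigma_ms <= 0) stop_invalid("kernel sigma_ms must be > 0")
    if (k$latency_ms < 0) stop_invalid("kernel latency_ms must be >= 0")
    if (k$premove_fraction < 0 || k$premove_fraction > 1)
      stop_invalid("premove_fraction must lie in [0, 1]")
  }
  if (p$dropped_frame_prob < 0 || p$dropped_frame_prob >= 1)
    stop_invalid("dropped_frame_prob must lie in [0, 1)")
  if (p$frame_rate <= 0 || p$pulse_interval <= 0)
    stop_invalid("frame_rate and pulse_interval must be > 0")
  class(p) <- c("sim_params", "list")
  p
}

## ---- movement-locked rate kernel: two-piece (split) Gaussian -------------
# Mode sits exactly at the latency; the left/right widths are chosen so the
# fraction of kernel mass before t = 0 equals premove_fraction. The split
# Gaussian reaches any premovement fraction in (0, 1) with the mode pinned,
# which a symmetric (or skewed unimodal with bounded skew) kernel cannot.

# Mass of a split normal (mode m, widths sl/sr) below 0, for m >= 0.
split_mass_before0 <- function(sl, sr, m) {
  2 * sl / (sl + sr) * pnorm(-m / sl)
}

#' Solve the two-piece Gaussian response kernel
#'
#' Given the kernel's mode (`latency_ms`), right-hand width (`sigma_ms`) and
#' target fraction of mass before the event onset, solves the left-hand
#' width. Used internally by the generator and exposed so tests can build
#' analytic reference kernels.
#'
#' @param kernel A kernel list (see [sim_params()]).
#' @return The kernel with `sl_s`, `sr_s`, `mode_s` (seconds) added, plus
#'   `true_width_ms`, the kernel's full width at half maximum.
#' @export
solve_kernel <- function(kernel) {
  m <- kernel$latency_ms / 1000
  sr <- kernel$sigma_ms / 1000
  p <- kernel$premove_fraction
  if (p <= 1e-6) {
    sl <- 1e-6
  } else if (m < 1e-12) {
    sl <- sr * p / (1 - p)          # closed form when the mode is at onset
  } else {
    f <- function(logsl) split_mass_before0(exp(logsl), sr, m) - p
    lo <- log(1e-6); hi <- log(1e4 * sr + 10 * m)
    if (f(hi) < 0)
      stop_invalid("premove_fraction %.3f unreachable at latency %.0f ms", p,
                   kernel$latency_ms)
    sl <- exp(uniroot(f, c(lo, hi), tol = 1e-12)$root)
  }
  kernel$sl_s <- sl
  kernel$sr_s <- sr
  kernel$mode_s <- m
  kernel$true_width_ms <- 1000 * sqrt(2 * log(2)) * (sl + sr)
  kernel
}

# Draw spike-time offsets from a solved split-Gaussian kernel.
rsplitnorm <- function(n, k) {
  left <- runif(n) < k$sl_s / (k$sl_s + k$sr_s)
  dev <- abs(rnorm(n))
  k$mode_s + ifelse(left, -dev * k$sl_s, dev * k$sr_s)
}

# Split-normal density (used by tests as an analytic rate trace).
#' Density of a solved response kernel
#' @param t Times in seconds relative to event onset.
#' @param kernel A kernel solved by [solve_kernel()].
#' @return Density values (1/s); integrates to 1.
#' @export
dkernel <- function(t, kernel) {
  s <- ifelse(t < kernel$mode_s, kernel$sl_s, kernel$sr_s)
  2 / (sqrt(2 * pi) * (kernel$sl_s + kernel$sr_s)) *
    exp(-(t - kernel$mode_s)^2 / (2 * s^2))
}

## ---- von Mises angles ----------------------------------------------------
# Best & Fisher (1979) rejection sampler; no installed package provides one.

#' Sample von Mises angles
#' @param n Number of draws.
#' @param mu_deg Mean direction in degrees.
#' @param kappa Concentration (>= 0); 0 is uniform, very large values
#'   degenerate to the mean direction.
#' @return Angles in degrees in `[0, 360)`.
#' @export
rvonmises_deg <- function(n, mu_deg, kappa) {
  if (kappa < 1e-8) return(runif(n, 0, 360))
  if (kappa > 1e6) return(rep((mu_deg %% 360), n))
  mu <- mu_deg * pi / 180
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  i <- 1L
  while (i <= n) {
    u <- runif(3)
    z <- cos(pi * u[1])
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    if (cc * (2 - cc) - u[2] > 0 || log(cc / u[2]) + 1 - cc >= 0) {
      out[i] <- mu + sign(u[3] - 0.5) * acos(max(-1, min(1, f)))
      i <- i + 1L
    }
  }
  (out * 180 / pi) %% 360
}

## ---- operations -----------------------------------------------------------

#' Simulate a behavioral state timeline
#'
#' States cycle in the order given by `names(params$state_mean_durations)`
#' with exponential dwell times; the final interval is truncated so the
#' intervals exactly partition `[0, session_duration]`.
#'
#' @param params A [sim_params()] object.
#' @return A [state_timeline()].
#' @export
simulate_state_timeline <- function(params) {
  params <- validate_sim_params(params)
  dur <- params$session_duration
  means <- params$state_mean_durations
  states <- names(means)
  if (length(states) == 1L)
    return(state_timeline(0, dur, states))
  starts <- c(); ends <- c(); labs <- c()
  t <- 0; i <- 1L
  while (t < dur) {
    d <- rexp(1, rate = 1 / means[[i]])
    e <- min(t + d, dur)
    starts <- c(starts, t); ends <- c(ends, e); labs <- c(labs, states[i])
    t <- e
    i <- if (i == length(states)) 1L else i + 1L
  }
  state_timeline(starts, ends, labs)
}

# Homogeneous Poisson arrivals restricted to a set of intervals.
poisson_in_intervals <- function(rate, starts, ends) {
  out <- numeric(0)
  for (j in seq_along(starts)) {
    len <- ends[j] - starts[j]
    n <- rpois(1, rate * len)
    if (n) out <- c(out, starts[j] + sort(runif(n, 0, len)))
  }
  out
}

#' Simulate scored movement events
#'
#' Twitches are Poisson events per body part confined to REM intervals; wake
#' movements occur only in wake intervals with at least 500 ms between
#' retained onsets (a greedy-from-left spacing rule on a denser Poisson
#' stream). Each event receives a true amplitude (log-normal, mm) and angle
#' (von Mises, degrees, math convention).
#'
#' @param timeline A [state_timeline()].
#' @param params A [sim_params()] object.
#' @param min_wake_gap Minimum spacing between wake-movement onsets (s).
#' @return A [movement_events()] table (possibly empty), sorted by onset.
#' @export
simulate_movement_events <- function(timeline, params, min_wake_gap = 0.5) {
  params <- validate_sim_params(params)
  if (is.null(timeline) || !nrow(timeline))
    return(movement_events(numeric(0), character(0), character(0)))
  rem <- timeline[timeline$state == "REM", , drop = FALSE]
  wake <- timeline[timeline$state %in% c("quiet_wake", "active_wake"), , drop = FALSE]
  onset <- numeric(0); part <- character(0); cls <- character(0)
  for (bp in params$twitch_body_parts) {
    tt <- poisson_in_intervals(params$twitch_rate, rem$start, rem$end)
    onset <- c(onset, tt)
    part <- c(part, rep(bp, length(tt)))
    cls <- c(cls, rep("twitch", length(tt)))
  }
  wt <- poisson_in_intervals(params$wake_move_rate, wake$start, wake$end)
  if (length(wt) > 1) {
    keep <- rep(FALSE, length(wt)); last <- -Inf
    for (i in seq_along(wt)) {
      if (wt[i] - last >= min_wake_gap) { keep[i] <- TRUE; last <- wt[i] }
    }
    wt <- wt[keep]
  }
  onset <- c(onset, wt)
  part <- c(part, rep("forelimb", length(wt)))
  cls <- c(cls, rep("wake", length(wt)))
  if (!length(onset))
    return(movement_events(numeric(0), character(0), character(0)))
  amp <- numeric(length(onset)); ang <- numeric(length(onset))
  for (cl in EVENT_CLASSES) {
    idx <- which(cls == cl)
    if (!length(idx)) next
    ad <- params$amplitude_distribution[[cl]]
    amp[idx] <- rlnorm(length(idx), ad[["meanlog"]], ad[["sdlog"]])
    ang[idx] <- rvonmises_deg(length(idx), params$angle_distribution$mu_deg,
                              params$angle_distribution$kappa)
  }
  movement_events(onset, part, cls, state = state_at(timeline, onset),
                  amplitude_mm = amp, angle_deg = ang)
}

#' Describe a simulated neuron
#'
#' @param neuron_id Identifier.
#' @param baseline_rate Named spikes/s per state (defaults to the session
#'   parameters' baseline).
#' @param kernels Per-class response kernels, as in [sim_params()]; set a
#'   class's gain to 0 (or drop it) for no response.
#' @param responsive_body_parts Twitch body parts this neuron responds to.
#' @param direction_tuning `list(mu_deg, kappa)` multiplicative von
#'   Mises-shaped gain profile (`kappa = 0` means untuned).
#' @param amplitude_slope Fractional gain increase per mm of movement
#'   amplitude (0 means untuned).
#' @param region Region label.
#' @return A list of class `neuron_spec`.
#' @export
neuron_spec <- function(neuron_id, baseline_rate = NULL, kernels = NULL,
                        responsive_body_parts = "forelimb",
                        direction_tuning = list(mu_deg = 0, kappa = 0),
                        amplitude_slope = 0, region = "M1") {
  structure(list(neuron_id = neuron_id, baseline_rate = baseline_rate,
                 kernels = kernels,
                 responsive_body_parts = responsive_body_parts,
                 direction_tuning = direction_tuning,
                 amplitude_slope = amplitude_slope, region = region),
            class = "neuron_spec")
}

#' Simulate one neuron's spike train
#'
#' Inhomogeneous Poisson process: a state-dependent homogeneous baseline
#' plus, for each event the neuron responds to, a two-piece Gaussian rate
#' bump of area `gain` with its mode at `latency_ms` and `premove_fraction`
#' of its mass before the onset. Direction tuning scales the per-event gain
#' by `exp(kappa * (cos(angle - mu) - 1))`; amplitude tuning by
#' `1 + amplitude_slope * amplitude_mm` (floored at 0).
#'
#' @param events A [movement_events()] table.
#' @param timeline A [state_timeline()].
#' @param params A [sim_params()] object.
#' @param neuron A [neuron_spec()]; defaults to a generic responsive neuron.
#' @return A [spike_train()] restricted to the session span.
#' @export
simulate_spike_train <- function(events, timeline, params, neuron = NULL) {
  params <- validate_sim_params(params)
  if (is.null(neuron)) neuron <- neuron_spec("sim_neuron")
  base <- neuron$baseline_rate
  if (is.null(base)) base <- params$baseline_rate
  if (any(base < 0)) stop_invalid("baseline rates must be >= 0")
  kernels <- neuron$kernels
  if (is.null(kernels)) kernels <- params$response_kernel
  span <- timeline_span(timeline)
  rate_for <- function(st) {
    if (st %in% names(base)) base[[st]] else mean(base)
  }
  spikes <- numeric(0)
  for (j in seq_len(nrow(timeline))) {
    spikes <- c(spikes, poisson_in_intervals(rate_for(timeline$state[j]),
                                             timeline$start[j], timeline$end[j]))
  }
  if (nrow(events)) {
    solved <- lapply(kernels, solve_kernel)
    for (i in seq_len(nrow(events))) {
      cl <- events$class[i]
      k <- solved[[cl]]
      if (is.null(k) || k$gain <= 0) next
      if (cl == "twitch" &&
          !events$body_part[i] %in% neuron$responsive_body_parts) next
      g <- k$gain
      dt <- neuron$direction_tuning
      if (!is.null(dt) && dt$kappa > 0 && is.finite(events$angle_deg[i])) {
        g <- g * exp(dt$kappa *
                       (cos((events$angle_deg[i] - dt$mu_deg) * pi / 180) - 1))
      }
      if (neuron$amplitude_slope != 0 && is.finite(events$amplitude_mm[i])) {
        g <- g * max(0, 1 + neuron$amplitude_slope * events$amplitude_mm[i])
      }
      n <- rpois(1, g)
      if (n) spikes <- c(spikes, events$onset_s[i] + rsplitnorm(n, k))
    }
  }
  spikes <- sort(spikes)
  spikes <- spikes[spikes >= span[1] & spikes <= span[2]]
  spike_train(neuron$neuron_id, spikes, span = span, region = neuron$region)
}

#' Simulate a limb trajectory
#'
#' Renders per-frame x/y positions (pixels, image coordinates: y increases
#' downward) of one tracked body part. Each forelimb event produces a
#' raised-cosine excursion whose peak displacement equals the event's true
#' amplitude (mm x calibration) in the direction of its true angle (math
#' convention, so the image y-component is negated). Gaussian tracking
#' jitter is added to every frame.
#'
#' @param events A [movement_events()] table; only forelimb events are
#'   rendered (twitch excursions span 160 ms, wake excursions 500 ms).
#' @param params A [sim_params()] object.
#' @param duration Session duration (s); defaults to the parameter value.
#' @param origin Resting position in pixels.
#' @return A [trajectory()] at the video frame rate.
#' @export
simulate_trajectory <- function(events, params, duration = NULL,
                                origin = c(x = 360, y = 270)) {
  params <- validate_sim_params(params)
  if (params$frame_rate <= 0) stop_invalid("frame_rate must be > 0")
  if (is.null(duration)) duration <- params$session_duration
  fr <- params$frame_rate
  n <- floor(duration * fr) + 1L
  tt <- (seq_len(n) - 1L) / fr
  x <- rep(origin[["x"]], n)
  y <- rep(origin[["y"]], n)
  ev <- events[events$body_part == "forelimb", , drop = FALSE]
  for (i in seq_len(nrow(ev))) {
    w <- if (ev$class[i] == "twitch") 0.16 else 0.5
    k <- 2L * ceiling(w * fr / 2)           # even frame count: exact mid peak
    i0 <- round(ev$onset_s[i] * fr) + 1L
    jj <- i0:(i0 + k)
    ok <- jj >= 1L & jj <= n
    prof <- sin(pi * (0:k) / k)^2           # 0 at ends, exactly 1 at k/2
    amp_px <- ev$amplitude_mm[i] * params$calibration_px_per_mm
    th <- ev$angle_deg[i] * pi / 180
    x[jj[ok]] <- x[jj[ok]] + amp_px * cos(th) * prof[ok]
    y[jj[ok]] <- y[jj[ok]] - amp_px * sin(th) * prof[ok]   # image y is flipped
  }
  if (params$trajectory_noise_px > 0) {
    x <- x + rnorm(n, 0, params$trajectory_noise_px)
    y <- y + rnorm(n, 0, params$trajectory_noise_px)
  }
  trajectory(seq_len(n) - 1L, tt, x, y, likelihood = 1,
             bodypart = "forelimb",
             calibration = params$calibration_px_per_mm)
}

#' Simulate an ROI pixel-change series
#'
#' 100 Hz (by default) non-negative integer counts: a Poisson noise floor
#' plus, per event, a rectangular pulse of elevated counts starting exactly
#' at the event's onset frame (10 frames for twitches, 30 for wake
#' movements).
#'
#' @param events Events whose `body_part` matches `roi_label` (use
#'   `"whole_body"` conventions upstream for whole-animal ROIs).
#' @param params A [sim_params()] object.
#' @param duration Session duration (s).
#' @param roi_label ROI name; only events of this body part are rendered.
#' @return A [pixel_change_series()], plus an attribute `onset_frames`
#'   (1-based first elevated frame per rendered event, in event order).
#' @export
simulate_pixel_change_series <- function(events, params, duration = NULL,
                                         roi_label = "forelimb") {
  params <- validate_sim_params(params)
  if (is.null(duration)) duration <- params$session_duration
  fr <- params$frame_rate
  n <- floor(duration * fr) + 1L
  vals <- if (params$roi_noise_lambda > 0) rpois(n, params$roi_noise_lambda)
          else integer(n)
  ev <- events[events$body_part == roi_label, , drop = FALSE]
  onset_frames <- integer(0)
  for (i in seq_len(nrow(ev))) {
    len <- if (ev$class[i] == "twitch") 10L else 30L
    i0 <- round(ev$onset_s[i] * fr) + 1L
    jj <- i0:min(i0 + len - 1L, n)
    jj <- jj[jj >= 1L]
    vals[jj] <- vals[jj] + params$roi_pulse_counts
    onset_frames <- c(onset_frames, i0)
  }
  out <- pixel_change_series(vals, frame_rate = fr, roi_label = roi_label)
  attr(out, "onset_frames") <- onset_frames
  out
}

#' Simulate a video frame clock with dropped frames
#'
#' Nominal frame timestamps at the frame rate, each deleted independently
#' with probability `dropped_frame_prob`; LED pulse times every
#' `pulse_interval` seconds starting at t = 0.
#'
#' @param params A [sim_params()] object.
#' @param duration Session duration (s).
#' @return A [frame_clock()] with attribute `dropped_indices` (1-based
#'   indices into the nominal frame grid that were deleted).
#' @export
simulate_frame_clock <- function(params, duration = NULL) {
  params <- validate_sim_params(params)
  if (is.null(duration)) duration <- params$session_duration
  fr <- params$frame_rate
  nominal <- seq(0, duration, by = 1 / fr)
  drop <- which(rbinom(length(nominal), 1, params$dropped_frame_prob) == 1L)
  keep_times <- if (length(drop)) nominal[-drop] else nominal
  pulses <- seq(0, duration, by = params$pulse_interval)
  out <- frame_clock(keep_times, pulses, frame_rate = fr,
                     pulse_interval = params$pulse_interval)
  attr(out, "dropped_indices") <- drop
  out
}

#' Simulate state-scoring feature traces
#'
#' Nuchal EMG tone and cortical delta-power surrogates sampled at `fs` Hz:
#' tone is low (atonia) in REM, moderate in NREM and high in wake; delta
#' power is high in NREM and low elsewhere; both carry Gaussian noise.
#'
#' @param timeline A [state_timeline()].
#' @param fs Sampling rate (Hz).
#' @param noise_sd Noise SD relative to the unit state contrasts.
#' @return List of two data frames `tone` and `delta`, each `(time, value)`.
#' @export
simulate_state_features <- function(timeline, fs = 10, noise_sd = 0.05) {
  span <- timeline_span(timeline)
  tt <- seq(span[1], span[2] - 1 / fs, by = 1 / fs)
  st <- state_at(timeline, tt)
  tone_mu <- c(NREM = 0.5, REM = 0.05, quiet_wake = 1, active_wake = 1)
  delta_mu <- c(NREM = 1, REM = 0.1, quiet_wake = 0.2, active_wake = 0.2)
  tone <- tone_mu[st] + rnorm(length(tt), 0, noise_sd)
  delta <- delta_mu[st] + rnorm(length(tt), 0, noise_sd)
  list(tone = data.frame(time = tt, value = as.numeric(tone)),
       delta = data.frame(time = tt, value = as.numeric(delta)))
}

#' Simulate a rectified EMG trace locked to movements
#'
#' Baseline half-normal noise plus a burst at each event onset, used to
#' exercise the EMG inclusion rule.
#'
#' @param events Events to receive bursts.
#' @param duration Trace duration (s).
#' @param fs Sampling rate (Hz).
#' @param burst_amp Burst amplitude in baseline-SD units.
#' @return Data frame `(time, value)`, `value >= 0`.
#' @export
simulate_emg <- function(events, duration, fs = 1000, burst_amp = 6) {
  tt <- seq(0, duration, by = 1 / fs)
  v <- abs(rnorm(length(tt), 0, 1))
  for (on in events$onset_s) {
    jj <- which(tt >= on & tt <= on + 0.08)
    v[jj] <- v[jj] + burst_amp * sin(pi * seq_along(jj) / max(1, length(jj)))
  }
  data.frame(time = tt, value = v)
}

#' Simulate a complete session with ground truth
#'
#' Runs every generator in sequence under the parameter seed and returns the
#' streams a real recording would provide (state timeline features, scored
#' events, spike trains, forelimb trajectory, per-body-part ROI series,
#' frame clock, EMG) together with a `ground_truth` list holding the true
#' timeline, events (with true kinematics), per-neuron kernel truths
#' (latency, width at half maximum, premovement fraction) and dropped-frame
#' indices.
#'
#' @param params A [sim_params()] object.
#' @param neurons List of [neuron_spec()]s; default is a single generic
#'   responsive neuron.
#' @return A list of class `sim_session`.
#' @export
simulate_session <- function(params, neurons = NULL) {
  params <- validate_sim_params(params)
  set.seed(params$seed)
  if (is.null(neurons)) neurons <- list(neuron_spec("n1"))
  timeline <- simulate_state_timeline(params)
  events <- simulate_movement_events(timeline, params)
  trains <- lapply(neurons, function(nn)
    simulate_spike_train(events, timeline, params, nn))
  names(trains) <- vapply(trains, `[[`, "", "neuron_id")
  traj <- simulate_trajectory(events, params)
  rois <- lapply(setNames(nm = params$twitch_body_parts), function(bp)
    simulate_pixel_change_series(events, params, roi_label = bp))
  clock <- simulate_frame_clock(params)
  features <- simulate_state_features(timeline)
  emg <- simulate_emg(events[events$body_part == "forelimb", , drop = FALSE],
                      duration = min(params$session_duration, 600))
  truth_neurons <- lapply(neurons, function(nn) {
    kernels <- nn$kernels
    if (is.null(kernels)) kernels <- params$response_kernel
    lapply(kernels, function(k) {
      s <- solve_kernel(k)
      list(latency_ms = k$latency_ms, width_ms = s$true_width_ms,
           premove_fraction = k$premove_fraction, gain = k$gain)
    })
  })
  names(truth_neurons) <- names(trains)
  structure(list(
    params = params,
    timeline = timeline,
    events = events,
    spike_trains = trains,
    trajectory = traj,
    roi_series = rois,
    frame_clock = clock,
    features = features,
    emg = emg,
    ground_truth = list(
      timeline = timeline,
      events = events,
      neurons = truth_neurons,
      dropped_frame_indices = attr(clock, "dropped_indices"),
      roi_onset_frames = lapply(rois, attr, "onset_frames")
    )), class = "sim_session")
}

#' @export
print.sim_session <- function(x, ...) {
  cat(sprintf("<sim_session> %.0f s, %d states, %d events, %d neurons (seed %d)\n",
              x$params$session_duration, nrow(x$timeline), nrow(x$events),
              length(x$spike_trains), x$params$seed))
  invisible(x)
}
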