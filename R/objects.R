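# Core S3 containers shared across modules.

STATE_LEVELS <- c("NREM", "REM", "quiet_wake", "active_wake")
BODY_PARTS <- c("forelimb", "hindlimb", "whiskers", "tail", "whole_body")
EVENT_CLASSES <- c("twitch", "wake")

#' Construct a spike train
#'
#' A single neuron's sorted spike times over one recording session.
#'
#' @param neuron_id Character scalar identifier.
#' @param times Numeric spike times in seconds.
#' @param span Length-2 numeric session span `[t0, t1]`; defaults to
#'   `[0, max(times)]` (or `[0, 0]` for an empty train).
#' @param region Optional region label (e.g. `"M1"`, `"RN"`).
#' @return An object of class `spike_train` with elements `neuron_id`,
#'   `times` (sorted, strictly inside the span), `span` and `region`.
#' @export
spike_train <- function(neuron_id, times, span = NULL, region = NA_character_) {
  times <- as.numeric(times)
  if (anyNA(times)) stop_invalid("spike times must not contain NaN/NA")
  if (is.unsorted(times)) {
    mp_log("warn", "spike times for ", neuron_id, " were unsorted; sorting")
    times <- sort(times)
  }
  if (is.null(span)) span <- c(0, if (length(times)) max(times) else 0)
  span <- as.numeric(span)
  if (length(span) != 2 || span[1] > span[2])
    stop_invalid("span must be an ordered [t0, t1] pair")
  if (length(times) && (times[1] < span[1] || times[length(times)] > span[2]))
    stop_invalid("spike times fall outside the session span")
  structure(list(neuron_id = as.character(neuron_id), times = times,
                 span = span, region = as.character(region)),
            class = "spike_train")
}

#' @export
print.spike_train <- function(x, ...) {
  dur <- diff(x$span)
  cat(sprintf("<spike_train> %s (%s): %d spikes over %.1f s (%.2f spikes/s)\n",
              x$neuron_id, x$region, length(x$times), dur,
              if (dur > 0) length(x$times) / dur else NA_real_))
  invisible(x)
}

#' Construct a behavioral state timeline
#'
#' Non-overlapping labeled intervals (NREM, REM, quiet_wake, active_wake)
#' that exactly partition the session span. Intervals are half-open
#' `[start, end)`.
#'
#' @param start,end Numeric interval bounds in seconds.
#' @param state Character state labels, one of
#'   `r paste(STATE_LEVELS, collapse = ", ")`.
#' @return A data frame of class `state_timeline` with columns
#'   `start`, `end`, `state`.
#' @export
state_timeline <- function(start, end, state) {
  df <- data.frame(start = as.numeric(start), end = as.numeric(end),
                   state = as.character(state), stringsAsFactors = FALSE)
  if (!nrow(df)) stop_invalid("a state timeline needs at least one interval")
  bad <- setdiff(unique(df$state), STATE_LEVELS)
  if (length(bad)) stop_invalid("unknown state label(s): %s (allowed: %s)",
                                paste(bad, collapse = ", "),
                                paste(STATE_LEVELS, collapse = ", "))
  df <- df[order(df$start), , drop = FALSE]
  rownames(df) <- NULL
  if (any(df$end <= df$start)) stop_invalid("state intervals must have end > start")
  if (nrow(df) > 1 && any(abs(df$start[-1] - df$end[-nrow(df)]) > 1e-9))
    stop_invalid("state intervals must partition the span with no gaps/overlaps")
  class(df) <- c("state_timeline", "data.frame")
  df
}

#' Session span of a state timeline
#' @param timeline A `state_timeline`.
#' @return Length-2 numeric `[t0, t1]`.
#' @export
timeline_span <- function(timeline) {
  c(timeline$start[1], timeline$end[nrow(timeline)])
}

#' State label at given times
#' @param timeline A `state_timeline`.
#' @param t Numeric times (seconds).
#' @return Character vector of state labels (`NA` outside the span);
#'   intervals are half-open `[start, end)`, the final end point maps to the
#'   last interval.
#' @export
state_at <- function(timeline, t) {
  idx <- findInterval(t, timeline$start)
  out <- rep(NA_character_, length(t))
  ok <- idx >= 1 & t <= timeline_span(timeline)[2]
  out[ok] <- timeline$state[idx[ok]]
  out
}

#' Construct a movement-event table
#'
#' @param onset Numeric onset times in seconds.
#' @param body_part Character body-part labels
#'   (`r paste(BODY_PARTS, collapse = ", ")`).
#' @param class `"twitch"` or `"wake"`.
#' @param state Behavioral state at onset (optional).
#' @param amplitude_mm,angle_deg Optional kinematics.
#' @return A data frame of class `movement_events`, sorted by onset.
#' @export
movement_events <- function(onset, body_part, class,
                            state = NA_character_,
                            amplitude_mm = NA_real_, angle_deg = NA_real_) {
  n <- length(onset)
  df <- data.frame(onset_s = as.numeric(onset),
                   body_part = rep_len(as.character(body_part), n),
                   class = rep_len(as.character(class), n),
                   state = rep_len(as.character(state), n),
                   amplitude_mm = rep_len(as.numeric(amplitude_mm), n),
                   angle_deg = rep_len(as.numeric(angle_deg), n),
                   stringsAsFactors = FALSE)
  if (n) {
    badc <- setdiff(unique(df$class), EVENT_CLASSES)
    if (length(badc))
      stop_invalid("unknown event class label(s): %s (allowed: %s)",
                   paste(badc, collapse = ", "),
                   paste(EVENT_CLASSES, collapse = ", "))
    badb <- setdiff(unique(df$body_part), BODY_PARTS)
    if (length(badb))
      stop_invalid("unknown body part(s): %s (allowed: %s)",
                   paste(badb, collapse = ", "),
                   paste(BODY_PARTS, collapse = ", "))
    df <- df[order(df$onset_s), , drop = FALSE]
    rownames(df) <- NULL
  }
  class(df) <- c("movement_events", "data.frame")
  df
}

#' Construct a limb trajectory
#'
#' Per-frame x/y position (pixels, image coordinates with y increasing
#' downward) of a tracked body part, with a tracking-likelihood column.
#'
#' @param frame_index Integer 0-based frame indices.
#' @param time Frame times in seconds (strictly increasing).
#' @param x,y Position in pixels.
#' @param likelihood Tracking confidence in `[0, 1]`.
#' @param bodypart Body-part label.
#' @param calibration Pixels per mm (> 0); the conventional video
#'   calibration is 5.75 px/mm.
#' @return A data frame of class `trajectory` with the calibration and
#'   body part stored as attributes.
#' @export
trajectory <- function(frame_index, time, x, y, likelihood = 1,
                       bodypart = "forelimb", calibration = 5.75) {
  n <- length(time)
  if (n && is.unsorted(time, strictly = TRUE))
    stop_invalid("trajectory frame times must be strictly increasing")
  if (!is.numeric(calibration) || calibration <= 0)
    stop_invalid("calibration (px/mm) must be positive")
  df <- data.frame(frame_index = as.integer(frame_index),
                   time = as.numeric(time), x = as.numeric(x),
                   y = as.numeric(y),
                   likelihood = rep_len(as.numeric(likelihood), n))
  attr(df, "bodypart") <- as.character(bodypart)
  attr(df, "calibration") <- as.numeric(calibration)
  class(df) <- c("trajectory", "data.frame")
  df
}

#' Construct an ROI pixel-change series
#'
#' Per-frame count of pixels whose intensity changed by more than the
#' pixel-change criterion (conventionally 5%), one value per video frame.
#'
#' @param values Non-negative integer counts.
#' @param frame_rate Frames per second (default 100).
#' @param roi_label ROI name (usually a body part).
#' @param roi_size ROI area in pixels (optional).
#' @param t0 Time of the first frame (seconds).
#' @return An object of class `pixel_change_series`.
#' @export
pixel_change_series <- function(values, frame_rate = 100,
                                roi_label = "forelimb", roi_size = NA_integer_,
                                t0 = 0) {
  values <- as.integer(round(values))
  if (anyNA(values) || any(values < 0))
    stop_invalid("pixel-change values must be non-negative integers")
  structure(list(values = values, frame_rate = as.numeric(frame_rate),
                 roi_label = as.character(roi_label),
                 roi_size = as.integer(roi_size), t0 = as.numeric(t0)),
            class = "pixel_change_series")
}

#' Frame times of a pixel-change series
#' @param series A `pixel_change_series`.
#' @return Numeric frame times in seconds.
#' @export
series_times <- function(series) {
  series$t0 + (seq_along(series$values) - 1) / series$frame_rate
}

#' Construct a video frame clock
#'
#' @param frame_times Strictly increasing frame timestamps (seconds, on the
#'   electrophysiology clock).
#' @param pulse_times Sorted LED sync-pulse onset times (seconds).
#' @param frame_rate Nominal frame rate (frames/s).
#' @param pulse_interval Nominal inter-pulse interval (seconds, > 0).
#' @param dummy_flags Logical per frame; `TRUE` marks inserted dummy frames.
#' @return An object of class `frame_clock`.
#' @export
frame_clock <- function(frame_times, pulse_times, frame_rate = 100,
                        pulse_interval = 3, dummy_flags = NULL) {
  frame_times <- as.numeric(frame_times)
  if (length(frame_times) && is.unsorted(frame_times, strictly = TRUE))
    stop_invalid("frame times must be strictly increasing")
  if (pulse_interval <= 0) stop_invalid("pulse_interval must be positive")
  if (is.null(dummy_flags)) dummy_flags <- rep(FALSE, length(frame_times))
  if (length(dummy_flags) != length(frame_times))
    stop_invalid("dummy_flags must have one entry per frame")
  structure(list(frame_times = frame_times,
                 pulse_times = sort(as.numeric(pulse_times)),
                 frame_rate = as.numeric(frame_rate),
                 pulse_interval = as.numeric(pulse_interval),
                 dummy_flags = as.logical(dummy_flags)),
            class = "frame_clock")
}

#' @export
print.frame_clock <- function(x, ...) {
  cat(sprintf("<frame_clock> %d frames at %g fps, %d pulses every %g s, %d dummies\n",
              length(x$frame_times), x$frame_rate, length(x$pulse_times),
              x$pulse_interval, sum(x$dummy_flags)))
  invisible(x)
}
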