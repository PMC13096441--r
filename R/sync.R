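# Frame-clock validation and repair against LED sync pulses. A pulse every
# pulse_interval seconds at frame_rate frames/s implies an exact expected
# frame count per inter-pulse gap; missing frames are restored as flagged
# dummy frames so video-scored events stay aligned to the
# electrophysiology clock within one frame.

#' Expected frames between sync pulses
#'
#' @param frame_rate Frames per second (> 0).
#' @param pulse_interval Seconds between LED pulses (> 0).
#' @return `pulse_interval * frame_rate` as an exact integer; a non-integer
#'   product (tolerance 1e-9) is a configuration error.
#' @examples
#' expected_interpulse_frames(100, 3)   # 300
#' @export
expected_interpulse_frames <- function(frame_rate, pulse_interval) {
  if (frame_rate <= 0 || pulse_interval <= 0)
    stop_invalid("frame_rate and pulse_interval must be positive")
  prod <- frame_rate * pulse_interval
  if (abs(prod - round(prod)) > 1e-9)
    stop_invalid("frame_rate x pulse_interval = %g is not an integer frame count",
                 prod)
  as.integer(round(prod))
}

#' Check inter-pulse frame counts for dropped frames
#'
#' Counts the frames within each half-open inter-pulse gap
#' `[pulse_i, pulse_{i+1})` and compares with the expected count.
#'
#' @param clock A [frame_clock()].
#' @return Data frame with one row per gap: `gap` (index), `observed`
#'   frames, and `deficit` = expected - observed (negative for surplus
#'   frames). Fewer than two pulses yields an empty report with a warning.
#' @export
validate_frame_intervals <- function(clock) {
  expected <- expected_interpulse_frames(clock$frame_rate, clock$pulse_interval)
  np <- length(clock$pulse_times)
  if (np < 2) {
    warning("fewer than 2 sync pulses; no gaps to validate", call. = FALSE)
    return(data.frame(gap = integer(0), observed = integer(0),
                      deficit = integer(0)))
  }
  counts <- integer(np - 1)
  for (i in seq_len(np - 1)) {
    counts[i] <- sum(clock$frame_times >= clock$pulse_times[i] &
                     clock$frame_times < clock$pulse_times[i + 1])
  }
  data.frame(gap = seq_len(np - 1), observed = counts,
             deficit = expected - counts)
}

#' Repair a frame clock by inserting dummy frames
#'
#' For every inter-pulse gap with a frame deficit, the nominal frame grid of
#' that gap is reconstructed and each unoccupied grid slot receives a dummy
#' frame at its nominal time, so the repaired clock has the expected frame
#' count in every gap, dummies are flagged, and every frame sits within half
#' a frame of its nominal time. Repair is idempotent. Gaps with surplus
#' frames cannot be repaired and raise an error.
#'
#' @param clock A [frame_clock()].
#' @return A repaired [frame_clock()].
#' @export
repair_frame_clock <- function(clock) {
  report <- validate_frame_intervals(clock)
  if (!nrow(report) || all(report$deficit == 0)) return(clock)
  if (any(report$deficit < 0))
    stop_invalid("gap(s) %s contain surplus frames; clock is unrecoverable",
                 paste(report$gap[report$deficit < 0], collapse = ", "))
  expected <- expected_interpulse_frames(clock$frame_rate, clock$pulse_interval)
  step <- 1 / clock$frame_rate
  new_times <- clock$frame_times
  new_flags <- clock$dummy_flags
  for (i in report$gap[report$deficit > 0]) {
    p0 <- clock$pulse_times[i]
    slots <- p0 + (seq_len(expected) - 1) * step
    gapf <- clock$frame_times[clock$frame_times >= p0 &
                              clock$frame_times < clock$pulse_times[i + 1]]
    occupied <- rep(FALSE, expected)
    if (length(gapf)) {
      slot_of <- pmin(pmax(round((gapf - p0) / step) + 1, 1), expected)
      occupied[slot_of] <- TRUE
    }
    ins <- slots[!occupied]
    ins <- utils::head(ins, report$deficit[report$gap == i])
    mp_log("info", sprintf("gap %d: inserting %d dummy frame(s)", i, length(ins)))
    new_times <- c(new_times, ins)
    new_flags <- c(new_flags, rep(TRUE, length(ins)))
  }
  ord <- order(new_times)
  frame_clock(new_times[ord], clock$pulse_times,
              frame_rate = clock$frame_rate,
              pulse_interval = clock$pulse_interval,
              dummy_flags = new_flags[ord])
}
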