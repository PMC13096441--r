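# Readers and writers for all tabular inputs and results. All times are
# seconds (float), frame indices 0-based, intervals half-open [start, end).
# Numeric columns are written with 17 significant digits so that
# write -> read round-trips are bit identical.

fmt_num <- function(x) {
  out <- sprintf("%.17g", x)
  out[is.na(x)] <- "NA"
  out
}

#' Write a spike table
#'
#' One row per spike with columns `neuron_id`, `time_s` (and `region` when
#' any train carries one), full double precision.
#'
#' @param trains A [spike_train()] or list of them.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_spike_table <- function(trains, path) {
  if (inherits(trains, "spike_train")) trains <- list(trains)
  rows <- lapply(trains, function(tr) {
    data.frame(neuron_id = rep(tr$neuron_id, length(tr$times)),
               time_s = fmt_num(tr$times),
               region = rep(tr$region, length(tr$times)),
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  if (is.null(df)) df <- data.frame(neuron_id = character(0),
                                    time_s = character(0),
                                    region = character(0))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a spike table
#'
#' @param path CSV with header columns `neuron_id`, `time_s` (optional
#'   `region`). Times are sorted on load (with a warning when input was
#'   unsorted); NaN times are rejected.
#' @param span Optional session span applied to every train.
#' @return A named list of [spike_train()]s, one per neuron id (possibly
#'   empty).
#' @export
read_spike_table <- function(path, span = NULL) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  for (col in c("neuron_id", "time_s"))
    if (!col %in% names(df))
      stop_invalid("spike table %s is missing required column '%s'", path, col)
  if (!nrow(df)) return(list())
  if (anyNA(df$time_s)) stop_invalid("spike table %s contains NaN/NA times", path)
  region <- if ("region" %in% names(df)) df$region else NA_character_
  ids <- unique(df$neuron_id)
  if (is.null(span)) span <- c(0, max(df$time_s))
  out <- lapply(ids, function(id) {
    sel <- df$neuron_id == id
    spike_train(id, df$time_s[sel], span = span,
                region = if (all(is.na(region))) NA_character_
                         else region[sel][1])
  })
  names(out) <- ids
  out
}

#' Write a movement-event table
#'
#' Columns `onset_s`, `body_part`, `class`, `state`, `amplitude_mm`,
#' `angle_deg`. An empty event list produces a header-only file.
#'
#' @param events A [movement_events()] table.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_event_table <- function(events, path) {
  df <- as.data.frame(events)
  df$onset_s <- fmt_num(df$onset_s)
  df$amplitude_mm <- fmt_num(df$amplitude_mm)
  df$angle_deg <- fmt_num(df$angle_deg)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a movement-event table
#'
#' @param path CSV with columns `onset_s`, `body_part`,
#'   `class` (in `twitch`/`wake`), `state`; optional kinematics columns.
#'   Unknown class labels raise a format error naming the allowed labels.
#' @return A [movement_events()] table sorted by onset.
#' @export
read_event_table <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE,
                 colClasses = c(state = "character"))
  for (col in c("onset_s", "body_part", "class"))
    if (!col %in% names(df))
      stop_invalid("event table %s is missing required column '%s'", path, col)
  if (anyNA(df$onset_s)) stop_invalid("event table %s contains NaN/NA onsets", path)
  movement_events(df$onset_s, df$body_part, df$class,
                  state = if ("state" %in% names(df)) df$state else NA,
                  amplitude_mm = if ("amplitude_mm" %in% names(df))
                    df$amplitude_mm else NA_real_,
                  angle_deg = if ("angle_deg" %in% names(df))
                    df$angle_deg else NA_real_)
}

#' Write a pose table (3-header-row CSV dialect)
#'
#' Emits the scorer / bodyparts / coords header triple used by markerless
#' tracking tools, with x, y, likelihood columns per body part.
#'
#' @param trajs A [trajectory()] or list of them (one per body part, on a
#'   common frame grid).
#' @param path Output CSV path.
#' @param scorer Scorer name placed in the first header row.
#' @return `path`, invisibly.
#' @export
write_pose_table <- function(trajs, path, scorer = "synthetic") {
  if (inherits(trajs, "trajectory")) trajs <- list(trajs)
  bps <- vapply(trajs, function(tr) attr(tr, "bodypart"), "")
  n <- nrow(trajs[[1]])
  hdr1 <- c("scorer", rep(scorer, 3 * length(trajs)))
  hdr2 <- c("bodyparts", rep(bps, each = 3))
  hdr3 <- c("coords", rep(c("x", "y", "likelihood"), length(trajs)))
  body <- matrix("", nrow = n, ncol = 1 + 3 * length(trajs))
  body[, 1] <- as.character(seq_len(n) - 1L)
  for (j in seq_along(trajs)) {
    tr <- trajs[[j]]
    body[, 3 * j - 1] <- fmt_num(tr$x)
    body[, 3 * j] <- fmt_num(tr$y)
    body[, 3 * j + 1] <- fmt_num(tr$likelihood)
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste(hdr1, collapse = ","),
               paste(hdr2, collapse = ","),
               paste(hdr3, collapse = ",")), con)
  writeLines(apply(body, 1, paste, collapse = ","), con)
  invisible(path)
}

#' Read a pose table (3-header-row CSV dialect)
#'
#' Parses the scorer / bodyparts / coords header triple and returns one
#' trajectory per body part. Points with likelihood below `flag_likelihood`
#' are flagged (logged), not dropped. A missing likelihood column is filled
#' with 1.0 and logged.
#'
#' @param path CSV path.
#' @param calibration Pixels per mm stored on every trajectory (default the
#'   conventional 5.75 px/mm).
#' @param frame_rate Frames/s used to assign times when no clock is given.
#' @param clock Optional [frame_clock()]; its frame times are used instead
#'   of the nominal rate.
#' @param flag_likelihood Likelihood below which points are flagged.
#' @return Named list of [trajectory()] objects, one per body part.
#' @export
read_pose_table <- function(path, calibration = 5.75, frame_rate = 100,
                            clock = NULL, flag_likelihood = 0.85) {
  raw <- read.csv(path, header = FALSE, stringsAsFactors = FALSE)
  if (nrow(raw) < 3 ||
      tolower(raw[1, 1]) != "scorer" ||
      tolower(raw[2, 1]) != "bodyparts" ||
      tolower(raw[3, 1]) != "coords")
    stop_invalid("%s: malformed pose header (expected scorer/bodyparts/coords rows)",
                 path)
  bps <- as.character(unlist(raw[2, -1]))
  coords <- tolower(as.character(unlist(raw[3, -1])))
  data <- raw[-(1:3), , drop = FALSE]
  n <- nrow(data)
  times <- if (!is.null(clock)) {
    if (length(clock$frame_times) < n)
      stop_invalid("frame clock has fewer frames (%d) than pose rows (%d)",
                   length(clock$frame_times), n)
    clock$frame_times[seq_len(n)]
  } else (seq_len(n) - 1L) / frame_rate
  out <- list()
  for (bp in unique(bps)) {
    cols <- which(bps == bp) + 1L                   # +1: first column is index
    cc <- coords[cols - 1L]
    xi <- cols[match("x", cc)]; yi <- cols[match("y", cc)]
    li <- cols[match("likelihood", cc)]
    if (is.na(xi) || is.na(yi))
      stop_invalid("%s: body part '%s' lacks x/y columns", path, bp)
    lk <- if (is.na(li)) {
      mp_log("info", "pose table ", path, ": no likelihood column for ", bp,
             "; filled with 1.0")
      rep(1, n)
    } else as.numeric(data[[li]])
    tr <- trajectory(seq_len(n) - 1L, times,
                     as.numeric(data[[xi]]), as.numeric(data[[yi]]),
                     likelihood = lk, bodypart = bp, calibration = calibration)
    nlow <- sum(tr$likelihood < flag_likelihood, na.rm = TRUE)
    if (nlow) mp_log("info", "pose table ", path, ": ", nlow, " ", bp,
                     " points below likelihood ", flag_likelihood, " (kept)")
    out[[bp]] <- tr
  }
  out
}

#' Write a state timeline as a BED-like interval table
#' @param timeline A [state_timeline()].
#' @param path Output CSV path (columns start, end, state).
#' @return `path`, invisibly.
#' @export
write_state_timeline <- function(timeline, path) {
  df <- data.frame(start = fmt_num(timeline$start), end = fmt_num(timeline$end),
                   state = timeline$state)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a state timeline
#' @param path CSV with columns start, end, state.
#' @return A [state_timeline()].
#' @export
read_state_timeline <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  state_timeline(df$start, df$end, df$state)
}

#' Write a frame clock
#' @param clock A [frame_clock()].
#' @param frames_path CSV of `frame_time`, `dummy_flag`.
#' @param pulses_path CSV of `pulse_time`.
#' @return `frames_path`, invisibly.
#' @export
write_frame_clock <- function(clock, frames_path, pulses_path) {
  write.csv(data.frame(frame_time = fmt_num(clock$frame_times),
                       dummy_flag = clock$dummy_flags),
            frames_path, row.names = FALSE, quote = FALSE)
  write.csv(data.frame(pulse_time = fmt_num(clock$pulse_times)),
            pulses_path, row.names = FALSE, quote = FALSE)
  invisible(frames_path)
}

#' Read a frame clock
#' @param frames_path CSV of `frame_time`, `dummy_flag`.
#' @param pulses_path CSV of `pulse_time`.
#' @param frame_rate,pulse_interval Nominal clock parameters.
#' @return A [frame_clock()].
#' @export
read_frame_clock <- function(frames_path, pulses_path,
                             frame_rate = 100, pulse_interval = 3) {
  fr <- read.csv(frames_path, stringsAsFactors = FALSE)
  pl <- read.csv(pulses_path, stringsAsFactors = FALSE)
  frame_clock(fr$frame_time, pl$pulse_time, frame_rate = frame_rate,
              pulse_interval = pulse_interval,
              dummy_flags = as.logical(fr$dummy_flag))
}

#' Write a pixel-change series
#' @param series A [pixel_change_series()].
#' @param path CSV of `time`, `value`.
#' @return `path`, invisibly.
#' @export
write_pixel_series <- function(series, path) {
  write.csv(data.frame(time = fmt_num(series_times(series)),
                       value = series$values),
            path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a pixel-change series
#' @param path CSV of `time`, `value`.
#' @param roi_label ROI label to attach.
#' @return A [pixel_change_series()].
#' @export
read_pixel_series <- function(path, roi_label = "roi") {
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (anyNA(df$time)) stop_invalid("pixel series %s contains NaN/NA times", path)
  fr <- 1 / median(diff(df$time))
  pixel_change_series(df$value, frame_rate = fr, roi_label = roi_label,
                      t0 = df$time[1])
}

#' Write the simulation ground truth sidecar
#' @param truth The `ground_truth` element of a [simulate_session()] result.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(truth, path) {
  gt <- truth
  gt$timeline <- as.data.frame(gt$timeline)
  gt$events <- as.data.frame(gt$events)
  jsonlite::write_json(gt, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Read a simulation ground truth sidecar
#' @param path JSON path written by [write_ground_truth()].
#' @return A ground-truth list (timeline/events as data frames).
#' @export
read_ground_truth <- function(path) {
  gt <- jsonlite::read_json(path, simplifyVector = TRUE)
  gt$timeline <- state_timeline(gt$timeline$start, gt$timeline$end,
                                gt$timeline$state)
  gt$events <- movement_events(gt$events$onset_s, gt$events$body_part,
                               gt$events$class, gt$events$state,
                               gt$events$amplitude_mm, gt$events$angle_deg)
  gt
}
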