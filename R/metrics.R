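# Temporal response metrics per neuron: peak latency, width at half-height,
# premovement proportion, Fano factor, state-conditioned baseline rates.

#' Time of peak movement-related activity
#'
#' Bin-center time of the maximum z value within the response window; ties
#' resolve to the earliest bin.
#'
#' @param p A z-scored `peth`.
#' @param response_window Length-2 window in seconds (default the twitch
#'   classification window, -100..250 ms).
#' @return Peak latency in milliseconds (`NA` when z is undefined).
#' @export
peak_latency <- function(p, response_window = c(-0.1, 0.25)) {
  if (is.null(p$z_trace) || all(is.na(p$z_trace))) return(NA_real_)
  sel <- which(p$bin_centers >= response_window[1] &
               p$bin_centers <= response_window[2])
  1000 * p$bin_centers[sel[which.max(p$z_trace[sel])]]
}

# 10 ms -> 1 ms linear upsampling of a binned trace; returns times + values.
upsample_trace <- function(values, centers, step_s = 0.001) {
  grid <- seq(centers[1], centers[length(centers)], by = step_s)
  list(time = grid, value = approx(centers, values, xout = grid)$y)
}

# Contiguous run of >0.5 samples containing the peak, in samples.
run_above_half <- function(y) {
  ipk <- which.max(y)
  above <- y > 0.5
  if (!above[ipk]) return(0L)
  lo <- ipk
  while (lo > 1 && above[lo - 1]) lo <- lo - 1
  hi <- ipk
  while (hi < length(y) && above[hi + 1]) hi <- hi + 1
  hi - lo + 1L
}

#' Width at half-height of a perievent response
#'
#' Pipeline: smooth the trial-mean trace with a 5-bin moving average,
#' upsample from 10 ms to 1 ms bins by linear interpolation, normalize
#' affinely so the baseline maps to 0 and the peak to 1, then count the
#' contiguous 1 ms bins above 0.5 around the peak.
#'
#' Given a plain numeric vector, the input is taken to be an
#' already-normalized 1 ms trace and only the final counting step runs.
#'
#' @param p A `peth`, or a normalized numeric 1 ms trace.
#' @param baseline Baseline window (seconds) defining the zero level.
#' @param smooth_bins Moving-average width in bins (default 5).
#' @param config Optional `mp_config` supplying the two arguments above.
#' @return Width at half-height in milliseconds. A peak not strictly above
#'   the baseline is an error (undefined width).
#' @export
width_at_half_height <- function(p, baseline = c(-3, -0.5), smooth_bins = 5L,
                                 config = NULL) {
  if (is.numeric(p) && !inherits(p, "peth")) {
    return(as.numeric(run_above_half(p)))
  }
  if (!is.null(config)) {
    baseline <- config$peth$baseline_s
    smooth_bins <- config$metrics$whh_smooth_bins
  }
  sm <- boxcar_smooth(p$mean_rate_trace, smooth_bins)
  up <- upsample_trace(sm, p$bin_centers)
  base_sel <- up$time >= baseline[1] & up$time < baseline[2]
  b <- mean(up$value[base_sel])
  pk <- max(up$value)
  if (pk <= b) stop_invalid("peak does not exceed baseline; width undefined")
  norm <- (up$value - b) / (pk - b)
  as.numeric(run_above_half(norm))
}

# Trapezoidal integral of a binned trace over [lo, hi]: the trace is
# linearly interpolated at the window bounds so that adjacent windows
# partition the integral exactly (numerator + complement = total).
trapz_window <- function(centers, values, lo, hi) {
  lo <- max(lo, centers[1]); hi <- min(hi, centers[length(centers)])
  if (hi <= lo) return(NA_real_)
  inner <- centers > lo & centers < hi
  xs <- c(lo, centers[inner], hi)
  ys <- approx(centers, values, xout = xs)$y
  pracma::trapz(xs, ys)
}

#' Premovement proportion of twitch-triggered activity
#'
#' Ratio of the trapezoidal integral of the z-scored histogram over the
#' premovement numerator window (-0.2..0 s) to the integral over the full
#' analysis window. A negative numerator is clamped to 0; a non-positive
#' total integral leaves the proportion undefined (`NA`, logged).
#'
#' @param p A z-scored `peth`.
#' @param analysis_window Full window in seconds; -0.2..0.75 s for
#'   developmental analyses, -0.2..0.2 s for cross-structure comparisons.
#' @param numerator_window Premovement numerator window (default -0.2..0 s).
#' @return Proportion in `[0, 1]`, or `NA`.
#' @export
premove_proportion_twitch <- function(p, analysis_window = c(-0.2, 0.75),
                                      numerator_window = c(-0.2, 0)) {
  if (is.null(p$z_trace) || all(is.na(p$z_trace))) return(NA_real_)
  total <- trapz_window(p$bin_centers, p$z_trace,
                        analysis_window[1], analysis_window[2])
  num <- trapz_window(p$bin_centers, p$z_trace,
                      numerator_window[1], numerator_window[2])
  if (!is.finite(total) || total <= 0) {
    mp_log("info", "neuron ", p$neuron_id,
           ": non-positive total integral; premovement proportion undefined")
    return(NA_real_)
  }
  min(1, max(0, num / total))
}

#' Premovement proportion for wake movements
#'
#' Wake baselines are contaminated by prior movement, so an adjusted
#' baseline is used: the minimum of the 20-bin-smoothed z trace within the
#' preceding 500 ms. The analysis window runs from the time of that minimum
#' to 1 s after onset, the integrand is the z trace re-zeroed at the
#' adjusted baseline, and the numerator spans from the window start to
#' onset. Negative numerators are clamped to 0.
#'
#' @param p A z-scored `peth`.
#' @param search_s Length of the pre-onset minimum search (default 0.5 s).
#' @param end_s Window end after onset (default 1 s).
#' @param smooth_bins Smoothing width for the baseline search (default 20).
#' @return Proportion in `[0, 1]`, or `NA` for a non-positive total.
#' @export
premove_proportion_wake <- function(p, search_s = 0.5, end_s = 1,
                                    smooth_bins = 20L) {
  if (is.null(p$z_trace) || all(is.na(p$z_trace))) return(NA_real_)
  sm <- boxcar_smooth(p$z_trace, smooth_bins)
  pre <- which(p$bin_centers >= -search_s & p$bin_centers < 0)
  if (!length(pre)) stop_invalid("need %g s of pre-onset histogram", search_s)
  imin <- pre[which.min(sm[pre])]
  t_min <- p$bin_centers[imin]
  adj <- p$z_trace - sm[imin]
  total <- trapz_window(p$bin_centers, adj, t_min, end_s)
  num <- trapz_window(p$bin_centers, adj, t_min, 0)
  if (!is.finite(total) || total <= 0) {
    mp_log("info", "neuron ", p$neuron_id,
           ": non-positive adjusted total; wake premovement undefined")
    return(NA_real_)
  }
  min(1, max(0, num / total))
}

#' Per-event spike counts in a window
#'
#' @param spikes A [spike_train()].
#' @param events Events or numeric onsets.
#' @param window Half-open window `[onset + lo, onset + hi)` in seconds.
#' @return Integer counts, one per event.
#' @export
spike_counts_in_window <- function(spikes, events, window) {
  onsets <- if (is.data.frame(events)) events$onset_s else as.numeric(events)
  st <- spikes$times
  lo <- onsets + window[1]
  hi <- onsets + window[2]
  findInterval(hi, st, left.open = TRUE) -
    findInterval(lo, st, left.open = TRUE)
}

#' Fano factor of movement-related spike counts
#'
#' Sample variance (n - 1 denominator) of per-event spike counts within the
#' activity window, divided by their mean. Windows: -70..70 ms for twitches,
#' -100..500 ms for wake movements.
#'
#' @param spikes A [spike_train()].
#' @param events Events or onsets (at least two).
#' @param window Length-2 activity window in seconds.
#' @return Fano factor (unitless, >= 0); `NA` with a log entry when the mean
#'   count is zero.
#' @export
fano_factor <- function(spikes, events, window = c(-0.07, 0.07)) {
  counts <- spike_counts_in_window(spikes, events, window)
  if (length(counts) < 2) stop_invalid("Fano factor needs at least 2 events")
  m <- mean(counts)
  if (m == 0) {
    mp_log("info", "neuron ", spikes$neuron_id,
           ": zero mean count; Fano factor undefined")
    return(NA_real_)
  }
  var(counts) / m
}

#' Baseline firing rate per behavioral state
#'
#' Total spike count within each state's intervals divided by the state's
#' total duration. Spikes outside every interval count toward no state.
#'
#' @param spikes A [spike_train()].
#' @param timeline A [state_timeline()].
#' @return Named numeric vector of spikes/s per state present in the
#'   timeline (`NA` for zero-duration states).
#' @export
baseline_rate_by_state <- function(spikes, timeline) {
  states <- unique(timeline$state)
  out <- setNames(numeric(length(states)), states)
  for (s in states) {
    iv <- timeline[timeline$state == s, , drop = FALSE]
    dur <- sum(iv$end - iv$start)
    n <- sum(findInterval(iv$end, spikes$times, left.open = TRUE) -
             findInterval(iv$start, spikes$times, left.open = TRUE))
    out[s] <- if (dur > 0) n / dur else NA_real_
  }
  out
}

#' All temporal metrics for one neuron and event class
#'
#' @param spikes A [spike_train()].
#' @param events Events of one class.
#' @param class `"twitch"` or `"wake"`.
#' @param timeline Optional [state_timeline()] for baseline rates.
#' @param config An `mp_config`.
#' @return One-row data frame of metrics.
#' @export
peth_metrics <- function(spikes, events, class = c("twitch", "wake"),
                         timeline = NULL, config = default_config()) {
  class <- match.arg(class)
  pc <- config$peth; mc <- config$metrics
  p <- zscore_peth(build_peth(spikes, events, pc$window_s, pc$bin_s),
                   baseline = pc$baseline_s)
  win <- if (class == "twitch") pc$twitch_class_window_s else pc$wake_class_window_s
  fano_win <- if (class == "twitch") mc$fano_twitch_window_s else mc$fano_wake_window_s
  premove <- if (class == "twitch") {
    premove_proportion_twitch(p, mc$twitch_integral_window_s,
                              mc$premove_numerator_s)
  } else {
    premove_proportion_wake(p, mc$wake_baseline_search_s,
                            mc$wake_integral_end_s, mc$wake_smooth_bins)
  }
  whh <- tryCatch(width_at_half_height(p, pc$baseline_s, mc$whh_smooth_bins),
                  error = function(e) NA_real_)
  rates <- if (!is.null(timeline)) baseline_rate_by_state(spikes, timeline)
           else NULL
  out <- data.frame(neuron_id = spikes$neuron_id, region = spikes$region,
                    class = class,
                    peak_latency_ms = peak_latency(p, win),
                    whh_ms = whh,
                    premove_prop = premove,
                    fano = fano_factor(spikes, events, fano_win),
                    n_events = p$n_events,
                    stringsAsFactors = FALSE)
  if (!is.null(rates))
    for (s in names(rates)) out[[paste0("rate_", s)]] <- rates[[s]]
  out
}
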