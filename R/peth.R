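# Perievent time histograms, baseline z-scoring, and classification of
# movement-active neurons with somatotopic preference.

#' Build a perievent time histogram
#'
#' Spike counts per event and bin over a window around each event onset
#' (default -3..3 s in 10 ms bins, i.e. 600 bins). Binning is half-open:
#' a spike at offset `t` lands in bin `j` iff
#' `edge[j] <= t < edge[j+1]`.
#'
#' @param spikes A [spike_train()].
#' @param events A [movement_events()] table or numeric onset vector
#'   (at least one event).
#' @param window Length-2 window in seconds.
#' @param bin Bin width in seconds; must divide the window evenly.
#' @return An object of class `peth`: `counts` (events x bins integer
#'   matrix), `bin_edges`, `bin_centers`, `mean_rate_trace` (mean spikes
#'   per bin across events), `window`, `bin`, `n_events`, `neuron_id`, and
#'   (after [zscore_peth()]) baseline statistics and `z_trace`.
#' @export
build_peth <- function(spikes, events, window = c(-3, 3), bin = 0.01) {
  onsets <- if (is.data.frame(events)) events$onset_s else as.numeric(events)
  if (!length(onsets)) stop_invalid("cannot build a perievent histogram with zero events")
  nb <- diff(window) / bin
  if (abs(nb - round(nb)) > 1e-9)
    stop_invalid("bin (%g s) must divide the window evenly", bin)
  nb <- as.integer(round(nb))
  edges <- window[1] + bin * (0:nb)
  st <- spikes$times
  counts <- matrix(0L, nrow = length(onsets), ncol = nb)
  for (i in seq_along(onsets)) {
    lo <- onsets[i] + window[1]
    hi <- onsets[i] + window[2]
    j0 <- findInterval(lo, st, left.open = TRUE)        # spikes < lo
    j1 <- findInterval(hi, st, left.open = TRUE)        # spikes < hi
    sel <- if (j1 > j0) st[(j0 + 1L):j1] else numeric(0)
    if (length(sel)) {
      idx <- floor((sel - lo) / bin) + 1L
      idx[idx > nb] <- nb
      counts[i, ] <- tabulate(idx, nbins = nb)
    }
  }
  structure(list(counts = counts, bin_edges = edges,
                 bin_centers = edges[-1] - bin / 2,
                 mean_rate_trace = colMeans(counts),
                 window = window, bin = bin, n_events = length(onsets),
                 neuron_id = spikes$neuron_id,
                 baseline_mean = NA_real_, baseline_sd = NA_real_,
                 z_trace = NULL),
            class = "peth")
}

#' @export
print.peth <- function(x, ...) {
  cat(sprintf("<peth> %s: %d events x %d bins (%g ms), window %g..%g s%s\n",
              x$neuron_id, x$n_events, length(x$mean_rate_trace),
              1000 * x$bin, x$window[1], x$window[2],
              if (!is.null(x$z_trace)) ", z-scored" else ""))
  invisible(x)
}

#' Z-score a perievent histogram against its baseline
#'
#' The baseline mean and SD are taken across the baseline bins of the
#' trial-mean trace (default baseline -3..-0.5 s); the z trace is
#' `(mean_rate_trace - baseline_mean) / baseline_sd`. A zero baseline SD
#' leaves the neuron unclassifiable (`z_trace` all `NA`, with a warning).
#'
#' @param p A `peth` from [build_peth()].
#' @param baseline Length-2 baseline window in seconds.
#' @return The `peth` with `baseline_mean`, `baseline_sd` and `z_trace`
#'   filled in.
#' @export
zscore_peth <- function(p, baseline = c(-3, -0.5)) {
  sel <- p$bin_centers >= baseline[1] & p$bin_centers < baseline[2]
  if (!any(sel)) stop_invalid("baseline window contains no bins")
  p$baseline_mean <- mean(p$mean_rate_trace[sel])
  p$baseline_sd <- sd(p$mean_rate_trace[sel])
  if (!is.finite(p$baseline_sd) || p$baseline_sd == 0) {
    warning(sprintf("neuron %s: zero baseline SD; unclassifiable", p$neuron_id),
            call. = FALSE)
    p$z_trace <- rep(NA_real_, length(p$mean_rate_trace))
  } else {
    p$z_trace <- (p$mean_rate_trace - p$baseline_mean) / p$baseline_sd
  }
  p
}

#' Classify a neuron as twitch- or wake-movement-active
#'
#' A neuron is movement-active when its z-scored perievent histogram shows a
#' peak of at least `z_threshold` (default 3.5) inside the class window
#' (-100..250 ms for twitches, -100..500 ms for wake movements). More than
#' `min_events` events (default 20) are required; otherwise the neuron is
#' reported as `insufficient_events`, not inactive.
#'
#' @param p A z-scored `peth`.
#' @param class `"twitch"` or `"wake"`.
#' @param config An `mp_config`.
#' @return List with `status` (`"classified"`, `"insufficient_events"` or
#'   `"unclassifiable"`), logical `active`, `peak_z` and `peak_time_s`.
#' @export
classify_movement_active <- function(p, class = c("twitch", "wake"),
                                     config = default_config()) {
  class <- match.arg(class)
  pc <- config$peth
  win <- if (class == "twitch") pc$twitch_class_window_s else pc$wake_class_window_s
  if (p$n_events <= pc$min_events) {
    return(list(status = "insufficient_events", active = NA,
                peak_z = NA_real_, peak_time_s = NA_real_))
  }
  if (is.null(p$z_trace)) p <- zscore_peth(p, baseline = pc$baseline_s)
  if (all(is.na(p$z_trace))) {
    return(list(status = "unclassifiable", active = NA,
                peak_z = NA_real_, peak_time_s = NA_real_))
  }
  sel <- which(p$bin_centers >= win[1] & p$bin_centers <= win[2])
  zi <- p$z_trace[sel]
  imax <- sel[which.max(zi)]
  list(status = "classified",
       active = max(zi) >= pc$z_threshold,
       peak_z = max(zi),
       peak_time_s = p$bin_centers[imax])
}

#' Somatotopic preference across body parts
#'
#' The preferred body part is the one whose z-scored twitch-triggered
#' histogram (built on cross-body-part-isolated twitches) has the largest
#' super-threshold peak within the twitch window. Ties are broken by
#' earlier peak time, then lexical order (logged). Returns `NA` when no
#' body part is classified active.
#'
#' @param peths Named list of z-scored `peth`s, one per body part.
#' @param config An `mp_config`.
#' @return List `preferred` (label or `NA`), and per-part vectors `peak_z`,
#'   `peak_time_s`, `n_events`, `status`.
#' @export
preferred_body_part <- function(peths, config = default_config()) {
  res <- lapply(peths, classify_movement_active, class = "twitch",
                config = config)
  peak_z <- vapply(res, `[[`, 0, "peak_z")
  peak_t <- vapply(res, `[[`, 0, "peak_time_s")
  status <- vapply(res, `[[`, "", "status")
  active <- vapply(res, function(r) isTRUE(r$active), TRUE)
  nev <- vapply(peths, `[[`, 0L, "n_events")
  pref <- NA_character_
  if (any(active)) {
    cand <- names(peths)[active]
    o <- order(-peak_z[cand], peak_t[cand], cand)
    pref <- cand[o[1]]
    if (length(cand) > 1 && sum(peak_z[cand] == max(peak_z[cand])) > 1)
      mp_log("info", "preferred-body-part tie broken by peak time/lexical order")
  }
  list(preferred = pref, peak_z = peak_z, peak_time_s = peak_t,
       n_events = nev, status = status)
}

#' Event-triggered median displacement profile
#'
#' Median of the ROI pixel-change series across event-aligned snippets, per
#' time point, normalized to its own maximum (so the per-animal profile
#' peaks at exactly 1 before any cross-animal averaging).
#'
#' @param series A [pixel_change_series()].
#' @param events Event onsets (use same-body-part-isolated twitches).
#' @param window Length-2 window in seconds around onset.
#' @return List `offset` (seconds) and `profile` (normalized median).
#' @export
median_displacement_profile <- function(series, events, window = c(-0.5, 1)) {
  onsets <- if (is.data.frame(events)) events$onset_s else as.numeric(events)
  if (!length(onsets)) stop_invalid("no events for displacement profile")
  fr <- series$frame_rate
  rel <- seq(round(window[1] * fr), round(window[2] * fr))
  snips <- vapply(onsets, function(on) {
    i0 <- round((on - series$t0) * fr) + 1L
    idx <- i0 + rel
    out <- rep(NA_real_, length(rel))
    ok <- idx >= 1 & idx <= length(series$values)
    out[ok] <- series$values[idx[ok]]
    out
  }, numeric(length(rel)))
  med <- apply(snips, 1, median, na.rm = TRUE)
  mx <- max(med, na.rm = TRUE)
  if (mx <= 0) stop_invalid("median profile has no positive displacement")
  list(offset = rel / fr, profile = med / mx)
}

#' Average normalized displacement profiles across animals
#' @param profiles List of profiles from [median_displacement_profile()]
#'   (matched offsets).
#' @return List `offset`, `profile` (unweighted mean across animals).
#' @export
grand_displacement_profile <- function(profiles) {
  if (!length(profiles)) stop_invalid("no profiles to average")
  prof <- Reduce(`+`, lapply(profiles, `[[`, "profile")) / length(profiles)
  list(offset = profiles[[1]]$offset, profile = prof)
}
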