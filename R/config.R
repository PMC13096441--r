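#' Default analysis configuration
#'
#' Returns the full set of analysis constants used throughout the package,
#' as a nested list. All durations are seconds unless a name says otherwise.
#' The defaults encode the standard settings for this kind of analysis:
#' 10 ms perievent bins over a -3..3 s window with a -3..-0.5 s baseline,
#' a z >= 3.5 activation threshold inside a -100..250 ms (twitch) or
#' -100..500 ms (wake) window, a 100 ms twitch-isolation rule, a 500 ms
#' wake-quiescence rule, -70..70 ms / -100..500 ms Fano windows, 150/500 ms
#' kinematic windows, 12 direction bins with a 0.1 selectivity threshold,
#' 5.75 px/mm video calibration, a 5% pixel-change criterion at 100 frames/s
#' with 3 s LED pulses, and a 3-scaled-MAD outlier rule.
#'
#' @return A nested named list of class `mp_config`.
#' @seealso [load_config()] to override defaults from a YAML file.
#' @export
default_config <- function() {
  cfg <- list(
    peth = list(
      bin_s = 0.01,
      window_s = c(-3, 3),
      baseline_s = c(-3, -0.5),
      z_threshold = 3.5,
      min_events = 20L,                     # strictly more than this required
      twitch_class_window_s = c(-0.1, 0.25),
      wake_class_window_s = c(-0.1, 0.5)
    ),
    behavior = list(
      isolation_s = 0.1,
      wake_quiescence_s = 0.5,
      whisker_merge_s = 0.1,
      pixel_threshold_mads = 3,
      atonia_fraction = 0.2,
      delta_fraction = 0.7,
      active_wake_s = 3,
      emg_z_threshold = 2
    ),
    metrics = list(
      fano_twitch_window_s = c(-0.07, 0.07),
      fano_wake_window_s = c(-0.1, 0.5),
      premove_numerator_s = c(-0.2, 0),
      twitch_integral_window_s = c(-0.2, 0.75),
      wake_baseline_search_s = 0.5,
      wake_integral_end_s = 1,
      whh_smooth_bins = 5L,
      wake_smooth_bins = 20L,
      smooth_kernel = "boxcar"
    ),
    kinematics = list(
      twitch_window_s = 0.15,
      wake_window_s = 0.5,
      n_direction_bins = 12L,
      selectivity_threshold = 0.1,
      angle_method = "at_peak",             # or "path_mean"
      calibration_px_per_mm = 5.75,
      preferred_window_s = 0.3
    ),
    sync = list(
      frame_rate = 100,
      pulse_interval_s = 3
    ),
    roi = list(
      pixel_change_threshold = 0.05
    ),
    stats = list(
      mad_factor = 3,
      alpha = 0.05
    ),
    inclusion = list(
      min_forelimb_twitches = 40L           # strictly more than this required
    )
  )
  class(cfg) <- c("mp_config", "list")
  cfg
}

#' Load and validate an analysis configuration
#'
#' Reads a YAML configuration file and merges it over [default_config()];
#' unknown keys are rejected, known keys are range-checked. With
#' `path = NULL` the validated default set is returned, so an empty or
#' absent config yields the full default constants.
#'
#' @param path Path to a YAML file, or `NULL` for pure defaults.
#' @return Validated configuration of class `mp_config`.
#' @examples
#' cfg <- load_config()
#' cfg$peth$z_threshold
#' @export
load_config <- function(path = NULL) {
  cfg <- default_config()
  if (!is.null(path)) {
    if (!file.exists(path)) stop_invalid("config file not found: %s", path)
    user <- yaml::read_yaml(path)
    if (length(user)) {
      bad <- setdiff(names(user), names(cfg))
      if (length(bad)) stop_invalid("unknown config section(s): %s",
                                    paste(bad, collapse = ", "))
      for (sec in names(user)) {
        badk <- setdiff(names(user[[sec]]), names(cfg[[sec]]))
        if (length(badk)) stop_invalid("unknown config key(s) in '%s': %s",
                                       sec, paste(badk, collapse = ", "))
        cfg[[sec]] <- modifyList(cfg[[sec]], user[[sec]])
      }
    }
  }
  validate_config(cfg)
}

validate_config <- function(cfg) {
  chk_pos <- function(x, key) {
    if (!is.numeric(x) || length(x) != 1 || is.na(x) || x <= 0)
      stop_invalid("config key '%s' must be a positive number (got %s)",
                   key, paste(x, collapse = ","))
  }
  chk_win <- function(x, key) {
    if (!is.numeric(x) || length(x) != 2 || any(is.na(x)) || x[1] >= x[2])
      stop_invalid("config key '%s' must be an increasing length-2 window", key)
  }
  chk_frac <- function(x, key) {
    if (!is.numeric(x) || length(x) != 1 || is.na(x) || x <= 0 || x >= 1)
      stop_invalid("config key '%s' must lie strictly in (0, 1)", key)
  }
  chk_pos(cfg$peth$bin_s, "peth.bin_s")
  chk_win(cfg$peth$window_s, "peth.window_s")
  chk_win(cfg$peth$baseline_s, "peth.baseline_s")
  chk_pos(cfg$peth$z_threshold, "peth.z_threshold")
  chk_win(cfg$peth$twitch_class_window_s, "peth.twitch_class_window_s")
  chk_win(cfg$peth$wake_class_window_s, "peth.wake_class_window_s")
  if (cfg$peth$min_events < 0) stop_invalid("config key 'peth.min_events' must be >= 0")
  nb <- diff(cfg$peth$window_s) / cfg$peth$bin_s
  if (abs(nb - round(nb)) > 1e-9)
    stop_invalid("peth.bin_s must divide peth.window_s evenly")
  chk_pos(cfg$behavior$isolation_s, "behavior.isolation_s")
  chk_pos(cfg$behavior$wake_quiescence_s, "behavior.wake_quiescence_s")
  chk_pos(cfg$behavior$pixel_threshold_mads, "behavior.pixel_threshold_mads")
  chk_frac(cfg$behavior$atonia_fraction, "behavior.atonia_fraction")
  chk_frac(cfg$behavior$delta_fraction, "behavior.delta_fraction")
  chk_pos(cfg$behavior$active_wake_s, "behavior.active_wake_s")
  chk_pos(cfg$behavior$emg_z_threshold, "behavior.emg_z_threshold")
  chk_win(cfg$metrics$fano_twitch_window_s, "metrics.fano_twitch_window_s")
  chk_win(cfg$metrics$fano_wake_window_s, "metrics.fano_wake_window_s")
  chk_win(cfg$metrics$premove_numerator_s, "metrics.premove_numerator_s")
  chk_win(cfg$metrics$twitch_integral_window_s, "metrics.twitch_integral_window_s")
  chk_pos(cfg$metrics$wake_baseline_search_s, "metrics.wake_baseline_search_s")
  chk_pos(cfg$metrics$wake_integral_end_s, "metrics.wake_integral_end_s")
  chk_pos(cfg$metrics$whh_smooth_bins, "metrics.whh_smooth_bins")
  chk_pos(cfg$metrics$wake_smooth_bins, "metrics.wake_smooth_bins")
  chk_pos(cfg$kinematics$twitch_window_s, "kinematics.twitch_window_s")
  chk_pos(cfg$kinematics$wake_window_s, "kinematics.wake_window_s")
  chk_pos(cfg$kinematics$n_direction_bins, "kinematics.n_direction_bins")
  chk_pos(cfg$kinematics$selectivity_threshold, "kinematics.selectivity_threshold")
  chk_pos(cfg$kinematics$calibration_px_per_mm, "kinematics.calibration_px_per_mm")
  if (!cfg$kinematics$angle_method %in% c("at_peak", "path_mean"))
    stop_invalid("kinematics.angle_method must be 'at_peak' or 'path_mean'")
  chk_pos(cfg$sync$frame_rate, "sync.frame_rate")
  chk_pos(cfg$sync$pulse_interval_s, "sync.pulse_interval_s")
  chk_frac(cfg$roi$pixel_change_threshold, "roi.pixel_change_threshold")
  chk_pos(cfg$stats$mad_factor, "stats.mad_factor")
  chk_frac(cfg$stats$alpha, "stats.alpha")
  class(cfg) <- c("mp_config", "list")
  cfg
}
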