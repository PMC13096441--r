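# End-to-end orchestration: simulate (or load) a session, repair the frame
# clock, detect and select movements, score states, classify neurons,
# compute temporal metrics and kinematic tuning, and run group statistics,
# writing every stage's table plus a reproducible run manifest.

default_fixture_neurons <- function() {
  list(
    neuron_spec("m1_forelimb", region = "M1",
                kernels = list(twitch = list(latency_ms = 34, sigma_ms = 25,
                                             gain = 12, premove_fraction = 0.29),
                               wake = list(latency_ms = 100, sigma_ms = 150,
                                           gain = 15, premove_fraction = 0.07)),
                responsive_body_parts = "forelimb"),
    neuron_spec("m1_untuned", region = "M1",
                kernels = list(twitch = list(latency_ms = 30, sigma_ms = 20,
                                             gain = 0, premove_fraction = 0.1),
                               wake = list(latency_ms = 100, sigma_ms = 150,
                                           gain = 0, premove_fraction = 0.1))),
    neuron_spec("rn_tuned", region = "RN",
                kernels = list(twitch = list(latency_ms = 15, sigma_ms = 40,
                                             gain = 12, premove_fraction = 0.45),
                               wake = list(latency_ms = 100, sigma_ms = 150,
                                           gain = 20, premove_fraction = 0.14)),
                responsive_body_parts = "forelimb",
                direction_tuning = list(mu_deg = 129, kappa = 1),
                amplitude_slope = 0.25),
    neuron_spec("rn_wake_only", region = "RN",
                kernels = list(twitch = list(latency_ms = 15, sigma_ms = 40,
                                             gain = 0, premove_fraction = 0.45),
                               wake = list(latency_ms = 80, sigma_ms = 120,
                                           gain = 18, premove_fraction = 0.14)),
                responsive_body_parts = character(0))
  )
}

#' Generate a bundled synthetic test session on disk
#'
#' Writes a small complete session — four neurons (a forelimb-tuned M1-like
#' neuron, an untuned neuron, a direction-and-amplitude-tuned RN-like
#' neuron, and a wake-only neuron), twitches of four body parts — as the
#' table formats the readers accept, plus a ground-truth JSON sidecar.
#'
#' @param seed Integer seed.
#' @param dir Output directory (created if needed).
#' @param duration Session length in seconds (default 300).
#' @return Named list of file paths plus the in-memory `sim_session`.
#' @export
make_fixtures <- function(seed = 42L, dir = tempfile("fixtures"), duration = 300) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  # REM-rich cycling typical of young pups, so even a short fixture session
  # carries enough twitches for every downstream stage
  params <- sim_params(session_duration = duration, twitch_rate = 0.5,
                       wake_move_rate = 0.25,
                       state_mean_durations = c(NREM = 60, REM = 90,
                                                quiet_wake = 60),
                       seed = as.integer(seed))
  sess <- simulate_session(params, neurons = default_fixture_neurons())
  paths <- list(
    spikes = file.path(dir, "spikes.csv"),
    events = file.path(dir, "events.csv"),
    pose = file.path(dir, "pose.csv"),
    frames = file.path(dir, "frames.csv"),
    pulses = file.path(dir, "pulses.csv"),
    states = file.path(dir, "states.csv"),
    tone = file.path(dir, "tone.csv"),
    delta = file.path(dir, "delta.csv"),
    ground_truth = file.path(dir, "ground_truth.json"))
  write_spike_table(sess$spike_trains, paths$spikes)
  write_event_table(sess$events, paths$events)
  write_pose_table(sess$trajectory, paths$pose)
  write_frame_clock(sess$frame_clock, paths$frames, paths$pulses)
  write_state_timeline(sess$timeline, paths$states)
  write.csv(sess$features$tone, paths$tone, row.names = FALSE)
  write.csv(sess$features$delta, paths$delta, row.names = FALSE)
  write_ground_truth(sess$ground_truth, paths$ground_truth)
  for (bp in names(sess$roi_series)) {
    paths[[paste0("roi_", bp)]] <- file.path(dir, paste0("roi_", bp, ".csv"))
    write_pixel_series(sess$roi_series[[bp]], paths[[paste0("roi_", bp)]])
  }
  c(paths, list(session = sess))
}

#' Run the full analysis pipeline
#'
#' Stage order: simulate (or load) inputs, validate and repair the frame
#' clock, detect movements from the ROI series and apply the wake-bout and
#' twitch-isolation rules, score behavioral states, build and classify
#' perievent histograms per neuron (with somatotopic preference), compute
#' temporal metrics and kinematic tuning, and test metric contrasts across
#' regions. Sessions with 40 or fewer forelimb twitches, or with no
#' twitch-active neuron, are excluded (status recorded, no tables written
#' beyond the manifest).
#'
#' @param config An `mp_config` (or path to a YAML config).
#' @param seed Integer seed for the simulated session.
#' @param out_dir Output directory for result tables and the manifest.
#' @param params Optional [sim_params()] (its seed is overridden by `seed`).
#' @param neurons Optional list of [neuron_spec()]s.
#' @return Invisibly, a list with the run `manifest`, the result tables,
#'   and `status` (`"ok"` or an exclusion reason).
#' @export
run_pipeline <- function(config = NULL, seed = 1L, out_dir = tempfile("run"),
                         params = NULL, neurons = NULL) {
  if (is.character(config)) config <- load_config(config)
  if (is.null(config)) config <- default_config()
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- "simulate"
  result <- tryCatch({
    if (is.null(params))
      params <- sim_params(session_duration = 1800, twitch_rate = 0.4,
                           wake_move_rate = 0.2, seed = as.integer(seed))
    params$seed <- as.integer(seed)
    if (is.null(neurons)) neurons <- default_fixture_neurons()
    sess <- simulate_session(params, neurons)

    stage <- "sync"
    clock <- repair_frame_clock(sess$frame_clock)

    stage <- "behavior"
    detected <- lapply(sess$roi_series, detect_movement_bouts,
                       onset_threshold = params$roi_pulse_counts / 2)
    timeline <- classify_states(sess$features$tone, sess$features$delta,
                                movement_times = sort(unlist(
                                  lapply(detected, `[[`, "onset"))),
                                config = config)
    events <- sess$events
    events <- merge_whisker_twitches(events, config$behavior$whisker_merge_s)
    iso <- isolate_twitches(events, config$behavior$isolation_s,
                            "cross_bodypart")
    wake_ev <- events[events$class == "wake", , drop = FALSE]

    stage <- "inclusion"
    n_fl <- sum(iso$body_part == "forelimb")
    if (n_fl <= config$inclusion$min_forelimb_twitches)
      stop(sprintf("excluded: only %d isolated forelimb twitches (need > %d)",
                   n_fl, config$inclusion$min_forelimb_twitches), call. = FALSE)

    stage <- "peth"
    pc <- config$peth
    class_rows <- list(); metric_rows <- list(); tuning_rows <- list()
    kin <- if (nrow(wake_ev)) movement_kinematics(sess$trajectory, wake_ev, config)
           else data.frame(onset_s = numeric(0), class = character(0),
                           amplitude_mm = numeric(0), angle_deg = numeric(0),
                           peak_time_s = numeric(0))
    for (tr in sess$spike_trains) {
      peths <- list()
      for (bp in unique(iso$body_part)) {
        ev_bp <- iso[iso$body_part == bp, , drop = FALSE]
        if (!nrow(ev_bp)) next
        peths[[bp]] <- zscore_peth(
          build_peth(tr, ev_bp, pc$window_s, pc$bin_s), pc$baseline_s)
      }
      pref <- preferred_body_part(peths, config)
      tw_ev <- iso[iso$body_part == "forelimb", , drop = FALSE]
      tw_cls <- classify_movement_active(peths[["forelimb"]], "twitch", config)
      wk_cls <- if (nrow(wake_ev)) {
        classify_movement_active(
          zscore_peth(build_peth(tr, wake_ev, pc$window_s, pc$bin_s),
                      pc$baseline_s), "wake", config)
      } else {
        list(status = "insufficient_events", active = NA)
      }
      class_rows[[tr$neuron_id]] <- data.frame(
        neuron_id = tr$neuron_id, region = tr$region,
        twitch_active = isTRUE(tw_cls$active),
        wake_active = isTRUE(wk_cls$active),
        preferred_body_part = pref$preferred,
        peak_z_forelimb = pref$peak_z[["forelimb"]],
        stringsAsFactors = FALSE)

      stage <- "metrics"
      if (isTRUE(tw_cls$active))
        metric_rows[[paste0(tr$neuron_id, "_tw")]] <-
          peth_metrics(tr, tw_ev, "twitch", timeline = sess$timeline,
                       config = config)
      if (isTRUE(wk_cls$active))
        metric_rows[[paste0(tr$neuron_id, "_wk")]] <-
          peth_metrics(tr, wake_ev, "wake", timeline = sess$timeline,
                       config = config)

      stage <- "tuning"
      if (nrow(kin) >= 3)
        tuning_rows[[tr$neuron_id]] <-
          cbind(neuron_tuning(tr, kin, "wake", config),
                region = tr$region)
    }
    classifications <- do.call(rbind, c(class_rows, list(make.row.names = FALSE)))
    if (!any(classifications$twitch_active))
      stop("excluded: no twitch-active neurons", call. = FALSE)
    metrics <- do.call(rbind, c(metric_rows, list(make.row.names = FALSE)))
    tuning <- do.call(rbind, c(tuning_rows, list(make.row.names = FALSE)))

    stage <- "stats"
    stats_tab <- NULL
    tw_lat <- metrics[metrics$class == "twitch" &
                      is.finite(metrics$peak_latency_ms), , drop = FALSE]
    if (length(unique(tw_lat$region)) >= 2 && nrow(tw_lat) >= 4) {
      stats_tab <- omnibus_and_posthoc(
        data.frame(value = tw_lat$peak_latency_ms, group = tw_lat$region),
        design = "ttest", alpha = config$stats$alpha)
    }

    stage <- "write"
    outputs <- list(
      classifications = file.path(out_dir, "classifications.csv"),
      metrics = file.path(out_dir, "metrics.csv"),
      tuning = file.path(out_dir, "tuning.csv"),
      kinematics = file.path(out_dir, "kinematics.csv"),
      states = file.path(out_dir, "states.csv"))
    write.csv(classifications, outputs$classifications, row.names = FALSE)
    write.csv(metrics, outputs$metrics, row.names = FALSE)
    if (!is.null(tuning)) write.csv(tuning, outputs$tuning, row.names = FALSE)
    write.csv(kin, outputs$kinematics, row.names = FALSE)
    write_state_timeline(timeline, outputs$states)
    if (!is.null(stats_tab)) {
      outputs$stats <- file.path(out_dir, "stats.csv")
      write.csv(stats_tab, outputs$stats, row.names = FALSE)
    }
    list(status = "ok", classifications = classifications, metrics = metrics,
         tuning = tuning, kinematics = kin, timeline = timeline,
         clock = clock, stats = stats_tab, outputs = outputs)
  }, error = function(e) {
    if (grepl("^excluded", conditionMessage(e))) {
      mp_log("warn", conditionMessage(e))
      list(status = conditionMessage(e), outputs = list())
    } else {
      stop(sprintf("pipeline stage '%s' failed: %s", stage,
                   conditionMessage(e)), call. = FALSE)
    }
  })

  manifest <- list(
    tool = "motorpeth", version = as.character(packageVersion("motorpeth")),
    seed = as.integer(seed), status = result$status,
    config = unclass(config),
    outputs = result$outputs,
    output_hashes = if (length(result$outputs))
      as.list(tools::md5sum(unlist(result$outputs))) else list())
  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, digits = NA)
  result$manifest <- manifest
  result$manifest_path <- manifest_path
  invisible(result)
}
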