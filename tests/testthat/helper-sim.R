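# Small simulated sessions shared across tests.

quick_params <- function(seed = 1L, duration = 300, ...) {
  sim_params(session_duration = duration, twitch_rate = 0.5,
             wake_move_rate = 0.25, seed = seed, ...)
}

# A REM-only session with many forelimb twitches and one responsive neuron:
# the workhorse for temporal-metric recovery.
twitch_recovery_session <- function(kernel, seed = 1L, duration = 1200,
                                    rate = 0.4, gain = 15) {
  kernel$gain <- gain
  params <- sim_params(session_duration = duration,
                       state_mean_durations = c(REM = duration),
                       twitch_rate = rate, twitch_body_parts = "forelimb",
                       dropped_frame_prob = 0, seed = seed,
                       response_kernel = list(twitch = kernel,
                                              wake = list(latency_ms = 100,
                                                          sigma_ms = 150,
                                                          gain = 0,
                                                          premove_fraction = 0.1)))
  simulate_session(params)
}

# A wake-only session with many spaced movements.
wake_recovery_session <- function(kernel, seed = 1L, duration = 3000,
                                  rate = 0.3, gain = 25, neuron = NULL) {
  kernel$gain <- gain
  params <- sim_params(session_duration = duration,
                       state_mean_durations = c(quiet_wake = duration),
                       wake_move_rate = rate, dropped_frame_prob = 0,
                       seed = seed,
                       response_kernel = list(twitch = list(latency_ms = 30,
                                                            sigma_ms = 20,
                                                            gain = 0,
                                                            premove_fraction = 0.1),
                                              wake = kernel))
  simulate_session(params, neurons = if (is.null(neuron)) NULL else list(neuron))
}

# Poisson null neuron: evenly spaced events, homogeneous spiking at the
# REM baseline regime (13.1 spikes/s), where twitches are scored.
null_peth <- function(rate = 13.1, n_events = 100, spacing = 8, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  dur <- n_events * spacing + 8
  n <- rpois(1, rate * dur)
  tr <- spike_train("null", sort(runif(n, 0, dur)), span = c(0, dur))
  ev <- seq(4, by = spacing, length.out = n_events)
  zscore_peth(build_peth(tr, ev))
}
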