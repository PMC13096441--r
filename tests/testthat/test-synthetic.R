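# Synthetic-session generator: determinism, partition and support
# invariants, rate consistency, and kernel ground truth.

test_that("parameter validation rejects degenerate inputs", {
  expect_error(sim_params(session_duration = 0), "session_duration")
  expect_error(sim_params(dropped_frame_prob = 1), "dropped_frame_prob")
  expect_error(sim_params(twitch_rate = -1), "rates")
  expect_error(sim_params(response_kernel = list(
    twitch = list(latency_ms = 30, sigma_ms = 20, gain = 5,
                  premove_fraction = 1.5),
    wake = list(latency_ms = 100, sigma_ms = 150, gain = 5,
                premove_fraction = 0.1))), "premove_fraction")
})

test_that("identical seed and parameters reproduce the session exactly", {
  s1 <- simulate_session(quick_params(seed = 11, duration = 120))
  s2 <- simulate_session(quick_params(seed = 11, duration = 120))
  expect_identical(s1, s2)
  s3 <- simulate_session(quick_params(seed = 12, duration = 120))
  expect_false(identical(s1$events, s3$events))
})

test_that("state timeline partitions the session with plausible cycling", {
  set.seed(1)
  p <- sim_params(session_duration = 3600,
                  state_mean_durations = c(NREM = 60, REM = 60, quiet_wake = 60))
  tl <- simulate_state_timeline(p)
  expect_equal(tl$start[1], 0)
  expect_equal(tl$end[nrow(tl)], 3600)
  expect_true(all(abs(tl$start[-1] - tl$end[-nrow(tl)]) < 1e-9))
  # ~3600/180 = 20 cycles of 3 intervals; allow generous sampling spread
  expect_gt(nrow(tl), 60 * 0.4)
  expect_lt(nrow(tl), 60 * 2.5)
  # single-state request covers the whole session in one interval
  tl1 <- simulate_state_timeline(sim_params(
    session_duration = 500, state_mean_durations = c(quiet_wake = 60)))
  expect_equal(nrow(tl1), 1L)
  expect_equal(c(tl1$start, tl1$end), c(0, 500))
})

test_that("movement events respect state support and spacing rules", {
  set.seed(2)
  # no REM anywhere -> zero twitches
  tl_wake <- state_timeline(0, 1000, "quiet_wake")
  p <- quick_params(seed = 2)
  ev <- simulate_movement_events(tl_wake, p)
  expect_equal(sum(ev$class == "twitch"), 0L)
  # twitch count obeys Poisson bounds: rate 0.5/s over 1000 s of REM
  tl_rem <- state_timeline(0, 1000, "REM")
  set.seed(2)
  ev2 <- simulate_movement_events(tl_rem, sim_params(
    session_duration = 1000, twitch_rate = 0.5,
    twitch_body_parts = "forelimb", seed = 2))
  n <- sum(ev2$class == "twitch")
  expect_gt(n, 500 - 3 * sqrt(500))
  expect_lt(n, 500 + 3 * sqrt(500))
  expect_true(all(state_at(tl_rem, ev2$onset_s[ev2$class == "twitch"]) == "REM"))
  # wake onsets pairwise >= 500 ms apart even at high rate
  set.seed(3)
  ev3 <- simulate_movement_events(tl_wake, sim_params(
    session_duration = 1000, wake_move_rate = 5, seed = 3))
  wt <- ev3$onset_s[ev3$class == "wake"]
  expect_true(all(diff(wt) >= 0.5))
  # empty timeline -> empty list
  expect_equal(nrow(simulate_movement_events(NULL, p)), 0L)
})

test_that("spike trains recover state-dependent baseline rates", {
  tl <- state_timeline(c(0, 500), c(500, 1000), c("REM", "quiet_wake"))
  p <- sim_params(session_duration = 1000,
                  baseline_rate = c(REM = 13.1, quiet_wake = 7.2), seed = 4)
  set.seed(4)
  nn <- neuron_spec("n0", kernels = list(
    twitch = list(latency_ms = 30, sigma_ms = 20, gain = 0, premove_fraction = 0.1),
    wake = list(latency_ms = 100, sigma_ms = 150, gain = 0, premove_fraction = 0.1)))
  tr <- simulate_spike_train(movement_events(numeric(0), character(0), character(0)),
                             tl, p, nn)
  rates <- baseline_rate_by_state(tr, tl)
  # 3 sigma Poisson bounds on 500 s counts
  expect_lt(abs(rates[["REM"]] - 13.1), 3 * sqrt(13.1 * 500) / 500)
  expect_lt(abs(rates[["quiet_wake"]] - 7.2), 3 * sqrt(7.2 * 500) / 500)
  expect_false(is.unsorted(tr$times))
})

test_that("event-triggered rate peaks at the kernel latency", {
  s <- twitch_recovery_session(list(latency_ms = 30, sigma_ms = 10, gain = 30,
                                    premove_fraction = 0.05),
                               seed = 5, duration = 900, rate = 0.4)
  ev <- s$events[s$events$class == "twitch", ]
  expect_gt(nrow(ev), 250)
  p <- zscore_peth(build_peth(s$spike_trains[[1]], ev))
  expect_lt(abs(peak_latency(p) - 30), 10 + 1e-9)
})

test_that("solved kernels place the requested mass before onset", {
  for (case in list(c(15, 40, 0.45), c(34, 25, 0.29), c(100, 150, 0.14),
                    c(100, 150, 0.07), c(0, 20, 0.5))) {
    k <- solve_kernel(list(latency_ms = case[1], sigma_ms = case[2],
                           gain = 10, premove_fraction = case[3]))
    # numeric CDF of the solved two-piece Gaussian at 0
    mass <- integrate(dkernel, -Inf, 0, kernel = k)$value
    expect_lt(abs(mass - case[3]), 1e-6)
    # mode sits at the latency
    tgrid <- seq(-1, 1, by = 1e-4)
    expect_lt(abs(tgrid[which.max(dkernel(tgrid, k))] - case[1] / 1000), 2e-4)
  }
})

test_that("trajectory excursions reproduce amplitude and angle exactly", {
  ev <- movement_events(1, "forelimb", "twitch", amplitude_mm = 10,
                        angle_deg = 90)
  p <- sim_params(session_duration = 3, trajectory_noise_px = 0, seed = 1)
  tr <- simulate_trajectory(ev, p, duration = 3)
  disp <- sqrt((tr$x - tr$x[1])^2 + (tr$y - tr$y[1])^2)
  expect_equal(max(disp), 57.5, tolerance = 1e-12)     # 10 mm x 5.75 px/mm
  ipk <- which.max(disp)
  expect_equal(tr$x[ipk], tr$x[1], tolerance = 1e-9)   # straight "up":
  expect_lt(tr$y[ipk], tr$y[1])                        # image y decreases
  # no events -> displacement bounded by noise
  p2 <- sim_params(session_duration = 3, trajectory_noise_px = 0.3, seed = 2)
  set.seed(2)
  tr2 <- simulate_trajectory(movement_events(numeric(0), character(0),
                                             character(0)), p2, duration = 3)
  expect_lt(max(abs(tr2$x - 360)), 0.3 * 5)
})

test_that("degenerate von Mises collapses to the mean direction", {
  set.seed(6)
  a <- rvonmises_deg(200, 129, 1e9)
  expect_true(all(abs(a - 129) < 1e-6))
  # concentration increases clustering around mu
  set.seed(6)
  sd_tight <- sd(rvonmises_deg(500, 180, 50))
  set.seed(6)
  sd_loose <- sd(rvonmises_deg(500, 180, 1))
  expect_lt(sd_tight, sd_loose)
})

test_that("pixel-change series marks onset frames exactly", {
  p <- sim_params(session_duration = 3, roi_noise_lambda = 0, seed = 1)
  ev <- movement_events(1.0, "forelimb", "twitch")
  ser <- simulate_pixel_change_series(ev, p, duration = 3)
  expect_equal(which(ser$values > 0)[1], 101L)          # t = 1.00 s, frame 101
  expect_equal(attr(ser, "onset_frames"), 101L)
  # no events, zero noise -> all-zero series
  ser0 <- simulate_pixel_change_series(
    movement_events(numeric(0), character(0), character(0)), p, duration = 3)
  expect_true(all(ser0$values == 0L))
  # two close events produce bookkept onsets even if pulses merge
  ev2 <- movement_events(c(1.0, 1.05), "forelimb", "twitch")
  ser2 <- simulate_pixel_change_series(ev2, p, duration = 3)
  expect_equal(attr(ser2, "onset_frames"), c(101L, 106L))
})

test_that("frame clock drops frames at the recorded indices", {
  p <- sim_params(session_duration = 60, dropped_frame_prob = 0, seed = 1)
  set.seed(1)
  cl <- simulate_frame_clock(p)
  expect_equal(length(attr(cl, "dropped_indices")), 0L)
  expect_true(all(validate_frame_intervals(cl)$deficit == 0))
  # binomial bound on the drop count: 6000 frames at p = 0.001
  p2 <- sim_params(session_duration = 60, dropped_frame_prob = 0.001, seed = 4)
  set.seed(4)
  drops <- replicate(30, length(attr(simulate_frame_clock(p2), "dropped_indices")))
  expect_lt(abs(mean(drops) - 6), 3 * sqrt(6 * 0.999 / 30))
})

test_that("ground truth accounts for every event and dropped frame once", {
  s <- simulate_session(quick_params(seed = 9, duration = 200))
  gt <- s$ground_truth
  for (bp in names(s$roi_series)) {
    n_ev <- sum(s$events$body_part == bp)
    expect_length(gt$roi_onset_frames[[bp]], n_ev)
  }
  drops <- gt$dropped_frame_indices
  expect_equal(anyDuplicated(drops), 0L)
  nominal <- floor(200 * 100) + 1
  expect_equal(length(s$frame_clock$frame_times), nominal - length(drops))
})
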