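# Movement detection, event-selection rules, state scoring, EMG rules.

test_that("LFP preprocessing preserves constants and conserves impulse mass", {
  const <- rep(2.5, 25000)
  out <- preprocess_lfp(const, fs = 25000)
  expect_length(out, 1000L)
  expect_true(all(abs(out - 2.5) < 1e-12))
  # unit impulse: smoothed mass conserved within 1e-6
  imp <- c(rep(0, 12500), 1, rep(0, 12499))
  sigma <- 0.0005 / sqrt(2 * log(2)) * 25000
  half <- ceiling(4 * sigma)
  kern <- exp(-((-half):half)^2 / (2 * sigma^2))
  sm_oracle_mass <- sum(kern / sum(kern))
  out2 <- preprocess_lfp(imp, fs = 25000)
  expect_lt(abs(sm_oracle_mass - 1), 1e-12)
  expect_true(max(out2) < 1 && max(out2) > 0)   # spread, not lost
  # white noise: variance reduced by smoothing
  set.seed(1)
  wn <- rnorm(25000)
  expect_lt(var(preprocess_lfp(wn, 25000)), var(wn))
  expect_error(preprocess_lfp(1:10, fs = 500), "below the target")
})

test_that("bout detection finds threshold crossings at the right frames", {
  v <- rep(0L, 400)
  v[101:110] <- 50L
  v[301:305] <- 50L
  ser <- pixel_change_series(v, frame_rate = 100)
  cand <- detect_movement_bouts(ser, onset_threshold = 10)
  expect_equal(nrow(cand), 2L)
  expect_equal(cand$onset, c(1.00, 3.00))
  # two pulses separated by sub-threshold frames stay distinct
  v2 <- rep(0L, 100); v2[10:20] <- 40L; v2[30:40] <- 40L
  cand2 <- detect_movement_bouts(pixel_change_series(v2, 100),
                                 onset_threshold = 10)
  expect_equal(nrow(cand2), 2L)
  # zero series -> no candidates
  empty <- detect_movement_bouts(pixel_change_series(rep(0L, 50), 100),
                                 onset_threshold = 10)
  expect_equal(nrow(empty), 0L)
})

test_that("detected onsets match ground truth within one frame", {
  p <- sim_params(session_duration = 300, twitch_rate = 0.3,
                  roi_noise_lambda = 1, seed = 21)
  s <- simulate_session(p)
  ser <- s$roi_series$forelimb
  truth <- s$events[s$events$body_part == "forelimb", ]
  # restrict to events whose ROI pulses do not overlap a neighbor's
  gaps_ok <- c(TRUE, diff(truth$onset_s) > 0.4) &
             c(diff(truth$onset_s) > 0.4, TRUE)
  truth <- truth[gaps_ok, ]
  expect_gt(nrow(truth), 10)
  cand <- detect_movement_bouts(ser, onset_threshold = 25)
  err <- vapply(truth$onset_s, function(o) min(abs(cand$onset - o)), 0)
  expect_true(all(err <= 0.01 + 1e-9))
})

test_that("wake quiescence rule keeps a maximal greedy-from-left subset", {
  cand <- data.frame(onset = c(0.0, 0.3, 1.0), offset = c(0.1, 0.4, 1.1),
                     peak = 1)
  kept <- mark_wake_movement_onsets(cand, 0.5)
  expect_equal(kept$onset, c(0.0, 1.0))
  # exactly 500 ms of quiescence is enough (inclusive rule)
  cand2 <- data.frame(onset = c(0, 0.6), offset = c(0.1, 0.7), peak = 1)
  expect_equal(nrow(mark_wake_movement_onsets(cand2, 0.5)), 2L)
  # single candidate retained
  expect_equal(nrow(mark_wake_movement_onsets(cand2[1, ], 0.5)), 1L)
  # maximality: with sorted disjoint bouts the greedy rule reduces to the
  # gap to the immediately preceding candidate's offset, so every removed
  # candidate violates it and every retained one satisfies it
  set.seed(2)
  on <- sort(runif(50, 0, 20))
  cand3 <- data.frame(onset = on, offset = on + 0.05, peak = 1)
  kept3 <- mark_wake_movement_onsets(cand3, 0.5)
  gap_prev <- c(Inf, cand3$onset[-1] - cand3$offset[-nrow(cand3)])
  expect_identical(cand3$onset %in% kept3$onset, gap_prev >= 0.5)
})

test_that("twitch isolation enforces the 100 ms cross-body-part rule", {
  ev <- movement_events(c(1.00, 1.05, 3.00, 3.15, 5.0),
                        c("forelimb", "whiskers", "forelimb", "whiskers",
                          "forelimb"),
                        "twitch")
  iso <- isolate_twitches(ev, 0.1, "cross_bodypart")
  # 1.00 excluded (whisker at 50 ms), 3.00 retained (150 ms), 5.0 retained
  expect_false(1.00 %in% iso$onset_s)
  expect_true(all(c(3.00, 3.15, 5.0) %in% iso$onset_s))
  # exhaustive invariant on a random session
  set.seed(5)
  ev2 <- movement_events(sort(runif(300, 0, 300)),
                         sample(c("forelimb", "hindlimb", "tail"), 300, TRUE),
                         "twitch")
  iso2 <- isolate_twitches(ev2, 0.1, "cross_bodypart")
  for (i in seq_len(nrow(iso2))) {
    other <- ev2[ev2$body_part != iso2$body_part[i], ]
    expect_gte(min(abs(other$onset_s - iso2$onset_s[i])), 0.1)
  }
  # same-body-part mode additionally spaces same-part neighbors
  ev3 <- movement_events(c(1.0, 1.05), "forelimb", "twitch")
  expect_equal(nrow(isolate_twitches(ev3, 0.1, "same_bodypart")), 0L)
  expect_equal(nrow(isolate_twitches(ev3[1, ], 0.1, "same_bodypart")), 1L)
})

test_that("state scoring recovers ground truth and applies the 3 s rule", {
  p <- sim_params(session_duration = 1200, twitch_rate = 0.4,
                  wake_move_rate = 0.2, seed = 6)
  s <- simulate_session(p)
  det <- lapply(s$roi_series, detect_movement_bouts, onset_threshold = 25)
  mt <- sort(unlist(lapply(det, `[[`, "onset")))
  tl <- classify_states(s$features$tone, s$features$delta, mt)
  grid <- seq(0.05, 1199.9, by = 0.1)
  a <- state_at(s$timeline, grid)
  b <- state_at(tl, grid)
  a[!a %in% c("NREM", "REM")] <- "wake"
  b[!b %in% c("NREM", "REM")] <- "wake"
  expect_gt(mean(a == b, na.rm = TRUE), 0.9)
  # wake samples within 3 s after a movement are active wake
  tt <- seq(0, 99.9, by = 0.1)
  flat <- data.frame(time = tt, value = 1)
  low <- data.frame(time = tt, value = 0)
  tl_aw <- classify_states(flat, low, movement_times = 50)
  expect_equal(state_at(tl_aw, 51.5), "active_wake")
  expect_equal(state_at(tl_aw, 49.0), "quiet_wake")
  expect_equal(state_at(tl_aw, 54.0), "quiet_wake")
  # constant high tone, no movements -> all quiet wake
  tl2 <- classify_states(flat, flat, numeric(0))
  expect_equal(unique(tl2$state), "quiet_wake")
  # mismatched time bases error
  expect_error(classify_states(flat, data.frame(time = tt + 1, value = 1)),
               "time base")
})

test_that("EMG inclusion applies the z >= 2 rule inclusively", {
  tt <- seq(0, 60, by = 0.001)
  set.seed(7)
  emg <- data.frame(time = tt, value = abs(rnorm(length(tt))))
  ev <- movement_events(c(10, 30), "forelimb", "twitch")
  # inject a strong burst at the first event only
  emg$value[emg$time >= 10 & emg$time <= 10.08] <- 8
  mask <- emg_event_inclusion(emg, ev, z_threshold = 2)
  expect_true(mask[1])
  # flat EMG excludes everything (zero SD warning, one per event)
  flat <- data.frame(time = tt, value = 1)
  expect_warning(mask1 <- emg_event_inclusion(flat, ev[1, ]),
                 "zero baseline SD")
  expect_false(mask1)
  mask2 <- suppressWarnings(emg_event_inclusion(flat, ev))
  expect_false(any(mask2))
  # boundary: peak exactly at z = 2 is included
  base <- rep(c(0, 2), length.out = length(tt))     # mean 1, sd 1.0000...
  emg3 <- data.frame(time = tt, value = base)
  s <- sd(base[tt >= 9 & tt < 9.8])
  emg3$value[emg3$time >= 10 & emg3$time < 10.05] <- 1 + 2 * s
  mask3 <- emg_event_inclusion(emg3, ev[1, ], z_threshold = 2)
  expect_true(mask3[1])
})

test_that("grand mean EMG weights animals equally, not by event count", {
  a <- matrix(1, nrow = 10, ncol = 4)      # animal A: 10 events of [1,1,1,1]
  b <- matrix(3, nrow = 1000, ncol = 4)    # animal B: 1000 events of [3,3,3,3]
  gm <- grand_mean_emg(list(A = a, B = b))
  expect_equal(gm, rep(2, 4))
  # one animal: grand mean equals that animal's mean
  expect_equal(grand_mean_emg(list(A = a)), rep(1, 4))
  # permutation invariance
  expect_equal(grand_mean_emg(list(B = b, A = a)), gm)
  expect_error(grand_mean_emg(list()), "no animals")
})
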