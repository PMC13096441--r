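# Temporal metrics: latency, width at half-height, premovement proportion,
# Fano factor, state-conditioned rates.

test_that("peak latency reports the earliest maximal bin center", {
  trace <- rep(c(1, 3), 300)
  trace[304] <- 30
  p <- zscore_peth(fake_peth(trace))
  expect_equal(peak_latency(p), 35)
  # tie -> earliest bin
  trace[306] <- 30
  p2 <- zscore_peth(fake_peth(trace))
  expect_equal(peak_latency(p2), 35)
  expect_true(is.na(peak_latency(suppressWarnings(
    zscore_peth(fake_peth(rep(2, 600)))))))
})

test_that("latency recovery preserves the faster-structure ordering", {
  lat <- vapply(list(c(15, 25, 0.45), c(34, 15, 0.29)), function(cs) {
    s <- twitch_recovery_session(list(latency_ms = cs[1], sigma_ms = cs[2],
                                      premove_fraction = cs[3]),
                                 seed = 41, duration = 3000, rate = 0.5,
                                 gain = 40)
    ev <- s$events[s$events$class == "twitch", ]
    peak_latency(zscore_peth(build_peth(s$spike_trains[[1]], ev)))
  }, 0)
  expect_lt(abs(lat[1] - 15), 10 + 1e-9)     # within one 10 ms bin
  expect_lt(abs(lat[2] - 34), 10 + 1e-9)
  expect_lt(lat[1], lat[2])                  # subcortical leads cortical
})

test_that("width at half-height matches the independent oracle", {
  # minimal-width helper entry point: one 1 ms sample at 1.0
  expect_equal(width_at_half_height(c(rep(0, 50), 1, rep(0, 50))), 1)
  # analytic Gaussian bumps across widths
  for (sig in c(0.01, 0.02, 0.04)) {
    trace <- analytic_peth_trace(0.03, sig, gain = 40, baseline_rate = 5)
    p <- fake_peth(trace)
    got <- width_at_half_height(p)
    want <- oracle_whh(trace, p$bin_centers)
    expect_equal(got, want)
    # for kernels wide relative to the boxcar, the variance-addition
    # approximation of smoothing broadening holds to 15%:
    # 5-bin boxcar (10 ms bins) adds variance (5^2-1)/12 bins^2
    if (sig >= 0.02) {
      broadened <- 2.355 * sqrt((1000 * sig)^2 + (25 - 1) / 12 * 100)
      expect_lt(abs(got - broadened) / broadened, 0.15)
    }
  }
  # width increases monotonically with kernel sigma
  widths <- vapply(c(0.01, 0.02, 0.04), function(sig)
    width_at_half_height(fake_peth(analytic_peth_trace(0.03, sig, 40, 5))), 0)
  expect_true(all(diff(widths) > 0))
  # flat trace: undefined width
  expect_error(width_at_half_height(fake_peth(rep(2, 600))), "undefined")
})

test_that("twitch premovement proportion integrates and clamps correctly", {
  # symmetric response about onset confined to +/- 0.2 s -> exactly 0.5
  sym <- analytic_peth_trace(0, 0.04, gain = 30, baseline_rate = 0)
  psym <- fake_peth(sym)
  psym$z_trace <- sym                       # already baseline-zero
  psym$baseline_sd <- 1
  expect_equal(premove_proportion_twitch(psym, c(-0.2, 0.2)), 0.5,
               tolerance = 1e-9)
  # strictly post-onset activity -> 0
  post <- analytic_peth_trace(0.1, 0.02, gain = 30, baseline_rate = 0)
  ppost <- fake_peth(post); ppost$z_trace <- post; ppost$baseline_sd <- 1
  expect_lt(premove_proportion_twitch(ppost, c(-0.2, 0.75)), 0.01)
  # strictly pre-onset activity -> 1 (after clamping logic, still in [0,1])
  pre <- analytic_peth_trace(-0.1, 0.02, gain = 30, baseline_rate = 0)
  ppre <- fake_peth(pre); ppre$z_trace <- pre; ppre$baseline_sd <- 1
  expect_gt(premove_proportion_twitch(ppre, c(-0.2, 0.2)), 0.99)
  # non-positive total -> undefined
  neg <- -analytic_peth_trace(0, 0.05, 30, 0)
  pneg <- fake_peth(neg); pneg$z_trace <- neg; pneg$baseline_sd <- 1
  expect_true(is.na(premove_proportion_twitch(pneg, c(-0.2, 0.2))))
})

test_that("premovement fraction is recovered from simulated kernels", {
  cases <- list(rn = c(15, 25, 0.45), m1 = c(34, 25, 0.29))
  for (nm in names(cases)) {
    cs <- cases[[nm]]
    s <- twitch_recovery_session(list(latency_ms = cs[1], sigma_ms = cs[2],
                                      premove_fraction = cs[3]),
                                 seed = 42, duration = 1500, gain = 20)
    ev <- s$events[s$events$class == "twitch", ]
    p <- zscore_peth(build_peth(s$spike_trains[[1]], ev))
    got <- premove_proportion_twitch(p, c(-0.2, 0.2))
    expect_lt(abs(got - cs[3]), 0.05)
  }
})

test_that("wake premovement uses the smoothed pre-onset minimum", {
  # flat pre-onset trace: proportion driven by post-onset mass only
  post <- analytic_peth_trace(0.3, 0.05, gain = 30, baseline_rate = 0)
  p <- fake_peth(post); p$z_trace <- post; p$baseline_sd <- 1
  expect_lt(premove_proportion_wake(p), 0.06)
  # a pre-onset dip relocates the window start to the dip minimum
  dip <- rep(0, 600)
  centers <- fake_peth(dip)$bin_centers
  dip <- -2 * exp(-(centers + 0.3)^2 / (2 * 0.03^2)) +
         10 * exp(-(centers - 0.2)^2 / (2 * 0.05^2))
  pd <- fake_peth(dip); pd$z_trace <- dip; pd$baseline_sd <- 1
  sm <- motorpeth:::boxcar_smooth(dip, 20L)
  pre <- which(centers >= -0.5 & centers < 0)
  t_min_oracle <- centers[pre[which.min(sm[pre])]]
  expect_lt(abs(t_min_oracle - (-0.3)), 0.1)   # the dip is found near -0.3 s
  got <- premove_proportion_wake(pd)
  # oracle recomputation of the adjusted-baseline integrals
  adj <- dip - sm[pre[which.min(sm[pre])]]
  sel_all <- centers >= t_min_oracle & centers <= 1
  sel_num <- centers >= t_min_oracle & centers <= 0
  want <- max(0, min(1, pracma::trapz(centers[sel_num], adj[sel_num]) /
                          pracma::trapz(centers[sel_all], adj[sel_all])))
  expect_lt(abs(got - want), 0.01)
  # recovery of simulated wake premovement fractions
  for (frac in c(0.14, 0.07)) {
    s <- wake_recovery_session(list(latency_ms = 100, sigma_ms = 150,
                                    premove_fraction = frac),
                               seed = 43, duration = 2500, gain = 25)
    ev <- s$events[s$events$class == "wake", ]
    pw <- zscore_peth(build_peth(s$spike_trains[[1]], ev))
    expect_lt(abs(premove_proportion_wake(pw) - frac), 0.05)
  }
})

test_that("Fano factor follows its definition and Poisson calibration", {
  tr <- spike_train("n", c(9.99, 10.0, 20.0, 20.01, 20.02, 20.05),
                    span = c(0, 30))
  # counts [2, 4] in +/- 70 ms windows -> var 2 / mean 3
  f <- fano_factor(tr, c(10, 20), c(-0.07, 0.07))
  expect_equal(f, 2 / 3, tolerance = 1e-12)
  # constant counts -> 0
  trc <- spike_train("n", c(10.01, 20.01), span = c(0, 30))
  expect_equal(fano_factor(trc, c(10, 20), c(-0.07, 0.07)), 0)
  # boundary arithmetic: spikes at -0.071 and +0.069 -> one counted
  trb <- spike_train("n", c(9.929, 10.069), span = c(0, 30))
  expect_equal(spike_counts_in_window(trb, c(10, 20), c(-0.07, 0.07)),
               c(1L, 0L))
  # Poisson counts at 1000 events -> Fano within 1 +/- 0.1
  set.seed(44)
  ev <- seq(10, by = 1, length.out = 1000)
  spikes <- sort(unlist(lapply(ev, function(o)
    o - 0.07 + runif(rpois(1, 4), 0, 0.14))))
  trp <- spike_train("n", spikes, span = c(0, 1100))
  expect_lt(abs(fano_factor(trp, ev, c(-0.07, 0.07)) - 1), 0.1)
  # order invariance
  expect_equal(fano_factor(trp, rev(ev), c(-0.07, 0.07)),
               fano_factor(trp, ev, c(-0.07, 0.07)))
  # zero mean -> undefined
  expect_true(is.na(fano_factor(spike_train("n", 5, span = c(0, 30)),
                                c(10, 20), c(-0.07, 0.07))))
})

test_that("state-conditioned rates conserve spikes across the partition", {
  set.seed(45)
  tl <- state_timeline(c(0, 300, 600), c(300, 600, 900),
                       c("REM", "NREM", "quiet_wake"))
  tr <- spike_train("n", sort(runif(9000, 0, 900)), span = c(0, 900))
  rates <- baseline_rate_by_state(tr, tl)
  # homogeneous 10 spikes/s train: ~10 in every state
  expect_true(all(abs(rates - 10) < 3 * sqrt(10 * 300) / 300))
  # conservation: state counts sum to the total in-span count
  total <- sum(rates * 300)
  expect_equal(round(total), length(tr$times))
  # spikes outside all intervals count nowhere
  tl2 <- state_timeline(100, 200, "REM")
  r2 <- baseline_rate_by_state(tr, tl2)
  expect_equal(round(r2[["REM"]] * 100),
               sum(tr$times >= 100 & tr$times < 200))
})
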