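# motorpeth

Perievent analysis of movement-related neural activity across sleep and
wake, for developmental sensorimotor electrophysiology.

In infant mammals, brief REM-sleep twitches and longer wake movements drive
sensory-feedback activity that shapes developing motor circuits. Studies of
this process record extracellular spike trains alongside synchronized
high-speed video and EMG, then ask: which neurons are movement-active, how
fast and how temporally precise is their activity, how much of it precedes
movement onset, and is firing tuned to movement direction or amplitude?
`motorpeth` implements that full analysis chain in R, plus a
synthetic-session generator with complete ground truth so every stage can
be validated by parameter recovery.

## The model at the core

For a neuron with spike times aligned to `n` movement onsets, the perievent
time histogram (PETH) counts spikes in 10 ms bins over a −3..3 s window.
With baseline statistics taken across the baseline bins (−3..−0.5 s) of the
trial-mean trace x̄(t),

    z(t) = ( x̄(t) − μ_baseline ) / σ_baseline

a neuron is **twitch-active** if max z(t) ≥ 3.5 for t ∈ [−100, 250] ms
(wake-active: t ∈ [−100, 500] ms), given more than 20 events. On top of the
z trace the package computes peak latency, width at half-height (5-bin
smoothing → 1 ms interpolation → normalized half-height run), the
premovement proportion ∫z over [−0.2, 0] s divided by the window integral
(trapezoidal, clamped at 0), the Fano factor var/mean of per-event counts
(−70..70 ms twitches, −100..500 ms wake movements), direction tuning
η² = SS_between/SS_total over 12 angular bins, and amplitude tuning
r² (Pearson²) against counts, with a strict 0.1 selectivity threshold.

Upstream of the statistics it provides LED-pulse frame-clock validation and
dummy-frame repair (300 frames per 3 s pulse at 100 fps), ROI pixel-change
movement detection, the 100 ms twitch-isolation and 500 ms wake-quiescence
rules, rule-based sleep/wake scoring from EMG tone and delta power,
pose-table (3-header CSV dialect) ingestion at 5.75 px/mm, and group
statistics with Bonferroni post hocs and the 3-scaled-MAD outlier rule.

## Worked example

Generate a five-neuron-style fixture session (four neurons, four twitching
body parts, 600 s), then classify and characterize one neuron:

```r
library(motorpeth)

fx  <- make_fixtures(seed = 42, dir = tempfile(), duration = 600)
s   <- fx$session
iso <- isolate_twitches(s$events, 0.1, "cross_bodypart")
fl  <- iso[iso$body_part == "forelimb", ]      # 114 isolated twitches

tr <- s$spike_trains$rn_tuned
p  <- zscore_peth(build_peth(tr, fl))
classify_movement_active(p, "twitch")
peak_latency(p); width_at_half_height(p)
premove_proportion_twitch(p, c(-0.2, 0.2))
baseline_rate_by_state(tr, s$timeline)
```

Output:

```
<spike_train> rn_tuned (RN): 8463 spikes over 600.0 s (14.11 spikes/s)
twitch-active: TRUE (peak z = 17.5 at +15 ms)
peak latency: 15 ms | width at half-height: 118 ms | premovement proportion: 0.45
Fano factor (twitch window): 4.13
      NREM        REM quiet_wake
      9.06      16.97      12.73
```

The `rn_tuned` fixture neuron was generated with a response kernel whose
mode is 15 ms after twitch onset and 45% of whose mass precedes the onset —
both recovered exactly by the analysis (the 118 ms width reflects the
kernel's ~111 ms full width at half maximum plus the mandated 5-bin
smoothing). Baseline firing is higher in REM than wake, the regime these
recordings show. With only ~56 wake movements in 600 s, tuning statistics
are small-sample; the recovery tests use sessions with 400+ movements.

An end-to-end run (simulate → sync repair → detect → state-score →
classify → metrics → tuning → stats, with all tables and a run manifest):

```r
res <- run_pipeline(seed = 11, out_dir = "run1")
res$classifications
```

A thin command-line wrapper over the same functions is installed at
`inst/cli/motorpeth.R` (`Rscript motorpeth.R run-all --seed 11 --out-dir run1`).

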