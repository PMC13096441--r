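---
title: "Models and methods behind motorpeth"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind motorpeth}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(motorpeth)
```

## The scientific problem

In infant mammals, self-generated movements — brief myoclonic twitches
during REM sleep and longer, multi-muscle wake movements — drive
sensory-feedback (reafferent) activity that shapes developing sensorimotor
circuits. Quantifying that activity requires a chain of steps: synchronizing
high-speed video to the electrophysiology clock, detecting movement onsets
from region-of-interest (ROI) pixel changes, scoring behavioral state from
nuchal EMG and cortical delta power, aligning spike trains to movement
onsets, deciding which neurons are movement-active, and relating firing to
movement kinematics. `motorpeth` implements this chain as reusable,
individually testable functions, together with a synthetic-session generator
whose ground truth makes every stage verifiable by parameter recovery.

## The perievent model and the activation rule

The core object is the perievent time histogram (PETH): spike counts in
10 ms bins over a −3..3 s window around each event onset (600 bins). The
trial-mean trace is z-scored against its own baseline, taken as the mean and
standard deviation *across the baseline bins* (−3..−0.5 s) of the mean
trace. A neuron is movement-active when its z trace reaches at least 3.5
inside the class window: −100..250 ms for twitches, −100..500 ms for wake
movements. Classification requires strictly more than 20 events; with fewer
events the neuron is reported as `insufficient_events`, not inactive.

Two points were genuinely open and are resolved as follows:

* *Baseline SD across bins vs across trials.* We compute the SD across the
  baseline bins of the trial-mean histogram. The alternative (SD of
  per-trial counts) yields systematically smaller z values as event counts
  grow; the bin-wise convention makes the z threshold comparable across
  neurons with different event counts.
* *"A clear peak".* Operationalized as exactly the z ≥ 3.5 window rule with
  no additional shape test, since it is the only quantitative criterion
  available; this makes false-positive calibration meaningful (see below).

The somatotopic preference of a neuron is the body part with the largest
super-threshold peak, computed only from *cross-body-part-isolated*
twitches (no other body part twitching within ±100 ms). Ties — which never
occur in continuous data but can in principle — break deterministically by
earlier peak time, then lexical order, and are logged.

## Temporal metrics

* **Peak latency** is the bin-center time of the maximal z value in the
  response window (ties to the earliest bin). Reporting at bin centers is
  unbiased under 10 ms binning.
* **Width at half-height** follows a fixed pipeline: 5-bin moving-average
  smoothing, linear upsampling from 10 ms to 1 ms bins, affine
  normalization (baseline to 0, peak to 1), then the count of contiguous
  1 ms bins above 0.5 around the peak. The "5-bin kernel" (and the 20-bin
  kernel below) is a boxcar: the simplest reading, and the kernel choice is
  a config option. Smoothing broadens the measured width; for kernels wide
  relative to the boxcar the broadening is well approximated by adding
  (5² − 1)/12 squared bins of variance.
* **Premovement proportion** (twitches) is the trapezoidal integral of the
  z trace over −0.2..0 s divided by the integral over the analysis window
  (−0.2..0.75 s for developmental analyses, −0.2..0.2 s for
  cross-structure comparisons). The trace is linearly interpolated at the
  window bounds so numerator and complement partition the total exactly. A
  negative numerator is clamped to 0; a non-positive total leaves the
  proportion undefined (the neuron is excluded and logged).
* **Premovement proportion** (wake movements) re-zeroes the trace at an
  adjusted baseline — the minimum of the 20-bin-smoothed z trace in the
  preceding 500 ms — and integrates from that minimum to +1 s. The
  numerator runs from the window start to onset: the two printed
  conventions (a fixed −0.2..0 numerator vs a window starting at the
  minimum) interact, and we take the window-start reading so the numerator
  is always inside the analysis window.
* **Fano factor** is the sample variance (n − 1 denominator) of per-event
  spike counts in the activity window (−70..70 ms twitches, −100..500 ms
  wake movements) divided by their mean; a zero mean leaves it undefined.

## Kinematics and selectivity

Movement amplitude is the peak Euclidean displacement from the onset-frame
position within 150 ms (twitch) or 500 ms (wake movement), converted at
5.75 px/mm. The movement angle is the direction of the onset-to-peak vector
in mathematical convention (counterclockwise from +x, y up); pose tables are
in image coordinates, so the y axis is flipped on conversion. An alternative
reading — the circular mean of the per-frame onset-to-position vectors up to
the peak — is available behind `kinematics$angle_method = "path_mean"`;
`"at_peak"` is the default because it matches the operational definition of
"angle at peak displacement".

Direction selectivity is the one-way eta squared of per-movement spike
counts grouped into 12 equal 30° bins (grand-mean decomposition, empty bins
dropped); amplitude selectivity is the squared Pearson correlation between
amplitude and count (identical to the simple-regression R²). Both use a
strict > 0.1 threshold. Note the small-sample behavior of eta squared: its
null expectation is roughly (k − 1)/(n − 1) with k occupied bins, i.e.
about 0.14 at n = 80 movements — so selectivity calls are only meaningful
with a few hundred movements, which the recovery tests use (n ≈ 400+).

The preferred/non-preferred movement split classifies events by spike count
in a 300 ms post-onset window against the count expected from baseline
alone: at most half the expected count is non-preferred, at least one and a
half times is preferred, both boundaries inclusive — the only reading
consistent with integer thresholds of 2 and 6 at an expected count of 4.

## Synchronization and detection

The video clock is validated against an LED that pulses every 3 s: at
100 frames/s every inter-pulse gap must contain exactly 300 frames. Missing
frames are restored at their *nominal grid slots* within the deficient gap
(nearest-slot matching): this recovers the true drop location when it is
identifiable, bounds residual drift at half a frame, and makes repair
idempotent. Gaps with surplus frames are unrecoverable and raise an error.

Movement candidates are upward threshold crossings of the ROI pixel-change
series; the onset is the first frame above threshold. The default threshold
is the series median plus 3 scaled MADs — an explicit, logged stand-in for
the manual video confirmation step that a human scorer performs; it is a
config constant precisely because it is the one step that cannot be
reproduced from a written description alone. Wake-movement onsets then apply the
500 ms quiescence rule (greedy from the left, inclusive at the boundary),
and whisker candidates closer than 100 ms collapse into the first, since
whisker protraction/retraction series lack clear boundaries.

## Behavioral state scoring

A simplified rule-based scorer replaces expert judgment: atonia bouts
(nuchal tone below threshold) that contain at least one detected movement
are REM; quiescent samples with high delta power are NREM; everything else
is wake, split into active wake (within 3 s after a movement) and quiet
wake. NREM atonia — which does occur — is handled by the movement
requirement: an atonia bout without movements falls through to the delta
rule. Because absolute trace scales vary between preparations, each
threshold sits at a configurable *fraction of the trace's robust dynamic
range* (5th..95th percentile): 0.2 for tone, 0.7 for delta. A plain
quantile threshold was rejected because it slices inside the dominant
amplitude cluster whenever a state's time occupancy differs from the
quantile, which capped recovery on simulated sessions at about 67%;
the range-fraction rule recovers ground-truth states with ≥ 99%
time-weighted agreement. Traces are smoothed over 1 s before thresholding —
state transitions are slow relative to trace noise.

## The synthetic-session generator

The generator emulates, with full ground truth: exponential sleep/wake
cycling (default mean dwells 120 s NREM, 45 s REM, 75 s quiet wake — REM
occupancy just under 20%, the older end of the developmental range;
fixtures use a REM-rich young-pup profile); state-dependent Poisson
baseline firing (defaults 13.1 spikes/s REM vs 7.2 wake, the reported
regime); Poisson twitching confined to REM per body part; wake movements
with the 500 ms spacing rule; von Mises movement angles (Best–Fisher
sampler, since no installed package provides one) and log-normal amplitudes
(means 0.96 mm twitch, 6.95 mm wake); direction- and amplitude-tuned spike
gains; raised-cosine limb excursions with pixel-exact peak displacement;
ROI pixel-change pulses starting exactly at onset frames; and a frame clock
with independent frame drops.

The movement-locked rate kernel is a **two-piece (split) Gaussian**: mode
exactly at the target latency, right-hand width σ_r, left-hand width solved
so the mass before onset equals the target premovement fraction. A
skew-normal kernel was considered and rejected: with its mode pinned at the
latency, its mass before the mode is capped at one half (the half-normal
limit), so premovement fractions such as 0.29 at a 34 ms latency are
unreachable at realistic widths. The split Gaussian reaches any fraction in
(0, 1) while keeping both ground truths (latency = mode, premovement = left
mass) exact. Kernel widths for the recovery experiments follow the
structures being emulated: broad for the subcortical generator
(σ_r = 25 ms, FWHM ≈ 78 ms), narrower for cortex (σ_r = 15 ms,
FWHM ≈ 65 ms), consistent with the broader subcortical responses the
recordings show.

What the generator does *not* emulate — and hence what passing tests do not
show about real data: spike-sorting contamination and unit drift, movement
artifacts in the EMG, correlated (non-Poisson) baseline firing, twitch
clustering beyond Poisson placement (the inter-twitch-interval distribution
is not characterized beyond the 100 ms isolation rule, so Poisson placement
is an assumption), camera-perspective distortion of kinematics, and
pose-estimation failures other than Gaussian jitter.

## Null calibration and numerical choices

False-positive calibration of the z ≥ 3.5 rule simulates homogeneous
Poisson neurons at the REM baseline regime (13.1 spikes/s), where twitches
are actually scored. This matters: the family-wise false-positive rate of a
max-over-bins rule depends on the per-bin count distribution, and at low
rates (e.g. 5 spikes/s, 10 ms bins, 100 events) the Poisson upper tail is
heavy enough that the same rule exceeds a 5% false-positive rate even
though it calibrates comfortably below 5% at the study's rates.

Other numerical conventions: times are seconds (float), frame indices
0-based, all intervals and spike-count windows half-open `[lo, hi)`;
PETH binning is half-open per bin; trapezoidal integrals interpolate at
window bounds; moving averages renormalize at the edges (so constants are
preserved); pose points below 0.85 likelihood are flagged but kept, since
that figure describes a network-retraining criterion, not a per-point
filter; the scaled-MAD outlier rule (3 × 1.4826 × MAD) trims distribution
summaries only — hypothesis tests always run on full data; chi-squared
tests use no continuity correction; Bonferroni correction multiplies raw
post-hoc p values by the comparison count, capped at 1.

## Problem sizes

The bundled tests and the acceptance script run everything at desk scale,
chosen as the smallest sizes at which the stochastic criteria are stable:
recovery sessions of 1200–3000 simulated seconds (roughly 700–1500 events),
1000-replicate null calibrations, 1000-instance oracle sweeps, and a 5-min
four-neuron fixture session. Sessions of several hours and hundreds of
neurons run in proportionally longer but unremarkable time; `build_peth()`
uses binary search per event and scales as O(events × log spikes).

## Known limitations

* The state scorer is a deliberately simplified stand-in for expert
  scoring; theta-oscillation cues used for older pups are out of scope.
* Manual video confirmation of candidate movements is replaced by a single
  logged threshold; on real data the threshold needs per-ROI review.
* Wake-movement duration/timing comparisons across ages are intentionally
  not implemented, and grooming-vs-locomotion labeling is assumed to arrive
  as a labeled table.
* The event/spike generators draw independent events; refractory structure
  and burst firing are not modeled.
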