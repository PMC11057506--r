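---
title: "Methods: movement-aligned analysis of microendoscopic calcium signals"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: movement-aligned analysis of microendoscopic calcium signals}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(strical)
```

`strical` implements the downstream analysis of one-photon microendoscopic
Ca²⁺ imaging recorded together with head-mounted accelerometry in freely
moving mice: movement segmentation from total body acceleration, ΔF/F
extraction and transient detection, a circular-shift bootstrap for
event-locked response significance, reliability and recruitment statistics,
distance-binned pairwise signal correlations, and shift-predictor-corrected
joint peristimulus time histograms (JPSTHs). This vignette explains the
procedures, their assumptions, the tunable parameters, and the design
decisions taken where the methods literature leaves choices open.

## Kinematics

Total body acceleration (BA) is the per-sample Euclidean norm of the three
head-accelerometer axes, in units of g. In a session containing both rest
and movement its distribution is bimodal: a sharp rest mode (gravity plus
sensor noise) and a broad movement mode. `find_movement_threshold()`
automates the midpoint rule: a 100-bin histogram over the observed range is
smoothed with a 5-bin moving average; the two highest local maxima at least
5 bins apart are the modes, and the threshold is their midpoint. Two modes
are accepted only if the smoothed histogram drops below half the height of
the lower peak between them — without this valley requirement any noisy
unimodal histogram yields two spurious "peaks". When bimodality fails the
function signals a typed condition so a caller can fall back to a manual
threshold, mirroring practice with real sessions.

Frames above threshold are movement, frames below are rest
(`segment_movement()`; minimum bout length one frame, since shorter
constraints are an open choice we did not impose). The acceleration-change
amplitude of an onset is the maximal BA within 2 s after the onset minus BA
at the onset; session quartiles of these amplitudes define "small" (Q1) and
"large" (Q4) acceleration-change events, with boundary ties assigned to the
lower quartile for determinism.

Frames are 1-based R indices throughout the package, with
`frame = floor(t * fs) + 1` at `fs` = 15 frames/s; one frame (≈67 ms) is
also the canonical analysis bin.

## ΔF/F, transients, annuli

The baseline F₀ of a raw fluorescence trace is the minimum over the means
of all 2 s windows placed at 1 s steps (consecutive windows overlap by
1 s); a final window anchored at the trace end covers the remainder. ΔF/F
is (F − F₀)/F₀, which makes the measure invariant to multiplicative
rescaling of F.

Ca²⁺ transients are strict local maxima of the ΔF/F trace (plateaus
contribute their first frame) whose height exceeds both 2 SD of the trace
and the absolute value of its largest negative deflection. The SD is
computed over the full session; detection counts are monotone
non-increasing in the SD multiplier.

For each somatic ROI an annulus samples the local neuropil: a ring with the
same pixel area as the ROI, whose inner radius is the distance from the
ROI's center of mass to its farthest border pixel plus 5 px. The outer
radius solves the equal-area equation analytically; rasterization then
takes the ROI-area pixels nearest the center of mass among those at or
beyond the inner radius, so the discrete ring area matches the ROI area
(to within distance ties). For decay-kinetics comparisons the annulus raw
trace is subtracted from the somatic raw trace before ΔF/F extraction, and
`a·exp(−t/τ) + b` is fitted from the peak of the event-triggered average
over a 3 s window (5 s for the slower annular signals); starting values
come from a crude time-to-1/e estimate and the fit uses the `port`
algorithm with τ bounded positive.

## Event-locked significance: circular-shift bootstrap

For each neuron and event type the event-triggered average (ETA) is the
mean trace in a 5 s (or 10 s) window around the onsets, with
`pre = ceiling(span·fs/2)` frames before the onset. The test statistic is
computed from the ETA alone: its 85th percentile is a threshold line, the
single longest run of consecutive supra-threshold frames is located, and
the area between the ETA and the line over that run is the statistic. The
null distribution circularly shifts the full-session trace by a uniform
random number of frames, recomputes the ETA at the same event times, and
recomputes the statistic, 2,000 (or 5,000) times; the p-value uses the
add-one estimator (1 + #{null ≥ observed})/(1 + n) so it is never zero.
The 85th percentile is taken over the ETA's own window values — the
reference distribution is not otherwise specified in the methods
literature, and this choice makes the statistic scale-free. Because the
statistic only scores upward excursions, suppression reaches significance
only through the structure of its shuffled nulls; a two-sided variant that
also scores the area below the matching low quantile is provided but off
by default.

Significant neurons are labeled positively or negatively modulated by
comparing the mean ETA over the 1 s after the onset with the 1 s before
(ties, which essentially never occur with continuous data, are labeled
positive with a warning). Reliability is the fraction of events followed by
a detected transient within 1 s (computed for positively modulated neurons,
whose transients the detector can see); per-event population recruitment
uses a 1.5 s window, which floors to 22 frames.

An important caveat for simulation studies: circular-shift nulls assume the
events are irregularly spaced. Near-periodic event trains make every
circular shift realign the events with the true responses, destroying the
null. The synthetic sessions used in the tests therefore draw onsets with
random spacing above a minimum gap.

## Cross-session overlap

Registered cells are accepted when the registration confidence exceeds
`p_same > 0.5` and the centroid distance across sessions is below 14 µm
(both strict). Observed overlap fractions are compared against the
independence expectation: with per-session responsive probabilities p₁ and
p₂ the expected both-responsive fraction is p₁·p₂ (0.22 and 0.27 give
0.0594, i.e. 6% to the nearest percent); for k sessions the full
"significant in exactly j of k" profile is the Poisson-binomial
distribution, computed by polynomial convolution.

## Pairwise correlations and distance

Rest windows are 2 s long and start 250 ms after a movement offset, one per
rest interval of at least 2.5 s; movement windows are 2 s centered on each
onset; cue windows are 2 s from cue onset (the cue-window placement is not
pinned down externally; it is configurable). Pearson correlations are
computed within each window and averaged across windows per pair; windows
where either trace is constant are skipped and counted. Pairs are binned by
centroid distance in half-open 10 µm bins, each non-empty bin is
represented by its unweighted mean correlation, and ordinary least squares
of mean correlation on bin-center distance gives the slope, R², and p.
Empty bins are dropped, not zero-filled.

A calibration note: the OLS p-value treats bin means as independent. When
all pairs share a single global correlation factor, estimation errors are
correlated across pairs through shared neurons and the test becomes
anti-conservative. The package's null simulations for this analysis
therefore use uncorrelated traces (matching the near-zero somatic
correlations seen in this preparation) and 3,000-frame sessions (100 2-s
windows), where estimation noise is small enough for nominal coverage.

## JPSTH

Each repetition of a behavioral event is a trial; a trial matrix marks, per
67 ms bin, whether the neuron produced at least one detected transient (at
one frame per bin an indicator and a count coincide). The raw JPSTH entry
(t₁, t₂) counts trials in which neuron 1 was active in bin t₁ and neuron 2
in bin t₂. The shift predictor pairs trial n of neuron 1 with trial n + m
of neuron 2 circularly and averages over all N − 1 nonzero shifts; the sum
over all N shifts factorizes exactly into the outer product of the two
neurons' per-bin counts, so the predictor is computed in closed form as
`(outer(colSums) − raw)/(N − 1)` — bin-for-bin identical to the explicit
loop, which the test suite verifies by brute-force enumeration. The
corrected JPSTH is raw minus predictor, smoothed with a 2-D Gaussian of
1 bin SD (kernel truncated at 3 SD, renormalized at the matrix edges so a
constant field is preserved exactly). Normalization divides by the product
of the scalar SDs of the two neurons' PSTH curves, making the matrix
unitless and approximately bin-width independent; the classical per-bin
across-trial-SD normalization is available behind a flag, but with sparse
transient trains many bins have zero across-trial variance, so the scalar
reading is the default. The population JPSTH is the elementwise mean of the
normalized corrected matrices over pairs (optionally restricted to
modulation-defined subgroups).

The diagonal of the population JPSTH tracks zero-lag noise correlation
around the event. Random fluctuation is gauged from surrogate events
displaced by a random circular shift of at least 20 s, using a 10 s window;
the band is the mean ± SD of that diagonal. Two design decisions here:
(i) the surrogate matrices are normalized by the *event-aligned* per-pair
PSTH-SD denominators, so band and diagonal share one scale — normalizing
the surrogate by its own (nearly flat) PSTHs would inflate the band
arbitrarily; (ii) the band pools five independent random placements,
because the SD estimated from a single 10 s placement of smoothed,
correlated bins is unstable. The statistics extracted per session are the
maximal diagonal value in the 0.5 s before the onset (baseline peak) and in
the 1.5 s after it (post peak); comparisons across sessions delegate to
standard signed-rank routines.

A known limitation: when transient rates are modulated after the event, the
coincidence-count variance of post-event bins exceeds that of the
far-removed baseline bins by roughly the rate gain, so the post-event
*maximum* sits systematically high relative to a ±2 SD band even for fully
independent neurons. The band comparison is therefore reliable for
detecting strong excess coupling (which exceeds the band by an order of
magnitude in the simulations) but is not a calibrated α-level test of
independence under strong rate modulation; for that, per-session peak
differences compared across sessions are the appropriate test.

## The synthetic-data generator

The generator produces sessions with the statistical structure the
analysis assumes, with ground truth for every recovered quantity.

* **Kinematics** — BA is generated directly as a two-mode process: rest
  samples from a truncated normal around 0.018 g and movement-bout samples
  around 0.099 g (midpoint 0.0585 g, matching the regime in which manual
  thresholds average 0.0584 g); truncation at fixed margins around the
  midpoint keeps each bout one contiguous supra-threshold run, so
  ground-truth onsets are recoverable exactly. Axes are BA times a random
  3-D unit vector, so the norm identity holds by construction — only the
  norm enters any analysis.
* **Traces** — transient times are Bernoulli-per-frame trains at
  `base_rate_hz` (default 0.1 Hz, an order-of-magnitude choice for sparse
  striatal GCaMP6f activity; configurable), multiplied by `gain_pos` (> 1)
  or `gain_neg` (< 1) inside the 1 s after each event for responsive
  neurons. Negative modulation is rate suppression, not negative-going
  transients. Trains are convolved with a one-frame-rise,
  exp(−t/τ)-decay kernel (τ default 0.6 s, GCaMP6f-like), amplitudes are
  truncated-normal (mean 0.5 ΔF/F), and Gaussian noise (SD 0.05) is added.
  Recruitment draws are independent across sessions; 22% of responsive
  neurons are negatively modulated by default.
* **Conditioning sessions** — 42 trials of 10 s cues, CS+/CS− balanced and
  shuffled with at most 3 consecutive same-cue trials (a concrete reading
  of "pseudo-random"), inter-trial intervals uniform on (0.5, 1.5) times
  the 30 or 60 s mean, rewards following CS+ except in extinction mode.
* **Space** — centroids uniform on the 600 × 900 µm field with a hard
  minimum separation; the neuropil background is a low-rank Gaussian-bump
  random field (correlation length `neuropil_corr_len_um`) with slow
  temporal noise, plus a wide, low-pass-filtered (τ = 1 s) "bleed" of each
  soma's transients, which gives annular signals event-locked but slower
  kinetics than their somata. Movie patches add disc footprints and pixel
  noise. Prescribed correlation–distance profiles are injected by drawing
  multivariate-normal traces with covariance c(d); non-positive-definite
  targets are eigenvalue-clipped and the realized covariance is returned
  with the traces.
* **Coupling** — with probability `shared_coactivation_p` per (selected)
  trial, every neuron in a designated group receives one extra transient at
  a shared random latency within 0.5 s of the onset, injecting zero-lag
  trial-by-trial correlation that the shift predictor cannot explain.

What the generator does **not** emulate: biophysical spike-to-fluorescence
nonlinearity, optical point-spread functions, motion artifacts, slow
photobleaching drifts, or behavior-dependent rate dynamics beyond the 1 s
post-event window. Passing tests on these sessions demonstrate that the
pipeline recovers the structure it is designed to measure, not that real
data meet the generator's assumptions.

## Problem sizes used in the validation suite

The packaged experiments run at desk scale: 30-minute sessions at
15 frames/s, 100–200 neurons for bootstrap calibration and recruitment
recovery (2,000 circular shifts each), 1,000 registered cells for the
overlap Monte-Carlo, 200-trial sessions with 45 pairs for the JPSTH
experiments, 80 neurons over a 400 × 400 µm field for the
correlation–distance recovery, and a 128 × 128 px movie patch for the
soma/annulus kinetics contrast. These sizes keep every experiment
reproducible in minutes while leaving the statistical conclusions
comfortably powered.
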