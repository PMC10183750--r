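---
title: "Oscillatory EEG analysis: models, calibration and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Oscillatory EEG analysis: models, calibration and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(oscillatr)
```

This vignette is the package's own account of the science it implements:
the models and their assumptions, the parameters that matter, what the
synthetic-data generator does and does not emulate, and the choices made
where the design was genuinely open. It states no empirical result that
the test suite or `scripts/acceptance.R` does not itself compute.

## The analysis model

The pipeline targets a within-subject 2 x 2 design — task (picture
naming vs. size judgment) crossed with cognate status — measured with
38-channel 10–20 EEG at 500 Hz, epoched from −1 to +1 s around stimulus
onset. Three oscillatory phenomena carry the inference:

* **Beta desynchronization** (25–35 Hz): a stimulus-related decrease of
  beta power relative to the pre-stimulus baseline over centro-parietal
  electrodes, stronger for cognate than non-cognate items, in a
  task-specific window (160–260 ms for naming, 260–380 ms for size
  judgment).
* **Theta synchronization** (3–7 Hz): a broad post-stimulus power
  increase in the same windows and regions.
* **Theta–beta phase–amplitude coupling**: the concentration of beta
  power at particular phases of the theta cycle, quantified by a
  normalized Kullback–Leibler modulation index (MI).

### Time–frequency decomposition

Power is computed with complex Morlet wavelets of width 5 cycles on a
1–40 Hz, 1 Hz grid, sampled every 20 ms. Epochs are zero-padded to
±5 s before the transform so that even the 1 Hz wavelet (5 s long) sees
only literal zeros outside the signal window; with 5-cycle wavelets the
analysis windows (≤ 380 ms) are unaffected by edge effects for every
frequency of interest. The implementation convolves in the frequency
domain and aliases the product spectrum onto the decimated grid, which
is exact for the 20 ms samples; the analytic kernel has unit tone gain
(a sinusoid of amplitude *a* at the wavelet's centre frequency yields
power *a*²).

One property of this decomposition matters for interpretation: the
wavelet's spectral bandwidth grows proportionally with frequency
(SD = f/5), so the wavelet power of a 1/f^χ background falls as
f^(χ−1), not f^χ. The aperiodic subtraction below operates on the
observed wavelet spectrum and is unaffected; tests that recover the
generator's exponent therefore use a constant-bandwidth (periodogram)
spectral estimate.

### Aperiodic (1/f) correction

For every channel–time pair, a least-squares line of log power on log
frequency is fitted to the trial-averaged raw power and subtracted in
log space; the corrected power is carried back to the linear scale
(observed/fitted ratio) so that the subsequent baseline normalization
`(P(t) − P_base)/P_base` is a well-defined relative change. Fitting the
trial average rather than each trial is deliberate: the fit is indexed
by channel and time, and a shared fit makes "correct then average"
identical to "average then correct", while per-trial log-fits at the
low-frequency end are heavy-tailed (occasional extrapolation collapses
make the mean of per-trial ratios fail to converge).

The iterative refinement excludes frequencies whose residual exceeds
`k = 2` residual-SDs **above** the current line, refits, and repeats
until the excluded set stabilizes (at most 10 passes), peeling
progressively and never re-admitting a frequency. The one-sided rule
reflects that oscillations only add power; a symmetric rule cannot
isolate wavelet-broadened oscillatory bumps, which span a large part of
the 1–40 Hz grid and inflate the residual SD. Cells whose exclusion
would leave fewer than 3 frequencies stop peeling (non-iterative
fallback, with a warning).

Two residual limitations are worth knowing. First, the fitted line can
still absorb part of a large bump, which dilutes the measured relative
change; the generator's calibration (below) accounts for this. Second,
the bands interact through the fit: a change in the beta bump slightly
tilts the line under the theta band and vice versa. This cross-talk is
small but systematic, and it is why the end-to-end latency check uses
the midpoint of the dominant significant time cluster rather than its
onset.

### Baseline normalization

"Normalized power" is relative change on linear corrected power against
the −700 to −200 ms pre-stimulus baseline: a value of −0.21 is a 21%
decrease. Relative change (not dB, not z-scores) is chosen because the
condition means the analysis recovers (−0.13 … −0.22 for beta,
+0.36 … +0.55 for theta) are dimensionless fractions of that form. The
whole chain is invariant to global amplitude rescaling of the raw
signal, which the suite asserts.

### Cluster-based permutation inference

Channel-space contrasts use dependent-samples t maps thresholded at
alpha = 0.05 (two-sided, t with n−1 df). A supra-threshold channel is
retained only if at least 3 of its montage neighbours are
supra-threshold with the same sign; retained same-sign connected
components form clusters, scored by size (element count; the summed t
is recorded as well). Significance comes from 2000 within-subject
sign-flip permutations of the condition difference, recording the
maximum cluster statistic per permutation, with the add-one correction
so p ≥ 1/2001. Neighbours come from a Delaunay triangulation of the
azimuthal-equidistant projection of the idealized cap positions;
triangulation, projection and the montage itself are deterministic
functions of the channel list.

The minimum-neighbour rule is strictly conservative: on null data at
n = 18 essentially no cluster ever survives it, so the familywise error
sits near zero. The calibration test therefore verifies the core
machinery (no pruning) within [0.02, 0.08] and separately that the
pruned variant never exceeds the nominal rate.

### Searchlight mini-cluster test

To ask whether an ROI's cognate effect is specific to that scalp
region, every electrode outside the ROI becomes the centre of a
mini-cluster of the ROI's size (11 electrodes for naming, 8 for size
judgment), built from its nearest non-ROI channels in the planar
projection (ties broken by channel name; the construction depends only
on montage, ROI and size). ROI electrodes are excluded from membership
as well as centres — neighbourhoods that overlap the ROI would inherit
its effect and mask the comparison. The paired t of the cognate
contrast is computed per mini-cluster and for the ROI.

The permutation null retains the observed scalp effect distribution:
each subject's condition-difference vector is decomposed into the
channel-wise group mean plus a subject residual, residuals are
sign-flipped within subject, and the scalp-maximum |t| across
mini-clusters is recorded; p is the add-one-corrected fraction of
permutations reaching the observed ROI |t|. This construction is small
only when the ROI stands out from the scalp distribution: a spatially
uniform effect leaves the null centred on the observed mini-cluster
statistics and p large, while plain sign-flips (which test "no effect
anywhere") would reject. The descriptive percentile of the ROI t in the
observed mini-cluster distribution is reported alongside.

### Theta–beta coupling

Per subject and task, theta (3–7 Hz) and beta (13–30 Hz) spectral peaks
are found by prominence on the fractal-corrected ROI spectrum. Trials
are balanced across the four conditions by drawing, in each of 100
seeded iterations, `floor(0.8 × smallest correct-trial count)` trials
per condition without replacement. Each trial and ROI electrode is
filtered with zero-phase frequency-domain Gaussian kernels (SD 0.5 Hz
at the theta peak, 5 Hz at the beta peak); the analytic signal gives
theta phase and beta amplitude; beta **power** (squared envelope) is
binned into twelve 30° phase bins, and
`MI = (log 12 − H(p)) / log 12` with the `0·log 0 = 0` convention.
Binning power rather than amplitude follows the method's description
and matters quantitatively: group-level MI values near 0.03 are
unreachable for envelope binning under realistic background levels.

The analysis windows (100–120 ms) are shorter than a theta cycle, so
the extraction segment is extended symmetrically to at least two cycles
of the subject's theta peak (≈ 400 ms at 5 Hz) around the window
midpoint; filtering always runs over the full unpadded epoch for
stability. MI is computed per trial and electrode, averaged over
electrodes, then over the balanced draws.

### Behavioral statistics

Accuracy is the correct-trial proportion per subject and cell; mean RT
is taken over correct trials within ±2 SD of the cell's correct-trial
mean (single pass). Inference uses the 2 x 2 repeated-measures ANOVA
with subject-by-effect error strata (partial eta squared reported),
planned paired t tests with Cohen's d = t/√n and JZS Bayes factors
(Cauchy prior scale 0.707, computed by numerical integration over the
g-mixture), one-sample tests under Bonferroni control at
alpha = 0.05/4 = 0.0125, and Pearson correlations.

## The synthetic generator

`synthetic_config()` defines the emulated study: 18 subjects, 32 trials
per task × cognate cell (64 pictures per task, half cognates), 500 Hz,
−1..+1 s epochs, the 38-channel idealized cap. Signals sum:

* a 1/f background (exponent 1, SD 10 µV, spectrum flattened below
  1 Hz) plus white sensor noise (SD 2 µV);
* a theta oscillation (5 Hz, 7 µV) and a beta oscillation (29 Hz, 3 µV)
  with random phase per trial and channel and log-normal trial
  amplitude jitter (so single-trial band-power SNR stays below 1 and
  averaging matters);
* a beta carrier (29 Hz, 12 µV) whose envelope follows
  `(1 + m·cos φ_theta)/(1 + m)` with φ_theta the phase of that trial's
  theta component — the coupled portion of beta activity. The split
  between coupled carrier and uncoupled beta is heavily weighted toward
  the carrier because the printed MI targets require the coupled
  component to dominate the beta filter band, while the total beta-band
  power is kept small enough for a stable aperiodic fit;
* condition effects: amplitude envelopes `sqrt(1 + r·B(t))` applied on
  the task's ROI (full weight) and its immediate montage neighbours
  (half weight), where `B(t)` is a raised-cosine-edged plateau over the
  task window extended slightly beyond it so that, after wavelet
  smoothing, the band-power estimate inside the nominal window sits at
  the plateau.

Behavior draws, per subject, a shared baseline (overall speed /
ability, carrying most of the across-subject SD after subtracting the
binomial / trial-sampling component) plus small condition-specific
deviations (15 ms for RT, 0.04 for accuracy), then per-trial Bernoulli
correctness and normal RTs (trial SD 150 ms, floored at 150 ms). The
shared baseline is what gives the within-subject condition contrasts
paired t statistics of a realistic order; fully independent
per-condition draws would leave the marginal SDs intact but destroy the
within-subject correlation.

### Making the configured values the pipeline's estimand

The map from an injected relative power change to what the chain
measures is diluted by wavelet smoothing of the effect window, by
background power inside the band, and by whatever the iterative fit
absorbs of the oscillatory bump — and the two bands interact through
the fit. Rather than modelling this jointly, the generator measures the
map: for each task it pushes Monte-Carlo single-channel condition
trials (grouped at the subject's expected correct-trial count, so the
fit operates at the same noise level as a real subject's average)
through the actual chain on a 5 × 6 grid of injected (theta, beta)
changes, and inverts the resulting two surfaces per subject by fixed
point. Coupling depths are calibrated the same way: bisection on `m`
against the package's own MI estimator under the condition's signal
model until the mean MI is within 5% of the target. Surfaces and
coupling depths use fixed internal seeds — they are calibration
constants of the configuration, memoized across cohorts — while all
cohort-level randomness derives from `rng_seed` (identical seeds give
bit-identical cohorts).

### Between-subject variability

The share of the study-scale across-subject SDs treated as true
between-subject variance is `between_sd_scale = 0.25`; the rest is
trial-level and measurement noise. The scale was fixed by a
design-stage power computation: the validation suite requires the theta
task-by-cognate interaction (a 0.18 contrast against a ≈ 0.54 raw
contrast SD) to be detectable in ≥ 80% of 20 replicate cohorts at
n = 18, which needs well above 95% per-cohort power and hence a between-subject
interaction SD well below the raw value. The cost is that simulated
one-sample t statistics run about twice the study-scale ones; the
condition means, their orderings, and the ANOVA effect pattern are
unaffected.

### What the generator does not emulate

No ocular or muscle artifacts (trial rejection exists but rarely
fires on clean synthetic data), no volume conduction or forward
modelling (channels are independent up to the shared average
reference), no phase-locked (ERP) components, no drifts or line noise
(the filters are exercised on constructed signals instead). Passing
tests on this generator demonstrate that the pipeline recovers known
oscillatory structure under realistic power spectra and trial-count
noise — not that it is robust to every artifact class of real
recordings.

## Numerical choices and degenerate inputs

* Delaunay neighbours come from circumcircle-emptiness triple
  enumeration with boundary contacts allowed, so the exactly co-circular
  quadruples of the idealized cap yield a well-defined (slightly
  conservative) neighbour graph; collinear layouts are an explicit
  error.
* Channel interpolation is an inverse-planar-distance mean of good
  Delaunay neighbours; isolated bad channels error.
* Butterworth filtering is order 4 per pass, forward–backward;
  unstable designs are rejected with advice rather than applied.
* The permutation p-values carry the add-one correction and can never
  be exactly zero; positive and negative clusters are formed
  separately.
* MI with an all-zero amplitude series is an error; empty phase bins
  enter the entropy via `0·log 0 = 0`.
* Zero-variance contrasts error in the t routines; elements with zero
  difference variance in a t map become ±Inf and count as
  supra-threshold.
* The degenerate ANOVA stratum (an effect constant within subject)
  reports F = 0, p = 1 rather than a 0/0 ratio.

## Problem sizes used in validation

The recovery checks run the full chain at the study scale (18 subjects,
32 trials per cell, all 38 channels for generation, ROI channels for
decomposition, the 1–40 Hz grid on ±5 s padded epochs). The 20-cohort
detection study uses a reduced spectral grid (16 frequencies spanning
2–38 Hz, ±2 s padding, the ROI-union channels, no coupling carrier
calibration) — the detection questions it answers do not depend on the
absolute calibration precision the full grid buys. Permutation counts
follow the analysis defaults (2000) except where a property is averaged
over many replicates, which use 250–500 permutations each. All of this
is stated here as the package's validation design.
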