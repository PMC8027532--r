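---
title: "Methods: multiscale entropy and spectral scaling of resting EEG"
author: "eegcomplexity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multiscale entropy and spectral scaling of resting EEG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(eegcomplexity)
```

# Overview

`eegcomplexity` implements a resting-state EEG complexity pipeline:
multiscale sample entropy (MSE) over coarse-grained time scales, Welch
power spectral density (PSD) with a robust 1/f power-law slope,
IAAFT phase-shuffled surrogate controls, mass-univariate group
contrasts with threshold-free cluster enhancement (TFCE) and
max-statistic permutation testing, and robust trimmed-mean bootstrap
topography contrasts. Because large developmental EEG cohorts are
rarely shareable, the package ships a synthetic cohort generator with
known ground truth; every statistical component is validated against
that ground truth (parameter recovery, error control, coverage) rather
than against any particular empirical dataset.

This vignette explains the models, defaults, and design choices; it
states no empirical result that the test suite and
`scripts/acceptance.R` do not themselves compute.

# Preprocessing

Recordings are zero-phase low-pass filtered at 30 Hz (4th-order
Butterworth, forward-backward, so the effective order is 8 and the
attenuation at 1.5 x cutoff is well beyond 20 dB). Zero-phase filtering
matters here: phase distortion would alter temporal patterns and bias
entropy. Filtering runs on mean-removed signals with the mean restored,
which keeps DC exact and avoids start-up transients on offset data.

Filtered recordings are cut into contiguous, non-overlapping 20-s
epochs (trailing remainder discarded); a recording shorter than one
epoch is an error, mirroring the usual minimum-continuous-data rule for
resting EEG. Two rejection rules follow:

* **Extreme voltage**: an epoch is rejected iff any channel sample
  strictly exceeds ±150 µV. The boundary is strict (a sample exactly at
  150 is retained) and the threshold configurable. Amplitude criteria in
  this range are standard for dense-array scalp EEG; anything in the
  hundreds of millivolts would not be physiological scalp signal.
* **Joint probability**: per channel, an empirical amplitude density is
  built from a 100-bin histogram with add-one (Laplace) smoothing over
  values pooled across retained epochs; each epoch's per-channel sum of
  sample log-probabilities is z-scored across epochs, and an epoch is
  rejected iff any channel's |z| exceeds 5. The histogram/smoothing
  re-specification keeps the rule deterministic, dependency-free, and
  directly testable; with n retained epochs the attainable |z| is
  bounded by (n-1)/sqrt(n), so the 5-SD default only bites once a few
  dozen epochs are available — with fewer epochs the rule is
  (correctly) conservative.

Both rules are order-independent and `reject_extreme` is idempotent;
these are tested properties.

# Multiscale sample entropy

Scale-τ coarse-graining replaces non-overlapping windows of length τ by
their means. Sample entropy with template length m and tolerance r is
`-ln(B/A)`, where A counts pairs of distinct m-length templates whose
Chebyshev distance is strictly below r and B the corresponding
(m+1)-length counts; both template sets start at the same N − m
positions so the ratio is a conditional match probability. Zero counts
yield an undefined (NA) value — never silently 0, which would bias group
means downward.

Defaults are m = 2, r = 0.5 x SD, scales 1–20. Design choices:

* **r as a fraction of SD**, anchored to the scale-1 SD and held fixed
  across scales (the original multiscale-entropy convention). A
  per-scale-SD mode and an absolute mode are available
  (`mse_params(r_mode = ...)`). With the fixed anchor, white noise shows
  the canonical strictly-decreasing profile (coarse-graining shrinks the
  SD relative to the fixed tolerance), while 1/f noise stays nearly
  flat — both verified by seed-averaged simulation in the tests.
* **Chebyshev distance** and **strict inequality** in match counting,
  the standard choices for sample entropy.
* The C++ kernel is cross-checked to 1e-10 against a brute-force
  template enumeration oracle on random series.

A useful analytic anchor, used as an acceptance check: for iid data the
conditional (m+1 | m) match probability equals the single-point match
probability, so standard-Gaussian white noise has sample entropy
`-ln(erf(r/2))` at tolerance r in SD units — about 1.286 at r = 0.5.

Per-subject maps average the per-epoch channel x scale matrices over
retained epochs, ignoring undefined cells (counts reported).

# Spectral scaling

PSD uses Welch's method: Hanning-tapered 1024-sample windows with 50 %
overlap (2-s windows at 512 Hz), mean-removed per window, one-sided
density normalized by window power, averaged within each retained epoch
and then across epochs so no window straddles an epoch boundary. Power
is reported in dB with a machine-epsilon floor before `log10`.

The 1–30 Hz power-law exponent is the slope of an iteratively
reweighted least-squares fit (Tukey bisquare, conventional tuning
constant, 50-iteration cap, ordinary-least-squares fallback with a
warning on non-convergence) of log10 power on log10 frequency, so an
exact `f^-2` spectrum yields slope −2.000 and the estimate is invariant
to rescaling the power. Robustness matters because a single
oscillatory peak (e.g. alpha) acts as an outlier bin for the aperiodic
fit. Parameter recovery — mean fitted slope within ±0.15 of −β for
β in {0.5, 1, 2} on 2^16-sample spectral-synthesis noise — is part of
the acceptance suite.

Region-level slopes default to fitting the region-averaged spectrum;
averaging per-channel slopes is available
(`region_mode = "mean_of_slopes"`), since either convention is
defensible and they differ only through fit nonlinearity.

# IAAFT surrogates

The iterated amplitude-adjusted Fourier transform alternates between
imposing the original Fourier amplitudes and rank-remapping onto the
sorted original values, from a random permutation start, for at most
100 iterations or until the rank ordering reaches an exact fixed
point. The returned surrogate ends on the rank-remap step, so its
sorted values equal the original's exactly (hence exact mean and
variance) while the amplitude spectrum is matched to well under 1 %
relative error on linear colored noise; a spectrum-exact variant is a
flag away. Surrogates destroy phase (nonlinear temporal) structure, so
entropy on surrogates of a deterministic nonlinear series (the
logistic map in the tests) exceeds the original's in ≥95 % of an
ensemble, while iid input shows no systematic difference. Surrogates
are generated independently per channel and epoch; multivariate
phase-consistent surrogates are out of scope.

# TFCE permutation contrasts

Group contrasts over channel x bin grids (bin = entropy scale or
frequency) use per-cell pooled-variance two-sample t statistics
(Welch available by flag), with per-cell complete cases when entropy is
undefined for some subject. The enhancement is

TFCE(cell) = Σ_h e(h)^E · h^H · dh

summed over thresholds h = dh, 2dh, … up to the map maximum, where
e(h) is the size of the supra-threshold connected component containing
the cell; E = 0.66 and H = 2 by default. Positive and negative parts
are enhanced separately and recombined with sign. Design choices:

* **Connectivity**: channel adjacency at the same bin plus ±1 bin at
  the same channel, exploiting the spatial and scale/frequency
  smoothness of EEG effects. Channel adjacency comes from the montage
  (distance threshold; the automatic default gives the median channel
  4–8 neighbours, sparse but connected).
* **dh**: adaptive, max/100 per sign and map. The closed form for an
  isolated cell, t0^(H+1)/(H+1), is reproduced within 2 % at this step
  (right-endpoint Riemann sum), and halving dh moves scores by well
  under 1 % of the map scale.
* **Inference**: max-statistic permutation. Each of n_perm (default
  2000) random label reassignments recomputes the t map and
  enhancement; the per-cell familywise-corrected p is
  `(1 + #{null_max ≥ |enhanced|}) / (1 + n_perm)`, two-tailed via the
  absolute maximum, with the +1 guaranteeing validity. Missing cells
  are excluded symmetrically from observed and permuted maxima.

The acceptance suite verifies the enhancement against an igraph
connected-component oracle, familywise error on 200 null cohorts
(empirical rate within 0.05 ± 0.04 at n_perm = 500), and recovery of
effects injected on 5 of 16 channels (sensitivity ≥ 80 %, no off-effect
cells in ≥ 95 % of replicates).

# Robust topography and linkage

Topography uses the six Region x Hemisphere cell means per subject
(frontal / central / parieto-occipital x left / right; midline channels
excluded from lateralized cells). Contrasts are linear per-subject
scores — pairwise region differences averaged over hemisphere, the
hemisphere difference averaged over region, and pairwise
difference-of-differences interactions — summarized by 20 % trimmed
means with a 2000-resample percentile bootstrap over subjects
(resampling subjects, not cells, preserves within-subject dependence).
The two-sided bootstrap p uses the half-count tie adjustment. Null
coverage of the 95 % CIs is verified by simulation. Pairwise
interaction contrasts were chosen over an omnibus statistic because the
scientific questions here are directional region-pair asymmetries.

The slope-entropy linkage robustly regresses each subject's mean
entropy over short (default 1–5) and long (default 16–20) scale bands
on the subject's mean-over-channels PSD slope, per group, reporting
variance explained (squared correlation of fitted and observed).

# The synthetic cohort

Each channel is a standardized mixture
`(1 − mix) · colored_noise(β) + mix · white noise` plus an alpha-band
sinusoid with random phase, scaled to ~10 µV RMS. Colored noise is
generated by spectral synthesis — white Fourier amplitudes scaled by
`f^(−β/2)` with uniform random phases — giving exact control of the
expected exponent (an autoregressive generator would control it only
asymptotically). β is drawn per subject from a truncated normal, so
cohorts have realistic between-subject spectral variability.

Group effects are encoded independently: a larger `irregularity_mix`
raises fine-scale entropy (the "older group is more complex" effect),
and a smaller β flattens the PSD ("older group has less negative
slope"). The two dials are separate so entropy effects can be studied
with the spectrum held fixed and vice versa. One caveat discovered in
validation and worth stating: the white-noise admixture itself lifts
the high-frequency tail of the spectrum, so varying `mix` also flattens
the band-limited 1/f slope. A cohort whose entropy differences are
"mix-driven" therefore still shows a real slope-entropy association;
the package's null-linkage demonstration instead holds all generator
parameters fixed, so both quantities vary only by estimation noise.
`effect_channels` restricts the group-specific parameters to a channel
subset (other channels follow the reference group), which is how the
TFCE localization tests plant spatially confined effects.

Default conditions are a dense 96-channel layout at 512 Hz with 60 s
per subject — one resting block. What the generator does *not* emulate:
volume-conduction correlations between channels (channels are
independent), eye/muscle artifacts beyond optional amplitude spikes,
non-stationarity within a recording, and oscillatory peaks other than a
single alpha component. Passing tests therefore demonstrate that the
*estimators and error control* behave correctly on signals with known
spectral and entropy structure — not that any particular developmental
claim holds in real EEG.

# Simulation sizes

The validation studies run at desk scale, chosen once: null
familywise-error cohorts use 8 channels at 32 Hz, 20 s per subject,
12 subjects per group, 500 permutations, 200 replicate cohorts; effect
recovery uses 16 channels (effect on 5), scales 1–5, 20 subjects per
group, 50 replicates; bootstrap coverage uses 30 subjects, 500
resamples, 200 replicates; exponent recovery uses 2^16-sample signals
and 20 seeds. A 32 Hz rate keeps the alpha component below Nyquist
while making the O(N²) entropy kernel cheap; none of the verified
properties (error control, coverage, recovery, ordering) depends on the
sampling rate. The analysis scripts under `analysis/` use an
intermediate scale (16 channels, 128 Hz, 40 s, 12 per group).

# Numerical notes and limitations

* Sample entropy is O(N²m); at 512 Hz a 20-s epoch (10,240 samples)
  takes on the order of a second per channel across scales 1–20.
* Undefined entropy (no template matches) propagates as NA through
  subject averaging, t maps (per-cell complete cases), and enhancement
  (cells excluded from components).
* IAAFT may stop at the iteration cap rather than an exact rank fixed
  point; the spectrum mismatch it reports is the honest convergence
  measure, and its per-iteration trace is non-increasing.
* Permutations are sampled with replacement from the label-assignment
  space; a warning notes when n_perm exceeds the number of distinct
  assignments.
* The region/hemisphere partition of the default montage is a
  convention (anterior-posterior thirds, |x| < 0.08 midline), editable
  via the montage file; it is not a reconstruction of any particular
  cap's cluster memberships.
* Supported on-disk formats are the delimited rows-as-channels dialect
  (with JSON sidecar) for signals plus delimited montage/result tables;
  binary acquisition formats are out of scope.
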