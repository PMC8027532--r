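# eegcomplexity

Resting-state EEG complexity analysis in R: multiscale sample entropy,
1/f spectral scaling, surrogate controls, and familywise-corrected
mass-univariate group statistics — with a ground-truth synthetic cohort
generator so every statistical claim the pipeline makes can be verified
by simulation.

It is written for researchers comparing groups (e.g. age bands in
developmental cohorts) on multichannel resting EEG, and for
methodologists who want a tested, scriptable reference implementation
of this analysis stack.

## What it computes

**Multiscale entropy (MSE).** The scale-τ series replaces
non-overlapping windows of length τ by their means; sample entropy at
each scale is

&nbsp;&nbsp;SampEn(m, r, N) = −ln( B / A ),

where A counts pairs of distinct m-length templates within Chebyshev
distance < r and B the corresponding (m+1)-length counts. Defaults
m = 2, r = 0.5 × SD (anchored at scale 1), scales 1–20. Low values mean
regular/predictable signal; undefined values (no matches) propagate as
`NA`, never as 0.

**Spectral scaling.** Welch PSD (Hanning, 1024-sample windows, 50 %
overlap) over 1–30 Hz, and the power-law exponent β from a robust
(Tukey bisquare IRLS) fit of log10 power on log10 frequency, so
`power = f^-2` gives slope −2.

**IAAFT surrogates.** Phase-shuffled surrogates preserving the
amplitude distribution exactly and the spectrum approximately (≤100
iterations), to test whether entropy effects reflect nonlinear
temporal structure rather than the spectrum alone.

**TFCE permutation contrasts.** Per-cell two-sample t maps over
channel × scale (or × frequency) grids, enhanced by
TFCE(cell) = Σ_h e(h)^E · h^H · dh with E = 0.66, H = 2, and tested
against the permutation distribution of the map-wide maximum
(2000 between-subject permutations by default), giving
familywise-corrected per-cell p-values; plus per-region
proportion-significant summaries.

**Robust topography.** Region × Hemisphere cell means per subject,
contrasted with 20 % trimmed means and a 2000-resample percentile
bootstrap; robust regression linking each subject's PSD slope to
short- and long-scale entropy.

**Synthetic cohorts.** Per channel,
`(1−mix)·colored_noise(β) + mix·white + alpha sinusoid`, with β drawn
per subject; `mix` raises fine-scale entropy, smaller β flattens the
spectrum, and effects can be confined to chosen channels. This is the
ground truth the validation studies recover.

## Worked example

The `analysis/` directory is a numbered workflow over a simulated
two-group cohort (12 "age9" + 12 "age15" subjects, 16 channels,
128 Hz, 40 s; the older group has higher irregularity and a flatter
spectral exponent). Run the stages from the repository root:

```sh
Rscript analysis/01_simulate_cohort.R
Rscript analysis/02_preprocess_qc.R
Rscript analysis/03_complexity_spectra.R   # MSE + PSD/slope maps
Rscript analysis/04_surrogate_check.R      # IAAFT surrogate control
Rscript analysis/05_group_contrasts.R      # TFCE permutation contrasts
Rscript analysis/06_topography_linkage.R   # robust topography + linkage
```

Stage 3 prints the group-level ground-truth recovery:

```
Group mean scale-1 entropy:
age15  age9
0.555 0.317
Group mean PSD slope (1-30 Hz):
 age15   age9
-0.547 -1.373
```

— higher entropy and a flatter (less negative) slope for the older
group, as constructed. Stage 5 then shows the TFCE contrast flagging
widespread entropy increases (320 of 320 channel × scale cells
significant at familywise α = .05 for this strong simulated effect),
and stage 6 prints bootstrap CIs for the six Region × Hemisphere
contrasts and the per-group slope–entropy fits, e.g.

```
 group  band  n  slope intercept variance_explained
  age9 short 12 -0.090     0.438              0.814
  age15 short 12 -0.144    0.772              0.634
```

where the high variance explained reflects that in this cohort
between-subject entropy differences are partly β-driven. All tables
land under `results/`.

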