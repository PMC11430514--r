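---
title: "QEEG/ERP group comparison with Wilcoxon z-sum cluster permutation tests"
author: "qeegperm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{QEEG/ERP group comparison with Wilcoxon z-sum cluster permutation tests}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(qeegperm)
```

## The problem

Small familial cohorts with rare neurological disease cannot be compared to
controls with mass-univariate parametric statistics: a 19-channel EEG
spectrum or ERP comparison involves thousands of (channel, bin) points,
group sizes are tiny and skewed (here 9 affected family members against 50
age-matched normative controls), and the data are far from Gaussian.
`qeegperm` implements the analysis chain used in clinical QEEG/ERP practice
for exactly this setting, together with a seeded simulator of the whole
study, so that every stage can be validated end to end without access to
confidential patient recordings.

The package covers:

1. **Simulation** of multichannel EEG for a cued GO/NOGO paradigm with
   known injected group effects (`simulateCohort()`,
   `synthesizeSession()`).
2. **Preprocessing**: zero-phase Butterworth filtering, 45–55 Hz notch,
   weighted-average re-referencing, FastICA ocular correction, and
   three-rule amplitude artifact rejection with an eight-clean-epoch
   quality gate.
3. **Welch spectra** on clean 5 s epochs, relative amplitudes, group
   grand averages and difference spectra.
4. **ERP averaging** per trial type with component quantification.
5. **The statistical core**: a cluster-based permutation test whose
   pointwise statistic is the normal-approximation Wilcoxon z (rank-sum or
   signed-rank) and whose cluster score is the summed z within a cluster,
   calibrated against the permutation null of the maximum absolute cluster
   mass.
6. **Correlation** of the late NOGO component amplitude with a behavioral
   memory score, and a reproducible report.

## The task model

A cued GO/NOGO trial presents two stimuli 1000 ms apart (animal `a`,
plant `p`, human `h`), in the pairs `aa`, `ap`, `pp`, `ph` with equal
probability; pairs are 3000 ms apart and each stimulus lasts 100 ms. `aa`
demands a button press (GO), `ap` demands withholding (NOGO), `pp`/`ph`
carry no demand (Ignore). The canonical session has 400 trials.
`generateTaskEvents()` reproduces this timing exactly and carries simulated
reaction times on GO trials.

## The forward model and what it does (not) emulate

`synthesizeSession()` builds each recording as a sum of sources mixed
through fixed per-channel gain maps:

- **Background**: independent per-channel 1/f noise (SD 8 µV) plus white
  noise (SD 2 µV). Amplitudes are chosen so the unfiltered signal stays
  below the 100 µV rejection threshold except in deliberately inserted
  artifact segments, keeping rejection-rule behavior controllable.
- **Posterior alpha** for every subject: an amplitude-modulated sinusoid at
  the normative peak (9.0 Hz) with a right occipito-temporal maximum
  (largest gains at O2/T6), 8 µV with eyes open, ×2.5 with eyes closed,
  ×0.8 during the task. Sinusoidal sources (rather than filtered noise)
  make the peak frequency exactly controllable on the 0.2 Hz Welch grid.
- **Patient low alpha**: an additional 7.6 Hz source with a left
  temporofrontal topography (maximal at F7/T3/T5, 12 µV) present only in
  patients, in all conditions. This is the simulated disease signature: an
  excess in the 6.5–9.5 Hz band over left temporofrontal channels.
- **ERP components** in the task condition: an early occipital response
  (140 ms, 6 µV) to every stimulus, a GO P3 at Pz (330 ms, 8 µV, identical
  between groups), and a late central positivity at Cz on NOGO trials
  (400 ms) scaled by each subject's latent amplitude — mean 5 µV in
  controls and 2 µV (40%) in patients, the simulated inhibition deficit.
- **Blinks**: a stereotyped biphasic ~400 ms waveform (70 µV) through a
  frontal gain map maximal at Fp1/Fp2 and zero posteriorly
  (`ocularTemplate()`), at 8/min, giving ICA a recoverable component.
- **Behavioral scores**: patient delayed-recall T-scores are generated by
  the bivariate-normal construction `z_score = r·z_amp + sqrt(1-r²)·e`
  around mean 29.6 (SD 11.5), so the population correlation with the
  latent NOGO amplitude is exactly `r` (default 0.78). Controls have no
  behavioral scores; correlation analyses are patient-only, mirroring the
  normative-database design where behavioral testing of controls is not
  available.

The model deliberately omits volume conduction (topographies are direct
gain maps, not dipole projections), spatially correlated background noise,
non-stationary artifacts other than blinks and inserted gross segments, and
latency jitter of ERP components. Passing recovery tests on this generator
therefore demonstrates that the analysis chain is correct and well
calibrated — not that it would have the same sensitivity on real data,
where between-subject topography variability and correlated noise reduce
effective effect sizes.

## Preprocessing decisions

- **Filters** are order-4 Butterworth applied forward–backward
  (`signal::filtfilt`), i.e. zero-phase, so ERP latencies are unaffected.
  The digital band is 0.53–30 Hz with a 45–55 Hz band-stop notch. The slow
  artifact band is a 0–1 Hz low-pass (order 2 for numerical robustness at
  a cutoff of 0.008 of Nyquist) and the fast band 20–35 Hz.
- **Weighted average reference**: published weighted-average schemes
  differ and the exact weighting used by clinical systems is not public,
  so the default weights are uniform (plain average reference, channel sum
  exactly zero per sample) with a weight-vector hook.
- **ICA**: FastICA (logcosh contrast, symmetric decorrelation) fitted on a
  2–30 Hz band-passed copy — the classical remedy for ICA overlearning on
  short recordings — keeping the 15 largest principal components. The
  implementation is authored in-package and is deterministic for a fixed
  seed and iteration cap (100 iterations, tolerance 1e-5). Components are
  removed when the absolute Pearson correlation of their scalp map with the
  frontal ocular template reaches 0.8; this replaces the manual component
  inspection of interactive packages with a reproducible rule, and the
  removal report preserves an audit trail.
- **Artifact rules**: strict `>` comparisons at 100 µV (raw), 50 µV
  (0–1 Hz) and 35 µV (20–35 Hz) on consecutive 5 s epochs, any channel
  triggering the epoch flag; at least 8 clean epochs (≈40 s) are required
  per subject and condition, otherwise a `qualityGateError` names the
  failing subject.

## Spectral decisions

Welch spectra use demeaned, Hann-tapered 5 s epochs (0.2 Hz resolution,
which resolves 7.6 vs 9.0 Hz peaks), averaged over clean epochs; power is
normalized so that its sum over bins equals the signal variance. The
analysis band is 0–30 Hz. The statistic compared between groups is the
**relative amplitude** — per-channel amplitude in percent of that channel's
summed amplitude over the band — which removes inter-subject scale
differences; absolute power and amplitude are also exposed. Task-condition
spectra are computed on clean 5 s segments of the continuous task
recording, ignoring trial structure, as condition spectrograms are in
clinical QEEG.

## ERP decisions

Epochs span −200…+800 ms around the second stimulus (Ignore trials: around
the first stimulus of the non-cue pairs), with a −200…0 ms baseline. The
late NOGO component is the 300–500 ms window mean at Cz (the group map
latency of ~340 ms sits inside); GO P3 is 250–450 ms at Pz; the early
sensory response is 80–180 ms at O1. A window mean (not a peak) is the
default quantification because it is less noise-sensitive at single-digit
trial counts; peak extraction is available via `type = "peak"`.

Before the between-group ERP cluster test, the per-subject waveforms are
smoothed with a zero-phase 6 Hz low-pass (`erpTestLowpassHz`, NULL
disables). Late positivities live well below 5 Hz, so the component of
interest passes essentially unchanged, while residual alpha leaks out of
the ERP average — in this simulation design the 9.0 Hz source is exactly
phase-locked to the 4.000 s trial grid (36 cycles per trial), so without
smoothing it contributes per-subject pointwise variance that no amount of
trial averaging removes. Low-pass filtering before late-component group
statistics is standard ERP practice; component amplitudes and exported
waveforms remain unfiltered.

## The cluster permutation test

For each (channel, bin) point the two groups are compared with the
Wilcoxon test in its normal approximation: rank-sum for independent
groups, signed-rank (zeros dropped, ties mid-ranked) for paired designs;
both use tie-corrected variances. The z-score `(W − μ_W)/σ_W` keeps the
direction sign (first group larger ⇒ positive). Two-sided p-values apply
the standard continuity correction `(|W − μ_W| − ½)/σ_W`, which keeps the
normal approximation within 0.05 of the exact enumeration p down to n = 4;
the uncorrected z remains the cluster-mass ingredient. A consequence worth
knowing: in a paired design with n = 5 subjects no point can pass the 0.05
forming threshold, so paired cluster tests need n ≥ 6.

Points with p below the cluster-forming threshold (default 0.05,
config-exposed since no canonical value exists) are clustered by
spatio-temporal adjacency — same-channel neighboring bins, same-bin
neighboring channels per the montage graph — and split by sign. The
montage graph connects electrodes within 0.35 unit-diameter head units in
the 2-D 10–20 projection, which yields the natural nearest-neighbor ring
of each site; both positions and threshold are overridable.

Each cluster is scored by its **summed z** (not a summed t). Significance
comes from the permutation null of the **maximum absolute cluster mass**
under relabeling — group labels for the independent design, per-subject
sign flips for the paired design — the standard max-statistic correction
for multiple comparisons. Monte-Carlo p-values use the +1 correction so
they are never exactly zero; exhaustive enumeration (all label assignments
or all 2^n sign patterns) replaces Monte Carlo when requested and is the
oracle against which the Monte-Carlo path is tested. Patients vs controls
is an independent-groups design here, so the rank-sum variant is the
default; the signed-rank variant serves paired condition contrasts.

## Correlation stage

Pearson r between the per-patient late NOGO amplitude at Cz and the
delayed-recall T-score, with the two-sided p from
`t = r·sqrt((n−2)/(1−r²))`. Because n = 9 strains the t approximation, a
seeded permutation p (shuffling scores) is computed alongside. Fisher-z
confidence intervals (`fisherCI()`) quantify the uncertainty honestly at
this sample size.

A distinction worth keeping in mind: the generator controls the
*population* correlation between the latent NOGO amplitude and the score
(recoverable to ±0.03 at n = 2000 by construction). The correlation of
the *measured* window-mean amplitude is attenuated by measurement noise —
by the classical factor `sqrt(reliability)` — and at sharply reduced trial
counts (tens of NOGO trials per subject instead of the ~100 of a full
400-trial session) the per-subject noise exceeds the between-subject
amplitude spread, so observed correlations in fast validation runs sit far
below the population value. This is expected attenuation, not a defect of
the correlation stage, and it disappears as the trial count approaches the
real design.

## Problem sizes used by the test-suite and acceptance script

Simulated sessions are expensive, so the validation suite runs the full
pipeline at reduced—but still statistically adequate—sizes, chosen once:
60 s resting sessions (12 clean 5 s epochs, comfortably above the 8-epoch
gate) and 25–48-trial task sessions (≈100–200 s, ≥20 clean epochs; 400
trials remain the default for real use). Null calibration uses 200
simulated experiments on reduced maps (4 channels × 12 bins, 8 vs 8
subjects, 200 permutations). Correlation recovery uses n = 2000 synthetic
patients for the point estimate and 500 replicates of n = 9 for CI
coverage. All of these sizes are stated here as the package's own
validation design.

## Known limitations

- Gain-map topographies cannot probe volume-conduction effects such as
  reference-dependent map distortions.
- The ICA template rule is tuned to stereotyped blinks; slow lateral eye
  movements with atypical topographies may evade the 0.8 correlation
  threshold.
- Independent per-channel background noise makes the cluster test's null
  calibration on simulated data slightly conservative relative to real
  EEG, where spatial correlation inflates cluster sizes under the null —
  the permutation calibration absorbs this on real data, but simulated
  power estimates do not transfer directly.
- The EDF writer targets continuous 16-bit export of one recording per
  file; it does not implement EDF+ annotations (events travel in the
  companion TSV file).
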