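---
title: "Two-dimensional LF-HF analysis of heart rate variability"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-dimensional LF-HF analysis of heart rate variability}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hrv2d)
```

## The problem

Heart rate variability (HRV) is the beat-to-beat fluctuation of the
normal-to-normal interval (NNI) series derived from the ECG.  Its
frequency content is conventionally split into a low-frequency band
(LF, 0.04–0.15 Hz), associated predominantly with sympathetic activity,
and a high-frequency band (HF, 0.15–0.4 Hz), dominated by
parasympathetic (respiratory) modulation.  The classical one-number
summary of "sympathovagal balance" is the ratio of the band powers,
LFp/HFp.

The ratio is a projection: it collapses a genuinely two-dimensional
quantity — the pair (LFp, HFp) — onto one axis, so very different
autonomic states can share a ratio value.  `hrv2d` implements an
analysis chain built around keeping both degrees of freedom:

1.  a family of univariate metrics (`metric_family()`, P1–P5) that all
    satisfy the usual monotonicity requirements of a stress index
    (increase with LFp, decrease with HFp) yet order states differently
    — evaluated along any constant-ratio locus `HFp = c * LFp`, P1 is
    flat while P2–P4 increase and P5 decreases, which is the ambiguity
    in closed form;
2.  the normalization identities: with total power taken as
    `LFp + HFp`, the normalized powers obey `HFn = 1 − LFn` exactly, so
    normalization also removes one degree of freedom
    (`normalize_powers()`);
3.  a robust two-dimensional feature pair: the *instantaneous
    amplitudes* `LFiA`/`HFiA`, per-window trimmed means of the Hilbert
    envelopes of the band-limited tachogram;
4.  categorization of stress states by a polynomial-kernel SVM on the
    2D feature plane, scored by categorization accuracy (CA), with
    per-subject baseline standardization and exact rank-sum scenario
    comparisons.

## The instantaneous-amplitude metric

Band power estimated per window reacts violently to short
large-amplitude artifacts (a deep breath, an ectopic beat, a transient
bradycardia): a 10 s event inflates every window that contains it,
producing rectangular plateaus the length of the window.  The
instantaneous-amplitude metric replaces "power of the window" by
"typical oscillation amplitude within the window":

1.  bandpass the uniformly resampled NNI series into LF and HF
    (`bandpass_filter()`: 4th-order Butterworth applied forward and
    backward, so the filter is zero-phase — envelope extraction is
    phase-sensitive);
2.  form the analytic signal of each band via the Hilbert transform and
    take its modulus (`hilbert_envelope()`);
3.  per sliding window, drop the largest and smallest 20% of envelope
    samples and average the rest (`trimmed_mean()`, `windowed_ia()`).

Because a 10 s artifact occupies ~3% of a 300 s window, it falls
entirely inside the trimmed tail and the window mean barely moves,
while the corresponding band-power trace shifts by its full energy
share.  The test suite quantifies this on a simulated resting recording
with an injected 10 s/300 ms deep breath: the maximal relative
deviation of the windowed HFiA trace from its artifact-free twin is
strictly smaller than that of the HFp trace.

For a stationary tone of amplitude $a$ the two views are linked by
$P = a^2/2$; the suite checks `LFp ≈ LFiA²/2` within 5% on single-tone
input.

### Reading of "the 20% largest and smallest"

The trimming rule is read as *per tail*: `floor(0.2 n)` samples dropped
from each end of the sorted window (40% in total).  The alternative
reading (20% in total, 10% per tail) is available via
`trimmed_mean(..., tail = "total")`.  Counts use `floor` and a stable
sort, so the statistic is deterministic under ties.

## Tunable parameters

| parameter | default | units | rationale |
|---|---|---|---|
| window length | 300 | s | ≥ 10 cycles of the 0.04 Hz LF edge per window (12 at 300 s); `validate_window_length()` reports cycles, the 30 s minimum resolvable period, and the beat-rate Nyquist |
| window step | 10 | s | conventional 4 min 50 s overlap |
| segment buffer | 120 | s | masks residuals of the preceding state at scenario boundaries |
| resampling rate | 4 | Hz | Nyquist 2 Hz is far above the 0.4 Hz HF edge; cubic spline on interval-vs-midpoint time |
| peak-removal rule | 30% of an 11-beat running median | — | the pre-conditioning step is named but not specified in the HRV literature we follow; both knobs are exposed |
| trim fraction | 0.2 per tail | — | see above |
| Welch segments | 100 s, 50% overlap, Hann | — | ≥ 4 LF-edge cycles per segment; density scaling, so the integral over a band is the band power in ms² |
| SVM | polynomial, degree 3, C = 1, coef0 = 1 | — | only the kernel family is dictated by the method; degree/C are conventional defaults, and coef0 = 1 makes the kernel span all monomials up to the degree (the homogeneous kernel cannot express interaction-only boundaries) |

Band edges are half-open (`[0.04, 0.15)` / `[0.15, 0.4]`) so 0.15 Hz is
counted once, in HF.

Numerical details worth knowing: band powers integrate the Welch
density by the trapezoid rule over the half-open band; windows are
half-open `[start, end)` on a time axis anchored at the first beat;
ratios with zero denominator and normalized powers at zero total power
are flagged `NA` rather than propagating NaN; the analytic signal is
formed by the FFT one-sided-spectrum construction and the first/last
two LF-edge periods carry an `edge_flag` that windows inherit as a
quality flag rather than being dropped.

## The synthetic-data generator

No public recordings accompany the protocol this package models, so
every claim is exercised against a seeded simulator
(`scenario_spec()`, `generate_protocol()`) whose band content is known
in closed form: the NN interval function is a mean plus one LF and one
HF sinusoid plus white Gaussian noise, and beats accumulate as
`t[k+1] = t[k] + m(t[k])/1000`.  With zero noise the tachogram equals
the closed form to machine precision, and its variance over whole
periods is `amp_lf²/2 + amp_hf²/2` — the oracle for all spectral
tests.  Artifacts are injectable: smooth unimodal interval excursions
(deep breath, transient bradycardia) and compensated 0.6/1.4 ectopic
pairs.

Two deliberate departures from the minimal model:

* **Slow amplitude drift.**  Real tachograms are nonstationary: band
  amplitudes wander over minutes.  A strictly stationary two-tone model
  makes every scenario trivially separable by every single feature,
  so the 1D-vs-2D contrast at the heart of the method could never
  manifest.  `scenario_spec()` therefore accepts a slow sinusoidal
  amplitude modulation per band (`drift_lf`, `drift_hf`, default depth
  0 — the closed form — and 6e-4 Hz, period ≈ 28 min, with phases drawn
  from the seeded stream).  The protocol presets use depth 0.15.
* **Subject-level random effects.**  `simulate_part1_cohort()` gives
  each simulated subject log-normal multipliers (sd 0.2 on the log
  scale) on both band amplitudes and a Gaussian offset (sd 60 ms) on
  the mean NNI.  Pooled across subjects, these baseline differences are
  what make univariate features ambiguous — and what per-subject
  first-rest median standardization (`standardize_by_baseline()`)
  partially removes, mirroring the protocol analysis this package
  models.

The `part1_protocol()` preset encodes five 15-minute segments — Rest 1,
Math, Rest 2, Exercise, Rest 3 — with effect directions taken from the
protocol literature: mental arithmetic raises the LF amplitude and
lowers the HF amplitude relative to rest; stepper exercise lowers the
HF amplitude and the mean NNI while leaving the LF amplitude near the
resting level.  The frozen magnitudes are rest (850 ms mean, LF 38 ms @
0.09 Hz, HF 40 ms @ 0.25 Hz), math (750, 52 @ 0.10, 15 @ 0.25),
exercise (600, 36 @ 0.08, 15 @ 0.30), all with 10 ms interval noise.
A synthetic transient-bradycardia artifact (8 s, 250 ms) sits in the
middle of Rest 3; its size is an illustrative placeholder, not an
empirical value.

What the simulator does *not* emulate: respiratory-coupling dynamics,
QRS morphology and detection errors, circadian trends, or the
integral-pulse-frequency-modulation view of beat generation.  Passing
tests therefore demonstrate internal correctness and robustness of the
pipeline under controlled nonstationarity — not clinical validity on
human recordings.

## The pooled study and its problem sizes

`run_part1_study()` is the package's headline computation: it simulates
a 10-subject cohort (the size of the protocol study it models), runs
sharp-peak removal, resampling, envelopes and per-window features for
every subject (37 windows per 15-minute segment after 120 s buffers),
pools Rest 1/Math/Exercise windows (≈ 1100 in total), standardizes each
subject by their Rest 1 median, and scores eight univariate metrics and
three 2D pairs by resubstitution CA.  Resubstitution is the primary
mode because the question it answers is *how separable the scenarios
are in a given representation*; `categorization_accuracy(mode = "cv")`
provides the stricter k-fold estimate.  Rank-sum p-values use one mean
per subject and scenario and are exact for these group sizes.

Across master seeds the study reproduces the qualitative structure it
was designed for: both-band 2D representations in the high 90s,
univariate metrics in the 65–90% range (each 1D projection is ambiguous
for at least one scenario pair), and the normalized-power pair `(LFn,
HFn)` performing worst among the 2D pairs — it is 2D only nominally,
since `HFn = 1 − LFn` collapses it to a line.  Individual seed
realizations vary by a few points; the amplitude-drift tails can push
one subject's scenario cloud into another's, which is exactly the
overlap the 2D representation is meant to expose rather than hide.

## Known limitations

* The sharp-peak rule (30% / 11 beats) is a reasonable stand-in for an
  unspecified pre-conditioning step; it is not claimed to reproduce any
  particular published figure.
* Interval values are attributed to interval midpoints before spline
  resampling, which implies a half-interval group delay relative to the
  generative model; amplitudes and band powers are unaffected.
* The SVM's degree, cost and scaling are conventions, not fitted
  hyperparameters; CA values on real data would depend on them.
* Decision regions are a plotting and categorization device; no
  physiological meaning is claimed for region boundaries.
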