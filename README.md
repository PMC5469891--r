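# hrv2d

Two-dimensional LF-HF analysis of heart rate variability (HRV) for the
categorization of mental and physical stress.

## What problem this solves, and for whom

HRV researchers summarize autonomic state from the frequency content of
the normal-to-normal interval (NNI) series: power in the low-frequency
band (LFp, 0.04–0.15 Hz, sympathetic-dominated) and the high-frequency
band (HFp, 0.15–0.4 Hz, parasympathetic).  The classical one-number
index, the ratio LFp/HFp, collapses this two-dimensional quantity onto
one axis, so distinct physiological states can be indistinguishable.
The ambiguity is visible in closed form: every member of the family

    P1 = LFp/HFp          P2 = b1·LFp²/HFp + b2     P3 = c1·LFp − c2·HFp + c3
    P4 = d1·LFp² − d2·HFp + d3                      P5 = e1·LFp/HFp² + e2

increases with LFp and decreases with HFp — all are "valid" stress
indices — yet along any constant-ratio locus HFp = 0.8·LFp, P1 is flat
at 1.25 while P2–P4 rise and P5 falls.  Normalized powers are no
escape: with TP = LFp + HFp one has HFn = 1 − LFn exactly, again one
degree of freedom.

`hrv2d` keeps both degrees of freedom.  Each sliding analysis window
(300 s, sliding by 10 s) becomes a point in the LF-HF plane, scenarios
occupy regions, and a polynomial-kernel SVM turns the regions into a
categorizer scored by categorization accuracy (CA).  For robustness to
short large-amplitude artifacts (deep breaths, ectopic beats, transient
bradycardia) the package implements the *instantaneous-amplitude*
feature pair: bandpass the resampled tachogram into LF and HF with a
zero-phase filter, take the Hilbert-envelope of each band, and average
each window after trimming the 20% largest and smallest envelope
samples.  A 10 s artifact lands in the trimmed tail and barely moves
`LFiA`/`HFiA`, while it inflates every band-power window that contains
it.

A seeded synthetic tachogram simulator with scenario protocols,
subject-level random effects and injectable artifacts provides ground
truth for every stage; no human recordings ship with the package.

## Worked example

Simulate the standardized rest/math/rest/exercise/rest protocol
(five 15-minute segments) and run the full pipeline:

```r
library(hrv2d)

rec <- generate_protocol(part1_protocol(seed = 42))
rec$segments
#> # A tibble: 5 × 3
#>   label    start_s end_s
#>   <chr>      <dbl> <dbl>
#> 1 Rest 1         0   900
#> 2 Math         900  1800
#> 3 Rest 2      1800  2700
#> 4 Exercise    2700  3600
#> 5 Rest 3      3600  4500

rep <- run_pipeline(rec$beats, labels = rec$segments)
rep
#> <hrv_report> 180 feature windows
#>   2D-iA categorization accuracy: 90.6%

dplyr::select(head(rep$features, 3),
              t_center_s, LFp_ms2, HFp_ms2, LFn, LFiA_ms, HFiA_ms, label)
#> # A tibble: 3 × 7
#>   t_center_s LFp_ms2 HFp_ms2   LFn LFiA_ms HFiA_ms label
#>        <dbl>   <dbl>   <dbl> <dbl>   <dbl>   <dbl> <chr>
#> 1       270.    832.    948. 0.467    40.6    42.8 Rest 1
#> 2       280.    846.    941. 0.473    40.9    42.6 Rest 1
#> 3       290.    862.    939. 0.479    41.2    42.5 Rest 1
```

Each row is one 300 s window (windows fully inside a 120 s-buffered
segment): `LFp_ms2`/`HFp_ms2` are Welch band powers in ms², `LFn` the
normalized LF share, and `LFiA_ms`/`HFiA_ms` the trimmed-mean Hilbert
envelopes in ms.  During Rest 1 the HF amplitude (~43 ms) slightly
exceeds LF (~41 ms): a resting, parasympathetically dominated pattern.
The report also carries exact rank-sum p-values per scenario pair and a
fitted 2D categorizer (`rep$model`), which `autoplot()` renders with
its decision regions.

Window-validity arithmetic and the ratio ambiguity in one breath:

```r
validate_window_length(300, 0.04, 60)
#> # A tibble: 1 × 3
#>   cycles min_period_s nyquist_hz
#>    <dbl>        <dbl>      <dbl>
#> 1     12           30        0.5

metric_family(c(1, 10, 100), 0.8 * c(1, 10, 100), "P1")
#> [1] 1.25 1.25 1.25
```

A 300 s window holds 12 cycles of the 0.04 Hz LF edge, resolves periods
down to 30 s, and at 60 bpm the beat rate supports frequencies up to
0.5 Hz — the window is valid for both bands.  The ratio metric cannot
tell (LFp, HFp) = (1, 0.8) from (100, 80); the 2D representation can.

The pooled cohort study (10 simulated subjects, per-subject Rest-1
median standardization, resubstitution CA for every representation) is
one call:

```r
study <- run_part1_study(n_subjects = 10, seed = 1)
tidy(study)       # CA per metric; 2D pairs vs univariate metrics
glance(study)     # headline: 2D-iA CA and the best 1D CA
autoplot(study)   # LF-HF scatter with SVM decision regions
```

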