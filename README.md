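# hrventropy

Entropy analysis of heart rate variability (HRV): **randomness versus
complexity**.

Beat-to-beat RR-interval (RRI) series mix two kinds of information.
*Randomness* — how unpredictable the next beat is — follows the
sympatho/vagal balance and is captured by estimators of the
Kolmogorov–Sinai entropy; *complexity* — how richly structured the
generating cardiovascular control is — can change (e.g. with impaired
integrative autonomic regulation after a low spinal cord lesion) even when
the HRV spectrum and all second-order statistics are untouched.
`hrventropy` implements the three estimators that probe these axes, for
physiologists and methodologists analysing short (~512-beat) recordings:

* **Sample Entropy** — `sample_entropy()`:
  SampEn = −ln [*n*ₚ(*m*+1, *r*) / *n*ₚ(*m*, *r*)], counting template-vector
  pairs with Chebyshev distance < *r* = 0.2 SD at embedding dimensions *m*
  and *m*+1 (equal vector counts *N* − *m*τ at both dimensions); zero-match
  cases are returned as explicitly *undefined*, never a silent 0 or ∞.
* **Fuzzy Entropy** — `fuzzy_entropy()`: ln φ*ᵐ* − ln φ*ᵐ*⁺¹ with a graded
  exponential membership, global form (no local trend removal); the default
  scale-invariant membership exp[−(d/r)ⁿ] and the historical exp(−dⁿ/r)
  family are both available.
* **Distribution Entropy** — `distribution_entropy()`: normalised Shannon
  entropy of the empirical distribution (ePDF, M = 512 bins) of *all*
  pairwise template distances — no threshold, no extra dimension; a measure
  of phase-space structure rather than series unpredictability.

Around the estimators the package provides multiscale profiles
(`multiscale_entropy()`: zero-phase Butterworth low-pass at cut-off 0.5/τ,
no decimation, delay-τ embedding, with classic moving-average
coarse-graining for contrast), benchmark-signal generators (white / pink /
Brown noise, chaotic and periodic logistic maps), a synthetic RRI cohort
with posture and lesion presets (`gen_synthetic_rri()`, `gen_cohort()`),
scale-wise nonparametric cohort statistics with FDR adjustment
(`compare_cohort()`, exact signed-rank under ties), RRI cleaning and
segment selection (`clean_rri()`, `select_segment()`), plain-text RRI and
CSV import/export, and a small command-line front-end
(`inst/cli/hrvent.R`).

## Worked example

```r
library(hrventropy)
rri <- gen_synthetic_rri("AB", "supine", seed = 7)  # 512 beats, ms

sample_entropy(rri)
#> Sample Entropy (m = 2, delay = 1, r = 8)
#>   value: 2.15967
distribution_entropy(rri)
#> Distribution Entropy (m = 2, delay = 1)
#>   value: 0.886539

coef(multiscale_entropy(rri, "sampen", scales = c(1, 2, 5, 10, 20)))
#>      tau1      tau2      tau5     tau10     tau20
#> 2.1596718 1.8929723 1.4573648 0.7652005 0.7293976
```

The tolerance `r = 8` is 20% of the series' 40 ms SD.  SampEn ≈ 2.16 says
the supine preset is strongly vagally (white-noise-like) driven; the mSE
profile falling from 2.16 to 0.73 across scales 1–20 is the classic
signature of a noise-dominated series losing irregularity once fast
fluctuations are filtered out.  DistEn ≈ 0.89 sits where white-noise-like
dynamics put it (the chaotic benchmark reaches ≈ 0.99, a periodic one
≈ 0.25).

Benchmark-bank summary (30 series per process, 512 samples, m = 2):

```r
res <- reproduce_bank(seed = 1, n_series = 30, m = 2L)
subset(res$tau1, method != "fuzzyen")
#>   process method m      mean          sem n_undefined
#>     white sampen 2 2.2011255 1.202510e-02           0
#>     white disten 2 0.9036282 2.387309e-03           0
#>      pink sampen 2 1.7980802 1.703183e-02           0
#>      pink disten 2 0.9072614 2.204420e-03           0
#>     brown sampen 2 0.4066502 3.914890e-02           0
#>     brown disten 2 0.9409405 3.179530e-03           0
#>   chaotic sampen 2 0.6404305 3.039292e-03           0
#>   chaotic disten 2 0.9943355 3.971593e-04           0
#>  periodic sampen 2 0.0000000 0.000000e+00           0
#>  periodic disten 2 0.2500527 2.026777e-05           0
```

Read the dissociation off the table: SampEn ranks white > pink > brown
(increasing long-range correlation = increasing predictability) with the
chaotic series in between, while DistEn is *largest* for the chaotic
series, higher for Brown than white noise, and virtually identical for pink
and white — randomness and complexity are different axes.  Note SampEn of
the periodic series is exactly 0: with transients discarded the ω = 3.5
logistic map sits exactly on its 4-cycle, and every m-dimensional template
match survives at m + 1 (the distance ePDF still has structure, so DistEn
is 0.25, about 28% of the white-noise value).  See the methods vignette
(`vignettes/hrv-entropy-methods.Rmd`) for the estimator conventions and
design decisions.

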