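---
title: "Randomness versus complexity: Sample, Fuzzy and Distribution Entropy of heart rate variability"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Randomness versus complexity: Sample, Fuzzy and Distribution Entropy of heart rate variability}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hrventropy)
```

## The problem

Beat-to-beat heart-rate variability (HRV) carries two conceptually distinct
kinds of information.  *Randomness* — how unpredictable the next RR interval
is given its recent past — tracks the sympatho/vagal balance: vagally driven
fluctuations resemble white noise, sympathetically driven ones resemble
strongly correlated (Brown-noise-like) dynamics, so a postural shift from
supine to sitting lowers HRV randomness without any structural change in the
regulating system.  *Complexity* — how richly structured the dynamics of the
generating system are — can change with conditions that impair integrative
autonomic control (such as a low-level spinal cord lesion) even when the HRV
power spectrum and all second-order amplitude statistics are untouched.

This package implements three entropy estimators that probe these two axes,
their multiscale extensions, the synthetic benchmark signals used to
characterise them, a synthetic RR-interval (RRI) cohort generator for
end-to-end validation, and the nonparametric statistics for posture and
group comparisons.

## The estimators

All three start from the same construction: the series
$X = \{x_1, \ldots, x_N\}$ is delay-embedded into template vectors
$X^m_i = [x_i, x_{i+\tau}, \ldots, x_{i+(m-1)\tau}]$ and pairwise
*Chebyshev* (infinity-norm) distances $d^m_{ij}$ are computed for all
unordered pairs.  We use $i = 1 \ldots N - m\tau$ vectors at *both*
dimensions $m$ and $m+1$, so the two match counts of SampEn run over equally
many vectors and their normalisations cancel.

**Sample Entropy** (`sample_entropy()`):
$\mathrm{SampEn} = -\ln[n_p(m+1, r) / n_p(m, r)]$, with $n_p(m, r)$ the
number of pairs with $d^m_{ij} < r$ (strict inequality) and
$r = 0.2\,\mathrm{SD}(X)$ by default.  When either count is zero the
estimate is returned as an explicitly *undefined* value carrying the reason,
never as a silent $0$ or $\infty$; group summaries skip and count these.

**Fuzzy Entropy** (`fuzzy_entropy()`):
$\mathrm{FuzzyEn} = \ln\phi^m - \ln\phi^{m+1}$, where $\phi^m$ is the mean
pairwise membership.  This is the *global* form, without local trend
removal, so values are comparable to SampEn at the same $m$.  The default
membership is $\exp[-(d/r)^n]$ with $n = 2$.  The literature also prints the
quadratic-exponential family $\exp(-d^n/r)$; we expose it as
`fuzzy_form = "chen"` but do not use it by default, because for $n \ne 1$ it
is not invariant under amplitude rescaling of the series — the same signal
measured in different units gets a different FuzzyEn — and on unit-free
synthetic benchmarks it even reorders processes (pink noise can exceed white
noise).  With the scaled form, FuzzyEn is exactly affine-invariant, always
defined, and non-negative.

**Distribution Entropy** (`distribution_entropy()`): the empirical
probability distribution (ePDF) of *all* the distances $d^m_{ij}$ is taken
over $M = 512$ equispaced bins spanning their observed range, and
$\mathrm{DistEn} = -\sum_t p_t \log_2 p_t / \log_2 M \in [0, 1]$.  No
tolerance threshold and no $m+1$ embedding are involved: DistEn measures the
entropy of a *structure of the phase space* (the distance distribution), not
the unpredictability of the series, which is why it responds to alterations
of system complexity that leave randomness measures unmoved.  A degenerate
distance set (e.g. a constant series) gives DistEn $= 0$ by convention, the
entropy of a single-outcome distribution.

```{r estimators}
set.seed(1)
x <- rnorm(512)                       # white noise benchmark
sample_entropy(x)
fuzzy_entropy(x)
distribution_entropy(x)
```

## Multiscale profiles

`multiscale_entropy()` evaluates an estimator at scales $\tau = 1 \ldots 20$.
The default path low-pass filters the series at each $\tau$ with a
zero-phase Butterworth filter at cut-off $0.5/\tau$ cycles/sample, does
*not* decimate, and embeds with delay $\tau$.  Compared with the classic
moving-average coarse-graining (kept available as `filter = "ma"`), the
Butterworth design has a far better transition band: the moving average
aliases periodic components near its lobe zeros.  The package demonstrates
this directly — the mDE profile of the period-4 logistic series
($\omega = 3.5$) under moving-average coarse-graining collapses to 0
whenever $\tau$ is a multiple of 4 (the block mean becomes constant),
imprinting a period-4 comb on the profile that is entirely absent under the
Butterworth path.  Because that comb carries strong harmonics, the
acceptance check detects it with a comb-contrast statistic (mean of the
linearly detrended profile off multiples of 4 minus the mean at multiples
of 4) together with the discrete-spectrum line at period 4, rather than
naively asking for the largest DFT peak.

Numerical choices:

* **Filter order.**  Not fixed by the literature; default 6 per pass
  (a 12-pole magnitude response after the forward–backward cascade),
  configurable.  A steep transition band is the entire motivation for
  replacing the moving average.
* **Edge handling.**  Odd (point-symmetric) reflection of length
  $3 \times \mathrm{order}$ at both ends, with steady-state initial
  conditions ("the signal was at its first sample forever"), then trimming.
  A constant series passes through unchanged to $10^{-10}$, and transients
  on 512-beat records are suppressed.
* **Tolerance across scales.**  $r$ is recomputed as $0.2\,\mathrm{SD}$ of
  the *filtered* series at each scale (the refined-multiscale convention):
  low-pass filtering removes variance, and a frozen threshold would mix that
  amplitude loss into the entropy estimate.  `rescale_r = FALSE` freezes the
  raw-series tolerance instead.
* **Bin count.**  DistEn keeps $M = 512$ at every scale.
* **Feasibility.**  The delay-$\tau$ embedding needs $N - m\tau \ge 2$
  vectors; at $N = 512$, $m = 2$, $\tau = 20$ there are 472 — no truncation
  is ever needed, but the bound is enforced with an explicit error.
* **Scale 1** bypasses filtering entirely and is bit-identical to the base
  estimator — an invariant under test.

## The synthetic benchmark bank

`gen_bank()` generates 30 series per process, 512 samples each: Gaussian
white noise, pink noise (frequency-domain $1/\sqrt{f}$ amplitude shaping of
a white spectrum — exact target slope, no filter warm-up), Brown noise
(cumulated white noise), and chaotic ($\omega = 4$) and periodic
($\omega = 3.5$) logistic-map series with 1000 transient iterations
discarded (initial condition drawn uniformly in $(0.1, 0.9)$ from the
seed).  Everything is reproducible bit-for-bit from the seed.

On this bank the package reproduces the published fingerprint: SampEn and
FuzzyEn order white $>$ pink $>$ brown $>$ periodic with the chaotic series
between pink and brown, while DistEn is largest for the chaotic series,
*higher* for Brown than white noise, and virtually equal for pink and white
— randomness and complexity genuinely dissociate.  One caveat discovered by
this implementation: with transients discarded the $\omega = 3.5$ series
sits exactly on its 4-cycle, the tolerance $0.2\,\mathrm{SD} \approx 0.042$
is smaller than the smallest attractor gap ($\approx 0.048$), so *only*
exact-repeat template pairs match, the $m$ and $m{+}1$ match sets coincide,
and SampEn of the periodic series is exactly 0 — not merely "about 1% of
white noise".  The reported ratio of roughly 1% is reproduced by FuzzyEn
under the `"chen"` membership (0.8%), not by SampEn under any convention we
could construct; the acceptance suite reports the computed SampEn ratio
honestly.  DistEn of the periodic series is $\approx 0.28$ of the
white-noise value at $m = 2$, consistent with the published "about
one-third".

## The synthetic RRI cohort

`gen_synthetic_rri()` is a *stand-in* for restricted clinical recordings —
explicitly not a physiological model.  Each series is a standardised mixture
$\mathrm{RRI} = \mu + \sigma[\sqrt{1-f}\,v + \sqrt{f}\,s]$ whose total SD is
exactly $\sigma$ for every preset, so all second-order amplitude statistics
are matched between groups by construction.  The correlated "sympathetic"
component $s$ is $\sqrt{0.7}\,\mathrm{pink} + \sqrt{0.3}\,\mathrm{Brown}$
(standardised); sitting raises its variance share $f$ from 0.30 to 0.60.
The SCI preset replaces 70% of the vagal component's variance with a
standardised chaotic logistic series, flattening the distance ePDF.

Two design points deserve explanation.  First, a purely Brown correlated
component would make the *posture* contrast visible to DistEn (Brown noise
has distinctly higher DistEn than white), destroying the signature the
cohort is meant to carry; pink-dominated correlated noise moves
SampEn/FuzzyEn strongly while leaving DistEn essentially flat, which is
exactly the dissociation required.  Second, the chaotic admixture raises
DistEn at nearly constant SampEn/FuzzyEn as long as enough white noise
remains (Monte-Carlo power at $n = 20$ per group, supine: DistEn 0.93,
SampEn 0.07, FuzzyEn 0.00), so no compensating adjustment of the other
fractions is needed; at the sitting preset the chaotic share is diluted by
the larger $f$ and the group separation weakens, which is why the validation
tests read the group contrast in the supine stratum.  Mean RRI defaults (950
ms supine, 860 ms sitting) are cosmetic realism; the entropy estimators are
affine-invariant, so means and SDs do not influence them.

What passing these tests shows — and does not show.  The generator emulates
the *directional* structure (which estimator moves under which
manipulation), under matched second-order statistics, with between-subject
variability arising only from finite-record estimation noise.  It does not
emulate absolute clinical entropy values, respiratory or Mayer-wave
oscillations, subject-level traits, or non-stationarity; agreement here
validates the pipeline's machinery, not any physiological claim.

## Cohort statistics

`compare_cohort()` computes the chosen estimator per recording and contrasts
supine versus sitting within each group (Wilcoxon signed-rank, paired over
subjects with both postures; subjects missing one posture drop out of the
paired contrast only) and AB versus SCI within each posture (Wilcoxon
rank-sum).  Scale-1 contrasts are a-posteriori comparisons and are
Benjamini–Hochberg-adjusted together; at $\tau \ge 2$ each scale tests its
own null hypothesis, so no multiplicity adjustment is applied — matching the
published analysis.  Undefined estimates are excluded listwise per contrast
with the exclusion count reported.

The signed-rank test enumerates its null distribution exactly for
$n \le 25$ *including ties* (convolution over midranks — base R's exact path
refuses ties); the rank-sum test uses the exact Mann–Whitney distribution
for small tie-free samples; both fall back to normal approximations with tie
and continuity corrections that match `stats::wilcox.test()` to $10^{-10}$,
which serves as an independent oracle in the tests (never as the
implementation).  Two-sided p-values throughout; the omnibus linear
mixed-effects analysis is deliberately out of scope — `cohort_estimates()`
exports the tidy long-format table (subject, group, posture, method, m,
value) that such a model consumes in any stats package.

```{r cohort}
co <- gen_cohort(n_ab = 8, n_sci = 8, n = 256, seed = 42)
compare_cohort(co, method = "disten")
```

## RRI cleaning and segments

Visual premature-beat editing is not reproducible, so `clean_rri()` applies
an explicit rule: a beat deviating by more than 25% from the median of the
surrounding 5-beat window is *removed* (not interpolated); removing more
than 10% of beats flags the series low-quality with a warning.
`select_segment()` then takes 512 consecutive beats (the first such window
by default, or the centred one).  Both parameters are configuration-exposed.

## Problem sizes and known limitations

The validation suite uses the study-scale bank (30 series per process, 512
samples, scales 1–20, both embedding dimensions), 7 replicate synthetic
cohorts of 20 + 20 subjects for the signature check, 200 replicates for
type-I control (with disjoint deterministic seed blocks so no series is
reused across replicates), and 50 series of length 128 for the
brute-force-oracle equivalence at $10^{-12}$.

Limitations: mSE of Brown noise rises monotonically with scale at $m = 1$
but peaks near $\tau \approx 8$ at $m = 2$ under every filter order and
tolerance convention we tried, so the monotone claim is asserted at $m = 1$
and as an endpoint inequality at $m = 2$; DistEn's group separation fades at
$\tau > 1$ (expected — it is designed to detect complexity at scale 1); and
the exact signed-rank enumeration is limited to $n \le 25$ by design, beyond
which the tie-corrected normal approximation is used.
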