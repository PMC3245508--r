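---
title: "Functional linear modeling of circadian actigraphy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Functional linear modeling of circadian actigraphy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(actflm)
```

## The problem

Wrist actigraphy records one activity count per minute for a week or
more per subject.  Collapsing such a recording to a scalar (mean
activity, total sleep time) can mask group differences entirely: two
groups with opposite morning/afternoon activity patterns can share the
same daily mean.  actflm instead treats each subject's rest--activity
rhythm as a smooth function of clock time and compares whole functions
across clinical groups, answering not only *whether* groups differ but
*when during the day* they differ.

## Model and procedure

**Circadian profile.**  For subject $k$, the minute counts $y_{kj}$ on
the kept weekdays (midnight Monday to midnight Saturday by default) are
averaged minute by minute into one 1440-point profile.  Internally the
minute grid is 0-based: index $j$ covers the clock interval
$[j-1, j)$ minutes after midnight.  Weekends are excluded by default to
avoid mixing weekday and weekend rhythms; day-effect models are out of
scope here.

**Fourier smoothing.**  The profile is projected onto a Fourier basis
$\Phi_1(t)=1,\ \Phi_2(t)=\cos\omega t,\ \Phi_3(t)=\sin\omega t,\dots$
with $\omega = 2\pi/T$, $T = 1440$ minutes, by unweighted least squares
(the SMSSE criterion $\sum_j (y_{kj} - \sum_i a_{ik}\Phi_i(t_j))^2$).
The default of $n = 9$ basis functions (constant plus four harmonic
pairs, i.e. periods of 24, 12, 8 and 6 hours) captures the major
circadian trend of minute actigraphy while suppressing minute-level
noise; both $n$ and $T$ are configurable, and $n$ must be odd so every
harmonic keeps its sine/cosine partner.  Raw counts are not normalised
before smoothing — all analysis operates on the functional form.  The
solve uses a QR factorisation rather than the explicit
$(\Phi'\Phi)^{-1}\Phi'$ inverse; the two agree to $10^{-8}$ relative
tolerance (a tested contract), the QR route simply being the numerically
stable formulation of the same estimator.  No roughness penalty is
used: the estimator is the plain least-squares projection.

**Function-on-scalar regression.**  With smoothed curves
$\mathrm{Act}_k(t)$ and scalar covariates coded into a design matrix
$Z$ ($N \times p$, first column all ones), the functional linear model
is
$$\mathrm{Act}_k(t) = Z_k\,\beta(t) + \varepsilon_k(t),$$
estimated by minimising the integrated squared error (LMSSE).  Binary
covariates are coded $+1$ below a clinical threshold and $-1$ at or
above it (low disease burden $= +1$), e.g. apnea-hypopnea index at its
cohort median, BMI at the obesity threshold of 30; group mean curves
are then sums/differences of coefficient curves, with interaction
coefficients added for concordant codes and subtracted for discordant
ones.  Continuous covariates enter uncentred by default (centring and
standardising are options); figures display continuous fits at the
10/50/90% quantiles, but inference never bins.

Because every curve lives in one Fourier basis that is orthogonal on
the evaluation grid, the LMSSE minimiser is obtained exactly by
ordinary least squares on the $N \times 9$ coefficient matrix, column
by column.  Equality with pointwise OLS at each of the 1440 minutes is
asserted by tests to $10^{-8}$, so the coefficient-space shortcut is a
verified identity, not an approximation.

**Pointwise F statistic.**  At each minute,
$$F(t) = \frac{\operatorname{Var}\big[(Z\hat\beta)_k(t)\big]}
             {\tfrac1N \sum_k \big(\mathrm{Act}_k(t) - (Z\hat\beta)_k(t)\big)^2}.$$
The variance in the numerator uses the sample divisor $N-1$ while the
denominator keeps the $1/N$ factor shown above; the divisor pair is a
deliberate, documented choice (the source formulation names no
divisors), and it implies the exact conversion
$F(t) = F_{\mathrm{anova}} \cdot N / ((N-1)(N-2))$ against the
classical one-way ANOVA F for balanced two-group constant curves —
which the tests verify.  Points where numerator and denominator are
both zero are reported as 0 with a warning.

**Permutation inference.**  The null distribution of $F(t)$ is built by
randomly rearranging the covariate assignment: each permutation shuffles
the non-intercept rows of $Z$ jointly (keeping the observed joint
covariate distribution in multi-term models) and refits the full model.
The *global* test compares the observed $\max_t F(t)$ with the permuted
maxima — one conservative critical value for the whole curve; the
*pointwise* test compares $F(t)$ with the permuted values minute by
minute.  p-values use the add-one estimator $(1+b)/(P+1)$, which is
strictly positive and valid, and ties count against rejection
(conservative).  In multi-covariate models the permutation tests the
global null only; it cannot isolate the significance of one covariate
among several.  Intervals where $F(t)$ exceeds a critical value are
reported as half-open minute ranges with clock labels, and runs
touching both midnight edges are merged into a single wrapped interval.

**Confidence bands.**  Pointwise (not simultaneous) normal-theory
limits for a group mean curve $c'\hat\beta(t)$:
$c'\hat\beta(t) \pm z_{(1+\gamma)/2}
\sqrt{\hat\sigma^2(t)\, c'(Z'Z)^{-1}c}$ with
$\hat\sigma^2(t) = \sum_k \hat\varepsilon_k(t)^2/(N-p)$.  The normal
quantile (rather than a t quantile) is the large-$N$ choice; at the
reference cohort size $N = 40$ the measured coverage is ~0.95 (see
below).

## Design decisions worth knowing

* **Average-then-smooth.**  The five weekday vectors are averaged first
  and the single averaged profile is smoothed, rather than smoothing
  each day and averaging curves.  With a common basis and grid the two
  orders coincide for complete days; averaging first also handles
  missing minutes cleanly.
* **Missing data.**  Gaps in the epoch stream become explicit missing
  minutes at I/O time (never imputed); edge days with incomplete
  coverage are dropped by default (`partial = "keep"` retains them);
  within kept days averaging simply ignores missing minutes
  (`missing = "ignore"`), erroring only if some minute has no data on
  any day.  Subjects need at least 3 usable weekdays (configurable) —
  a balance between robustness of the 1440-point average and subject
  retention — otherwise they are excluded with a logged warning.
* **Timestamps** are local clock time with no daylight-saving
  adjustment, since the analysis indexes minutes from midnight to
  midnight.
* **Complete-case per model.**  Each model drops only the subjects
  missing one of *its* covariates, so different models legitimately
  use different $N$; the design builder records who was dropped.
* **Thresholds.**  `"median"` thresholds are resolved on the per-model
  complete cases and stored in the fitted design for reporting.
* **Degenerate inputs.**  Even basis sizes, rank-deficient grids,
  singular or constant-column designs, $N \le p$, and all-one-group
  permutations are rejected with named errors rather than silently
  producing numbers.

## The synthetic cohort generator

`simulate_cohort()` draws minute counts
$$y = \max\!\big(0,\ \mu(t) + \textstyle\sum_c x_{kc}\,\delta_c(t)
      + s_k(t) + e\big)$$
per subject, day and minute, where $\mu$ and each effect $\delta_c$ are
cosinor-style curves (mesor, amplitude, acrophase, optional extra
harmonics), $s_k$ is a smooth subject-level random curve whose nine
Fourier coefficients are iid normal (scaled so its pointwise SD equals
`subject_sd` — in-span by construction, so the default smoother is
unbiased for it; a `rough_sd` option adds out-of-span harmonic-12
structure to probe robustness), and $e$ is Gaussian minute noise
(truncated at zero with the mean, because counts are nonnegative) or a
Poisson-like family with variance = mean × dispersion.  Truth curves
are stored pre-truncation; with the reference parameters below the mean
never approaches zero closely enough for truncation bias to matter.
Covariate codes are deterministic functions of the cohort size
(alternating $\pm 1$; evenly spaced continuous values), so the truth
bundle is identical across seeds and only the noise changes — a
property the tests rely on.

What the generator deliberately does **not** emulate: device artefacts
(spurious spikes, off-wrist periods beyond simple masked gaps),
non-stationary day-to-day rhythm changes, autocorrelated minute noise,
and the heavy right tail of real activity counts.  Passing tests
therefore demonstrate correctness of the estimators under a clean
data-generating model, not robustness to every property of real
recordings.

## Reference simulation settings

The simulation studies in the test suite and the acceptance script use
one fixed set of conditions, chosen to resemble a moderate clinical
actigraphy cohort: baseline mesor 300 and amplitude 150 counts/min with
a 15:00 acrophase, subject-level SD 30, minute noise SD 60, five
recorded weekdays, and cohorts of $N = 30$ (testing) or $N = 40$
(estimation).  Against these conditions the suite measures: type-I
error of the global test at $\alpha = 0.05$ (200 replicates × 199
permutations; binomial 95% band [0.02, 0.09]), power against a constant
group shift of twice the minute noise SD (≥ 0.9 over 100 replicates),
recovery of the true effect curve within 3 Monte-Carlo standard errors
at 24 hourly probe times (100 replicates), and pointwise band coverage
within [0.92, 0.98] at those probe times (500 replicates).

## Known limitations

* One curve per subject: day effects, weekday/weekend contrasts and
  functional mixed models are out of scope, as are functional PCA and
  penalised or alternative (spline/wavelet) smoothers.
* The permutation test is global across covariates; single-covariate
  significance in a multi-covariate model is not available.
* Bands are pointwise; simultaneous coverage over the whole day is not
  claimed (the global max-F critical value plays that role for the
  F test).
* Epochs other than 60 s must be resampled before profiling, and
  proprietary device exports must first be converted to the documented
  long CSV dialect.
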