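---
title: "Methods: age-normative reference values for serum neurofilament light chain"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: age-normative reference values for serum neurofilament light chain}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Serum neurofilament light chain (sNfL) is a blood marker of neuro-axonal
injury. In healthy adults its distribution is strongly right-skewed and its
level rises steeply with age (roughly 3% per year on the median), with
females running slightly lower than males. A single reference limit is
therefore clinically meaningless: what is needed is an age- and sex-specific
normative model. `nflref` implements the standard toolkit for building one
from a healthy reference cohort, at three levels of sophistication:

1. **Descriptive reference intervals.** The nonparametric 2.5th–97.5th
   percentile range within age strata, the definition used by the CLSI EP28
   guideline, with bootstrap confidence intervals for stratum medians and
   Mann–Whitney comparisons between groups.
2. **A log10-linear cut-off model.** Ordinary least squares of
   `log10(sNfL)` on age and a female indicator; adding 1.96 residual
   standard errors and exponentiating gives a closed-form multiplicative
   formula for the predicted 97.5th percentile.
3. **BCCG (LMS) centile curves.** A GAMLSS-type fit of the Box-Cox
   Cole-Green distribution with age-varying parameters, yielding full
   centile charts and per-subject Z-scores.

Because subject-level reference data of this kind are rarely public, the
package ships a seeded synthetic-cohort generator that emulates the
demographic and distributional structure of a healthy adult reference
population; every downstream stage is exercised and validated against the
generator's known truth.

## The synthetic cohort generator

`cohort_config()` fixes the study conditions. The defaults describe a
223-subject cohort with decade counts 57/58/59/37/12 over ages 20–69 and a
57% female fraction. Concentrations are drawn from a BCCG distribution with

$$\mu(\text{age}, \text{sex}) = 2.1 \cdot 10^{\,0.012\,\text{age}} \cdot
  0.873^{[\text{female}]} \ \text{pg/ml}, \qquad \sigma = 0.38, \qquad
  \nu = 0.3 .$$

The calibration is a design choice of the generator, not an estimate: it
places the stratified medians at roughly 3.6 pg/ml (ages 20–29) up to
12 pg/ml (ages 60–69), puts males about 1 pg/ml above females, and gives a
residual spread of $\sigma/\ln 10 \approx 0.166$ on the log10 scale —
the regime reported for healthy adult cohorts. Ages are drawn
continuous-uniform within each decade bin (reference tables only report
decade membership); sex is an independent Bernoulli draw by default, with a
fixed-count mode (`sex_mode = "fixed"`) for emulating cohorts with exact
totals. Recruitment windows of 18–70 years are common while decade tables
start at 20; the generator follows its decade bins (20–70) and the CSV
reader validates 18–70, so both conventions are representable.

Sampling is by inverse transform of a standard-normal draw,
$y = \mu(1 + \nu\sigma z)^{1/\nu}$; draws with $1 + \nu\sigma z \le 0$
(possible for $\nu \neq 0$) are rejected and redrawn. At the default
parameters the rejection probability is below $10^{-15}$, so the truncation
is practically invisible. A single `set.seed()` call drives all randomness,
making cohorts byte-identical for equal (config, seed).

What the generator does **not** emulate: assay noise and plate effects,
covariates such as BMI or renal function, and any age-by-sex interaction or
age-varying dispersion. Passing recovery tests on this generator therefore
demonstrates correctness of the estimators under the stated model, not
robustness to the messiness of real laboratory data.

## Descriptive reference intervals

The percentile rule is fixed to the CLSI nonparametric convention: rank
$r = p(n+1)$ with linear interpolation between order statistics, clamped to
the extremes when $r$ falls outside $[1, n]$ (`clsi_percentile()`). Guideline
documents name the convention without spelling out the interpolation rule;
this package states it and tests it against brute-force oracles. Ties are
handled by ordinary order statistics — no jittering.

Strata below the CLSI minimum of 120 subjects are computed and *flagged*
(`meets_clsi_min_n = FALSE`), never refused: decade tables in practice
include strata with as few as 12 subjects, and refusing them would make the
package useless for exactly the tables it is meant to reproduce.

Median confidence intervals use the percentile bootstrap on the raw
(untransformed) values, 2000 replicates by default — enough that the
Monte-Carlo error of a 95% interval endpoint is well below the reporting
precision of a concentration table.

`mann_whitney_u()` reports the U statistic counting pairs where the first
sample exceeds the second (ties count one half). The two-sided p-value is
exact when both groups are tie-free and the smaller has at most 8
observations — enumeration is cheap there — and otherwise uses the
tie-corrected normal approximation with continuity correction.

## The log10-linear cut-off model

`fit_loglinear()` is deliberately plain OLS: `log10(sNfL) ~ age + female`,
female coded 1 (so its coefficient is negative in cohorts where females run
lower). The "standard error of the model" is defined as the residual
standard deviation with $n - 3$ degrees of freedom; coefficient p-values
come from the t distribution. Under the implied log-normal residual model
the upper 97.5% prediction limit is the fitted line plus $1.96\,s$ on the
log10 scale, and exponentiating gives the multiplicative form

$$\text{sNfL}_{97.5}(\text{age}, \text{sex}) = 10^{\,\beta_0 + 1.96 s}
  \cdot (10^{\beta_{\text{age}}})^{\text{age}}
  \cdot (10^{\beta_{\text{female}}})^{[\text{female}]} .$$

The multiplier 1.96 is exposed as `z_mult` (0 recovers the median line).
`published_loglinear_fit()` freezes a published coefficient set
(0.326, 0.012, −0.059, s = 0.166) so the formula operations are usable
without subject-level data. Reconstructing the scale constant from those
*rounded* coefficients gives 4.481 pg/ml where the source computed 4.470
from unrounded internals — a 0.25% discrepancy that is documented rather
than hidden, and well within the model's own uncertainty.

## The BCCG distribution and the centile fit

The Box-Cox Cole-Green (LMS) distribution declares
$z = \{(y/\mu)^\nu - 1\}/(\nu\sigma)$ standard normal, with the log-normal
limit $z = \log(y/\mu)/\sigma$ as $\nu \to 0$. The branch switch happens at
$|\nu| \le 10^{-5}$, implemented with `expm1`/`log1p` so the two branches
agree to $10^{-5}$ relative across the switch (tested). Because the
transform reaches only part of the real line when $\nu \neq 0$, the raw
density integrates to $\Phi(1/(\sigma|\nu|))$; following the original LMS
convention the correction is ignored while that mass exceeds
$1 - 10^{-3}$ (always true in the biomarker regime, e.g. mass
$\approx 1 - 10^{-18}$ at the generator defaults) and applied as an exact
renormalization otherwise.

`fit_bccg_centiles()` maximizes the BCCG log-likelihood with age-varying
parameters: log link for $\mu$ and $\sigma$, identity for $\nu$. The
smoothness budget is expressed as a per-parameter `edf`: 1 = constant,
2 = linear in (standardized) age, $k \ge 3$ = an unpenalized natural cubic
regression spline whose design has exactly $k$ columns, with
quantile-placed interior knots. A regression spline with the requested
degrees of freedom gives the same smoothness budget as a penalized smoother
tuned to that effective df, without a ridge-parameter search — an
appropriate simplification when the edf is user-fixed and small, which is
the only regime a ~200-subject cohort supports. Defaults are edf 3 for
$\mu$ and constants for $\sigma$ and $\nu$: a spline in age for the median,
but no pretence that 223 subjects can support age-varying spread or
skewness.

Optimization cycles Newton-type block updates in the
Rigby–Stasinopoulos manner: the $\mu$ coefficients are updated by BFGS with
the analytic score $\partial\ell/\partial\eta_\mu = z(y/\mu)^\nu/\sigma -
\nu$, then the $\sigma$ and $\nu$ blocks, repeating until the
log-likelihood changes by less than $10^{-6}$ relative (at most 200 outer
cycles; typically 3–6). Initialization: $\mu$ from OLS of $\log y$ on the
spline basis, $\sigma$ from its residual spread, $\nu = 1$. Line-search
overshoots that overflow the log links are rejected by capping the
objective. The fit is deterministic given data and settings;
non-convergence raises an error carrying the tail of the likelihood trace.
Fitting is sex-stratified by default (`by_sex = TRUE`, matching
sex-stratified centile charts); `by_sex = FALSE` gives a single pooled
curve set. Both modes are provided because published cohort analyses are
often ambiguous about which was used.

Prediction outside the fitted age range is refused by default
(`allow_extrapolation = TRUE` overrides): centile estimates beyond the
observed ages — above ~50 years in small cohorts — are the least precise
part of any normative model. Model serialization keeps ~15 significant
digits, which reproduces predictions to better than $10^{-12}$ relative on
reload; the age-domain check tolerates the corresponding last-digit jitter.

## Validation design and problem sizes

All claims the package makes about itself are computed, not asserted:

* distribution-level identities (quantile/Z/CDF roundtrips to $10^{-9}$,
  density normalization to $10^{-4}$ by quadrature, the $\nu\to 0$ limit
  against the closed-form log-normal);
* estimator-level recovery against the generator truth — with 2000
  subjects per sex the fitted median curve stays within 5% of the
  generating curve across ages 20–60, in-sample Z-scores have mean within
  ±0.1 and SD within 1 ± 0.1, and the fitted 2.5th–97.5th band captures
  95% ± 1% of 50 000 fresh draws (the package's operational definition of
  a valid reference interval);
* agreement between routes — when the generator uses $\nu = 0$ and constant
  $\sigma$ (so the log-linear model is exactly true), the BCCG 97.5th
  centile and the exponentiated regression formula agree within 3% across
  ages 20–60 at 5000 subjects per sex.

Scale and shape ($\sigma$, $\nu$) are intrinsically noisy at reference-
cohort sizes (the SD of $\hat\nu$ is ≈ 0.04 at n = 2000), so their
recovery is checked on the mean of four replicate fits rather than a single
draw. Test problem sizes (e.g. 50 000 draws for tail-fraction checks, 200
replications for bootstrap coverage at n = 500) were chosen so that
Monte-Carlo error is several times smaller than the tolerance being
asserted while the whole suite stays interactive.

## Known limitations

* $\sigma$ and $\nu$ are modelled as age-constant by default; cohorts with
  genuinely age-varying dispersion need `edf_sigma`/`edf_nu` raised, and
  correspondingly more data.
* The BCCG family has no kurtosis parameter; heavy-tailed cohorts would
  need a four-parameter extension, which is out of scope.
* The generator draws no covariates beyond age and sex; BMI, renal
  function and assay batch effects — all known to move sNfL — are not
  represented, so real-cohort fits should expect somewhat wider residual
  spread than the synthetic benchmark.
* The closed-form cut-off inherits the log-normal residual assumption of
  the linear model; when skewness is material ($\nu$ far from 0) the BCCG
  centiles are the better reference and the two routes will disagree in
  the tails.
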