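---
title: "Measuring and decomposing wealth-related inequality in a binary health outcome"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring and decomposing wealth-related inequality in a binary health outcome}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(svyineq)
```

## The problem

Health surveys routinely show that adverse outcomes — here, anaemia in adult
men, defined as haemoglobin below 13.0 g/dL — are unevenly distributed across
the socio-economic spectrum. `svyineq` quantifies that unevenness with the
**concentration index** and attributes it to observable covariates with the
**Wagstaff decomposition**, using the machinery a health-economics analyst
would apply to Demographic and Health Survey (DHS)-style microdata: an
asset-based wealth score, population-weighted quintiles, weighted fractional
ranks, and survey-weighted regression.

## The model

### Wealth ranking

Households are scored on the first principal component of their standardized
asset indicators (`asset_scores()`), oriented so that more assets means a
higher score. The household score is replicated to each member, and each
individual receives a **weighted fractional rank**
$R_i = \sum_{j<i} \hat w_j + \hat w_i/2$ (after sorting by score, with
weights normalized to sum to one). Ties get the weighted-average rank of
their tie group — the Lerman–Yitzhaki convention — which makes everything
downstream invariant to the ordering of tied records. The weighted mean of
the ranks is exactly 1/2, a property the test suite asserts for arbitrary
weights. Quintiles cut the same ranks at 0.2/0.4/0.6/0.8; an individual
whose weight straddles a cut point takes the quintile of its
cumulative-weight midpoint, the one place where exact 20% shares can break.

### Concentration index and curve

For outcome $y$ with weighted mean $\mu > 0$,

$$C = \frac{2}{\mu}\,\mathrm{cov}_w(y_i, R_i),$$

with the covariance in its population (normalized-weight) form — no
$n/(n-1)$ correction, because the definitional formula carries none and the
decomposition identity below requires the uncorrected form. $C < 0$ means
the outcome is concentrated among the poor, and the concentration curve
(cumulative outcome share vs cumulative population share, poorest first)
then lies above the diagonal. For a binary outcome the attainable range is
$[\mu - 1,\, 1 - \mu]$; `svyineq` reports the plain index, with no
binary-outcome (Wagstaff/Erreygers) normalization, matching the common
reporting convention for this application. Ranking uses the continuous
wealth score, not the quintile, because the finer ranking is what the score
exists for; quintiles are kept as a reporting category.

### Wagstaff decomposition

Fitting the linear probability model
$y_i = \alpha + \sum_k \beta_k x_{ki} + \varepsilon_i$ by weighted OLS gives
the exact identity

$$C = \sum_k \underbrace{\frac{\beta_k \bar x_k}{\mu}}_{\eta_k} C_k
      + \frac{GC_\varepsilon}{\mu},$$

where $C_k$ is the concentration index of regressor $k$ against the *same*
ranks and weights, $\eta_k$ its elasticity, and the last term the
generalized concentration index of the residual. OLS — not logit marginal
effects — is used because the additivity is exact only under a linear fit.
`wagstaff()` computes every column of the usual decomposition table
(coefficient, elasticity, $C_k$, absolute contribution $\eta_k C_k$,
percentage contribution), stores the residual two ways (as
$C - \sum_k \eta_k C_k$ and as $(2/\mu)\,\mathrm{cov}_w(\varepsilon, R)$,
which agree to float precision), and `explained + residual = actual` holds
to $10^{-10}$ on arbitrary inputs — the central invariant of the package.

Percentage contributions are reported against the **explained** (calculated)
index by default, under which they sum to 100; published tables of this kind
are consistent with that denominator. `denominator = "actual"` switches to
the total index.

## The synthetic-data generator

Real DHS microdata are access-restricted, so `simulate_survey()` generates
a survey with the same anatomy and *known* ground truth:

* **Design.** Two-stage sampling: 560 clusters × 50 households by default,
  with 1 + Poisson(0.8) eligible men per household (≈ 50,000 individuals,
  the scale of the motivating analysis). Region and urban/rural residence
  are cluster-level; caste and religion are household-level; the remaining
  covariates are individual-level.
* **Covariate marginals** default to the published national sample profile
  (e.g. 13.1% with no education, 19.7% underweight, 62.7% rural).
* **Wealth.** A latent household affluence (cluster share 0.45) drives ten
  binary asset indicators with loadings 0.9–1.8 and intercepts from +1.5
  (common assets) to −1.5 (rare ones); the generator's wealth score is the
  first principal component of those assets, which correlates ≈ 0.85 with
  the latent affluence (the latent variable is emitted in a
  `latent_affluence` column so tests can check exactly this).
* **Outcome.** Anaemia is Bernoulli with logit = intercept + covariate
  effects + `wealth_effect` × standardized wealth score. Effect sizes use
  the published adjusted odds ratios (e.g. 1.51 for underweight, 1.40 for
  the East region, 0.71 for higher education). The intercept (−0.90) and
  `wealth_effect` (−0.28) were calibrated once, on a 200,000-person
  reference draw, so that the defaults reproduce the two national anchors:
  prevalence ≈ 23.3% and concentration index ≈ −0.12. They are fixed
  defaults, not fitting knobs.
* **Haemoglobin** is drawn *conditionally on* the simulated binary outcome
  from truncated normals on either side of 13.0 g/dL (mean 11.5 below, 14.8
  above). This guarantees that thresholding haemoglobin at 13.0 reproduces
  the binary outcome exactly, so the classifier can be tested without
  tolerance.
* **Weights** are household-level log-normal (σ = 0.25), normalized to mean
  1; dispersion 0 gives a self-weighting sample. All randomness flows from
  one seed, and the generator restores the caller's RNG state.

What the generator does **not** emulate: non-response (the survey's 92%
male response rate is ignored), informative weighting (weights are
independent noise), within-household outcome correlation beyond shared
wealth, state-level geography beyond the six-region label, and any
covariate–wealth correlation under the default configuration (covariates
are drawn independently of affluence). That last point matters when reading
test output: in synthetic data nearly the whole explained index flows
through the wealth quintiles, whereas in real data education, BMI and
region correlate with wealth and pick up sizeable shares. Passing tests
therefore validate the estimators' arithmetic and recovery properties, not
the sociological structure of any real population.

## Anaemia grading

`classify_anaemia()` grades severity as none (≥ 13.0), mild (12.0–12.9),
moderate (9.0–11.9), severe (< 9.0 g/dL). Two boundary choices are
documented rather than silent: 13.0 g/dL exactly is non-anaemic (the verbal
definitions of "anaemic" and "not anaemic" leave the boundary ambiguous),
and the gap between "below 8.9" and "9.0–11.9" is closed at 9.0, so
[8.9, 9.0) counts as severe. Values outside 2–25 g/dL warn.

## Association screens

* Chi-square tests use weighted counts rescaled to the unweighted total by
  default (p-values are approximate under clustering; `weighted_test =
  FALSE` reverts to raw counts). No design-adjusted (Rao–Scott) variant is
  offered.
* The Cochran–Armitage trend test uses unweighted counts and scores 1..k,
  the standard form; its Z statistic is invariant to affine score changes
  and antisymmetric under level reversal.
* The weighted logistic fit treats weights as analytic weights normalized
  to mean 1 (so rescaling all weights changes nothing) and reports
  information-matrix standard errors with dispersion fixed at 1; a
  cluster-robust option (`robust = TRUE, cluster =`) is available but off
  by default, matching the plain Wald intervals of the motivating analysis.
  Coefficients with absolute value above 10 on the dummy scale are treated
  as separation and reported as an error naming the term.
* VIFs are computed as $1/(1 - R_j^2)$ with perfectly collinear columns
  reported as infinite and flagged, not as a crash.

## Numerical choices and degenerate inputs

* A zero weighted outcome mean is an error everywhere an index is divided
  by $\mu$; constant outcomes give $C = 0$ (overall) or a documented skip
  (per-stratum).
* Stratified indices recompute fractional ranks within each stratum; the
  pooled index is deliberately *not* the average of stratum indices, and a
  test pins that non-additivity on a constructed example.
* Rank-deficient design matrices are refused with the collinear columns
  named; zero-variance asset columns are dropped with a warning, and an
  all-constant asset matrix is an error.
* Regressors with weighted mean zero have undefined $C_k$ (reported `NA`)
  but a well-defined contribution $2\beta_k\mathrm{cov}_w(x_k,R)/\mu$,
  which is what enters the identity.

## Problem sizes used in validation

The test suite exercises: oracle equivalence of the index on 200 random
instances (n ≤ 20) against a definitional brute-force computation at
$10^{-10}$; the decomposition identity on 100 random instances; parameter
recovery on 20 replicate surveys of ≈ 50,000 individuals (all replicates
pro-poor, each within 3 Monte-Carlo SDs of the planted large-sample index;
≥ 90% of logistic terms within 3 SEs of the planted coefficients); null
calibration at ≈ 100,000 individuals (|C| < 0.01) with the trend test's
size checked over 1,000 small-sample replicates; and the re-derived
arithmetic of the published decomposition table (products of rounded cells
to 1.5 × 10⁻³, percentage sums to half a printed unit per summand). These
sizes keep the full suite to a few minutes on one core while leaving the
Monte-Carlo bands comfortably wider than the simulation error.

## A short session

```{r example, eval = FALSE}
cfg <- sim_config(seed = 1)
d <- simulate_survey(cfg)

ci <- concindex(d$anaemic, scores = d$wealth_score, weights = d$weight)
print(ci)
plot(ci)  # concentration curve above the diagonal

d$wealth_quintile <- factor(d$wealth_quintile)
fit <- wagstaff(anaemic ~ education + bmi + residence + region +
                  wealth_quintile,
                data = d, scores = d$wealth_score, weights = d$weight)
summary(fit)
```

## Known limitations

No standard errors or dominance tests are provided for the concentration
index or for decomposition contributions; the index is the plain
(unnormalized) version; the decomposition is the single-equation Wagstaff
form, not an Oaxaca-style between-group split; and complete-case deletion
is the only missing-data policy in the pipeline, with per-run row
accounting in the log.
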