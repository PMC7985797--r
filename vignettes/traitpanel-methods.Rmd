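---
title: "Methods: text-derived geo-personality and interval-censored mortality panels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: text-derived geo-personality and interval-censored mortality panels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Small-area mortality surveillance suppresses low counts: a county-year with
fewer than 10 deaths is released not as a number but as the knowledge that
the count lies in [0, 9]. At the same time, aggregate psychological
characteristics of a county — its *geo-personality* — can be estimated by
scoring the text its residents post online against a psycholinguistic
dictionary. `traitpanel` implements the full analysis chain that connects
the two: score geo-tagged short texts into county-year Big Five percentile
scores, build superordinate personality components as controls, and regress
the interval-censored death counts on the trait percentiles with a panel
random-effects interval model, including an instrumental-variable control
function for the endogeneity of the trait scores.

Because the real inputs (suppressed vital statistics, a proprietary
dictionary, third-party covariate panels) cannot ship with a package, a
synthetic-data generator with known ground truth stands in for them. The
generator is first-class, tested code: every pipeline stage is exercised
end to end against planted parameters.

## Lexicon trait scoring

A dictionary maps lowercase patterns (exact tokens or `prefix*` wildcards)
to categories. A county-year document — the concatenation of all retained
tweets assigned to that county and calendar year — is scored as category
proportions $p_c = (\text{tokens matching } c)/(\text{total tokens})$, and a
trait's raw score is the affine combination
$r_t = \alpha_t + \sum_c w_{tc}\, p_c$ given by a configurable weight table.
Raw scores are converted to percentiles within year,
$100\,(\bar{\text{rank}} - 0.5)/n$ with average ranks for ties. This
convention is strictly monotone in the raw score, invariant under monotone
transformations, and has mean exactly 50 in every year; it was chosen
because no single percentile convention is canonical, and it is tested as
stated.

Decisions on deliberately open points:

* **Filtering.** At most one tweet per (author, normalized text) pair —
  earliest timestamp kept — and a minimum of three tokens.
* **Tokenization.** Lowercase, apostrophes stripped (`don't` → `dont`),
  split on non-alphanumeric runs. Stop-word removal and a rule-based suffix
  stripper exist behind flags but are **off by default**: wildcard patterns
  subsume most inflection, and dictionary matching conventionally consumes
  raw tokens. Word counts (the language control variable) are always taken
  before stop-word removal.
* **Geo-assignment.** Ray-casting point-in-polygon with boundary points
  counted inside, ties resolved in favor of the first feature in file
  order. Year attribution uses the tweet timestamp's calendar year in UTC.

## Superordinate components

The two higher-order personality dimensions — stability (alpha) over
neuroticism, conscientiousness and agreeableness, and plasticity (beta)
over extraversion and openness — are built from facet matrices by
correlation-matrix PCA. The battery is screened first: inter-item
correlations against a 0.3 threshold, the Kaiser–Meyer–Olkin measure of
sampling adequacy

$$\mathrm{KMO} = \frac{\sum_{i\neq j} r_{ij}^2}{\sum_{i\neq j} r_{ij}^2 +
\sum_{i\neq j} p_{ij}^2},$$

with $p_{ij}$ the anti-image partial correlations, and Cronbach's
$\alpha$. Components with eigenvalue strictly greater than 1 are retained
(ties at exactly 1 excluded; a $10^{-8}$ tolerance keeps floating-point
noise on an exactly spherical battery from flipping the rule). Scores are
standardized data projected on the retained eigenvectors, so on the fitting
sample each score has zero mean and variance equal to its eigenvalue. Note
that for independent columns KMO settles at 0.5 — the floor of the adequacy
scale — because simple and partial sample correlations are then noise of
the same magnitude; values near 0 require partial correlations that exceed
the marginal ones.

## The interval model

The outcome model is a Gaussian panel with county random effects,

$$y^*_{it} = x_{it}'\beta + u_i + e_{it}, \qquad
u_i \sim N(0, \sigma_u^2), \quad e_{it} \sim N(0, \sigma_e^2),$$

observed only through bounds $y_{1,it} \le y^*_{it} \le y_{2,it}$: exact
observations contribute normal densities and suppressed ones the CDF
difference over the closed interval $[0, 9]$ (a convention; the latent
outcome is continuous, so $[0,9]$ versus $[0,10)$ is immaterial). The
county effect is integrated out by Gauss–Hermite quadrature after the
change of variables $u = \sqrt2\,\sigma_u x$; the default order is $K = 12$
(configurable) and the recommended stability check is doubling $K$, which
should move the log-likelihood by less than $10^{-4}$.

Numerical choices:

* Optimization is BFGS over $(\beta, \log\sigma_u, \log\sigma_e)$ — the log
  parameterization keeps both SDs positive by construction — with an
  **analytic gradient** (verified against central differences in the test
  suite) and one polish restart to refresh the curvature approximation.
  The start is OLS on interval midpoints with the residual SD split evenly
  between the two variance components.
* Interval probabilities are floored at $10^{-300}$; inside that clamped
  region the gradient contribution is set to zero, matching the flattened
  objective, which keeps early iterations far from the optimum stable.
* With no censoring and $\sigma_u$ fixed at 0 the likelihood is maximized
  in closed form (OLS with the ML variance), so the model collapse to
  ordinary regression is exact rather than iterative.
* The convergence flag uses the relative gradient criterion
  $\max_i |g_i \max(|\theta_i|, 1)| / \max(|\ell|, 1) < 10^{-6}$.
* Standard errors come from the inverse numerical Hessian of the analytic
  gradient; `cluster_bootstrap()` resamples counties with replacement
  (whole blocks, resampled counties treated as distinct clusters), refits
  from the full-sample optimum, and reports the SD of the estimates,
  dropping non-convergent refits with a warning above 10%.
* Year dummies are coded against the earliest year. The robustness check
  `fit_fe_within()` is county-demeaned OLS on the exactly observed
  subsample, dropping within-invariant columns.

## Control function and diagnostics

Trait percentiles are endogenous if an omitted variable moves both the
language signal and mortality. Each trait is instrumented separately
(matching the one-diagnostic-row-per-trait reporting convention) by
linguistic-style variables screened three ways: $|r(Z, \text{trait})| \ge
0.3$, $|r(Z, \text{outcome})| \le 0.1$, and a significant first-stage
coefficient ($\alpha = 0.05$); the 0.3/0.1 cutoffs are the conventional
moderate/weak effect-size labels and are exposed as arguments. The first
stage is pooled OLS of the trait on instruments and second-stage
observables with county-cluster-robust standard errors — residual
inclusion, not first-stage efficiency, is what the control function needs —
and the second stage refits the interval model with the first-stage
residuals appended, listwise-dropping rows lacking a residual.

The diagnostic battery reports, per trait: the Anderson
canonical-correlation underidentification LM test, the Cragg–Donald
minimum-eigenvalue statistic against the Stock–Yogo 5% critical value (10%
maximal 2SLS size, one endogenous regressor, 1–10 instruments; the
comparison is reported, never auto-failed), the Sargan $n R^2$
overidentification test, and the Davidson–MacKinnon artificial-regression
endogeneity F-test. Classical IV tests presume an observed outcome, so
diagnostics run on the exactly observed rows (midpoint coding available for
interval rows). On linear, exactly observed data the control-function point
estimates coincide with two-stage least squares to machine precision; the
suite uses that identity, plus null-size and power simulations of each
test, as the correctness oracles.

## The synthetic generator as study design

The generator draws, per year: trait signal, an omitted confounder,
covariates, idiosyncratic errors and instrument noise, in a documented
order so seeds are stable across refactors. Latent traits are
percentile-ranked within year; the outcome is the continuous latent
$y^*$ above, reported as `round(max(0, y*))` and suppressed below the
threshold. Design choices worth stating explicitly:

* **Default regime.** 3000 counties × 3 years, threshold 10, trait
  coefficients of the magnitude the fitted models report (0.05–0.31 deaths
  per percentile point), $\sigma_u = 2$, $\sigma_e = 3$, and an intercept
  of −40.8 calibrated once by Monte Carlo so that ≈77% of county-years are
  suppressed — the coverage actually observed in national opioid-mortality
  surveillance. In this regime most suppressed county-years have latent
  means far below zero, so the Gaussian interval likelihood evaluated on
  $[0,9]$ is *deliberately misspecified*, exactly as it is on real
  count data; fitted coefficients attenuate accordingly. This regime is
  used for regime-level checks (suppression share, AIC ordering,
  diagnostics), not for parameter-recovery claims.
* **Recovery regime.** Parameter-recovery experiments keep the specified
  conditions (500 counties × 3 years, ≈70% suppressed, true
  $\beta_{\text{neuroticism}} = 0.25$, $\sigma_u = 2$, $\sigma_e = 3$) but
  position the outcome scale (intercept −3.5, threshold 44) so the zero
  floor of reported counts binds for well under 1% of records. Only there
  does the generator match the fitted model's assumptions, which is what
  makes recovery well-posed; rounding to integer counts is then the only
  count-like distortion.
* **Variance components are averaged.** In a heavily censored three-wave
  panel, $\hat\sigma_u$ from a single 500-county draw has a sampling SD
  around 0.25 — an uncensored-data oracle recovers 2.0 on the same seeds
  where the censored MLE legitimately prefers 1.6 or 2.5. Point checks on
  $\sigma_u$, $\sigma_e$ therefore average six replicate panels, which
  tests consistency (bias) rather than one draw's luck.
* **Endogeneity.** The confounder loads on the focal trait (neuroticism)
  and the outcome; loading it on all five latent traits would make the
  percentiles nearly collinear and diffuse the bias into
  uninterpretability. Instruments are built from the *pre-confounder*
  trait signal with one extra instrument per trait beyond the minimum, so
  they stay valid under confounding and the Sargan test keeps at least one
  degree of freedom.
* **Corpus.** Token emission is a mixture of five category vocabularies
  and neutral filler words, with the mapped category's probability affine
  in the county's trait percentile (base 0.02, slope 0.06 from percentile
  0 to 100); tweet lengths vary uniformly within ±3 tokens of the
  configured mean. Coordinates are uniform in the county square; authors
  are unique unless a duplicate-injection rate is set to exercise
  deduplication.

What the generator does **not** emulate: the heavy right skew and
integer-valuedness of real death counts (beyond rounding), population-size
heterogeneity across counties, temporal autocorrelation of traits, and any
realistic language structure. Passing tests demonstrate that the pipeline
recovers what it plants under its own assumptions — not that those
assumptions hold for real surveillance data.

## Problem sizes and tolerances

The test suite runs quadrature-versus-brute-force comparisons at
$10^{-6}$ (20 random parameter draws against 20,001-point trapezoid
integration, quadrature order 64 because draws with several exact records
concentrate the integrand), algebraic identities (control function ≡ 2SLS;
Cragg–Donald ≡ first-stage F when just identified) at $10^{-8}$, closed
psychometric forms exactly via empirical-moment data, and stochastic
checks at conventional sizes: Sargan null size within [3%, 7%] over 1000
simulations at $n = 500$; Anderson and Davidson–MacKinnon null uniformity
by Kolmogorov–Smirnov over 500 simulations; control-function bias
correction winning in at least 80% of 50 seeds at 250 counties; end-to-end
Spearman recovery of at least 0.8 at 2000 tweets per county across 60
counties. These sizes are the package's chosen experimental design and are
fixed in code.

## Limitations

The estimator is a Gaussian interval likelihood, not a count model; no
interval-censored count estimator is provided. Quadrature is non-adaptive;
for data with many exact records per county and small $\sigma_e/\sigma_u$,
raise `K` (the node-doubling check will show when it matters). Weak
instruments are reported, not remedied: no weak-instrument-robust
intervals, no LIML, no heteroskedasticity-robust overidentification test.
The shipped lexicon and weight table are small synthetic fixtures — the
file formats accept real dictionaries and weight tables, which is the
intended use.
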