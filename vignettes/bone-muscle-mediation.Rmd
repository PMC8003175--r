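---
title: "Methods: mediated multilevel models of muscle strength and bone development"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mediated multilevel models of muscle strength and bone development}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bonemed)
```

## The scientific question and the model

In growing children, bone strength (measured here as quantitative-ultrasound
speed of sound, SOS, in m/s at the radius and tibia) is thought to respond
primarily to muscle force, with maturity, body size, physical activity and
diet acting substantially *through* muscle rather than on bone directly.
`bonemed` estimates that claim as a recursive two-equation system on
repeated annual measurements nested in participants:

$$Y_{it} = \beta_0 + \beta_1 M_{it} + \Theta' Z_{it} + \gamma_i + \epsilon_{it}$$
$$M_{it} = \Omega' W_{it} + \delta_i + \mu_{it}$$

where $Y$ is a bone SOS z-score, $M$ the site-matched muscle-strength
z-score (grip strength for the radius, knee-extension peak torque for the
tibia), $Z$ = {NTX, PAQ-C, maturity offset, BMI} and $W$ = {maturity offset,
BMI, bone age, WAeq, energy intake}. $\gamma_i, \delta_i$ are normal random
participant effects (level 2), independent of the covariates;
$\epsilon_{it}, \mu_{it}$ are level-1 residuals. Physical activity enters
through two different instruments (PAQ-C in the bone equation, the
Godin-Shephard WAeq score in the muscle equation) because one column cannot
appear in both equations of a mediation system and the two scores capture
different facets of activity.

**Assumptions.** Gaussian random effects and residuals; random effects
independent of covariates; cross-equation errors independent, which makes
the system recursive — the bone equation conditions on the *observed*
mediator, the joint likelihood factorizes, and the two equations can be
fitted separately, each on its own complete cases. Missingness is treated
as ignorable given the design (equation-wise complete-case deletion); no
imputation, no outlier rejection, no multiple-testing correction.

## Estimation

`fit_random_intercept()` maximizes the marginal Gaussian likelihood by
profiling. With per-group covariance $\sigma^2(I + \lambda J)$,
$\lambda = \sigma^2_{\gamma}/\sigma^2_{\epsilon}$, the GLS coefficients and
$\sigma^2$ are closed-form at fixed $\lambda$ via the compound-symmetry
inverse $I - \tfrac{\lambda}{1+n\lambda}J$, so the search is a deterministic
1-D optimization over $\log\lambda$ on $[10^{-8}, 10^{8}]$ (argument
tolerance $10^{-10}$), with the boundary $\lambda = 0$ always evaluated. On
numerical ties the boundary wins: when every participant is observed once
the profile is flat in $\lambda$ (only $\sigma^2(1+\lambda)$ is identified)
and parsimony pins $\lambda = 0$, reproducing ordinary least squares.
Inputs are internally re-sorted into a canonical value-based order so the
fit is bitwise invariant to row permutation.

ML is the default, matching the large-sample z/star inference convention of
generalized-SEM software; REML is available via `reml = TRUE`.
Coefficient covariance is the inverse GLS information at the optimum — no
small-sample (Kenward–Roger-type) correction, and no robust sandwich:
plain model-based standard errors. Groups with a single observation are
retained. Tests cross-check the engine against `lme4` (ML and REML) and an
independent dense grid-plus-polish maximizer of the explicit marginal
likelihood.

The pooled two-site model stacks radial and tibial rows (two per session,
outcome-matched mediator, shared coefficients) and adds a session-level
random intercept nested in the participant intercept
(`fit_nested_intercepts()`, a second Woodbury step and a 2-D deterministic
search with all boundary cases evaluated). The shared session intercept
induces an exchangeable cross-outcome correlation within a session — a
one-parameter stand-in for an unstructured cross-outcome residual
covariance; the realized within-participant cross-outcome residual
correlation is additionally reported descriptively
(`residual_cross_correlation`). A full unstructured joint ML fit of both
outcomes is deliberately out of scope.

## Effects and inference

For each muscle-equation modulator $w$: indirect effect
$\Omega_w \hat\beta_1$ with first-order delta (Sobel) SE
$\sqrt{\hat\beta_1^2 v_{\Omega_w} + \Omega_w^2 v_{\beta_1}}$; total effect
$\Theta_w + \Omega_w \hat\beta_1$ with variance
$v_{\Theta_w} + se_{ind}^2 + 2\Omega_w\,\mathrm{cov}(\hat\Theta_w, \hat\beta_1)$,
the covariance taken from the bone-equation coefficient covariance and
cross-equation covariances set to zero (the equations are fitted on
overlapping but distinct complete-case sets; no joint covariance exists).
Additivity (total = direct + indirect) and the product rule are exact
identities of the decomposition and are asserted to $10^{-12}$ in tests.
Stars are always derived from the computed p-values
(p < 0.05 / 0.01 / 0.001). A percentile-free parametric bootstrap of the
indirect effects (`bootstrap_indirect()`, design held fixed, responses
resimulated from the fitted components) is available as `se = "bootstrap"`.

`classify_mediation()` labels a modulator *full* (significant indirect, no
significant direct path), *partial* (both significant) or *none*
(indirect not significant), at $\alpha = 0.05$.

**Small-sample behaviour of the Sobel SE.** The first-order formula omits
the $v_\Omega v_\beta$ term, and model-based ML standard errors shrink
roughly with $(N-p)/N$; both effects are material on very small fixtures.
On the 8-participant, 2-session test fixture the delta SEs sit up to about
16% below parametric-bootstrap SDs for the weakly identified paths, while
the identical comparison at 100 participants agrees within 15% on every
path (both computed in the test suite). Sobel inference from fits of a few
dozen observations should not be trusted at face value; at the package's
intended cohort scale (hundreds of observations) the approximation is
accurate.

## Stratum comparison

`chow_test()` implements coefficient-equality testing between independently
fitted strata as a Wald chi-square on the coefficient-difference vector,
with variance the sum of the stratum covariances — the standard
generalization of the classical pooled-F Chow test, which has no single
residual sum of squares in a mixed model. The default tested set is the
bone equation without the intercept; any subset (e.g. "all but BMI") is an
argument. Both strata must be fitted on the *whole-cohort* standardization
scale: re-standardizing within stratum would change the estimand and
invalidate the comparison. Under equal generating coefficients its
realized size at $\alpha = 0.05$ is checked over 500 replicates in the
acceptance suite.

## Preprocessing choices

* **Exclusion cascade** (`apply_exclusions()`): flags are removed in the
  fixed order diabetes, fracture, undetectable SOS, missed second visit; a
  multiply-flagged record counts once, under the first applicable reason,
  so the log is deterministic and balances exactly.
* **Standardization** (`zstandardize()`): population SD (divisor $n$), so
  $\{-1, +1\}$ is a fixed point and the operation is idempotent; the choice
  is a pure rescaling and immaterial to inference. One pooled scaling over
  all post-exclusion observations — computed after exclusions because only
  the analysis rows enter any model — reused by stratum fits (see above).
  The affine parameters are attached for exact back-transformation.
* **Variance decomposition** (`variance_decomposition()`): between-SD =
  population SD of participant means; within-SD = population SD over all
  observations of deviations from the own-participant mean (singletons
  contribute zero deviations). Population divisors in both components keep
  the decomposition consistent with the z-scoring.
* **Derivations**: NTX is the creatinine ratio (nmol BCE / mmol creatinine);
  WAeq is the MET-weighted weekly activity frequency sum with configurable
  weights defaulting to the Godin convention 3/5/9 (mild/moderate/strenuous).

## The synthetic cohort generator

`generate_cohort()` emulates a mixed-longitudinal pediatric cohort: 180
participants (92 boys), of whom 36/53/72/19 attend 1/2/3/4 annual sessions
(434 observations; the exclusion flags 6+8+11+3 leave 406 analysis rows),
spring and fall measurement series over 2010–2013, grip strength absent in
the fall-2010 season, NTX missing at a per-session Bernoulli rate of
29/434. All of these are `cohort_config()` knobs; the defaults *are* the
study conditions and are not tuned.

Generation happens on the standardized scale through a shared-factor
construction. Each exogenous variable is a participant-level baseline plus
session deviations; maturity offset (and chronological age) additionally
advance one year per annual session, with the within-participant jitter
chosen so the total within-SD matches its target. Bone age loads 0.8 on
standardized maturity offset (the only built-in covariate cross-correlation;
a config knob), all other covariates are independent given maturity — the
minimal structure that keeps the design well-conditioned while making
mediation non-trivial. Muscle strength is then generated *from the muscle
equation* and bone SOS *from the bone equation*, so the generator's truth is
exactly the estimand; the default structural coefficients are the total
cohort point estimates the package's documentation quotes, and residual
variance components are solved so each variable's realized moments hit its
calibration targets. Variables are finally mapped affinely to natural units
(means and within/between SDs of the default calibration table).

Two non-obvious calibration details:

* **Estimator inversion.** The population-divisor decomposition is biased
  for the latent SDs (e.g. the within estimator has expectation
  $\sigma_w^2 (N-G)/N$). The generator therefore solves the latent variances
  so that the *expected realized decomposition* — computed per variable on
  its own availability mask, including the exact contribution of the
  deterministic trend and of trend recentring after random exclusions —
  equals the configured targets. Without this, realized within-SDs would sit
  ~20% below target and the calibration tests could not pass honestly.
* **Mask recentring.** Calendar-tied grip missingness removes predominantly
  early sessions, which would otherwise shift the observed grip mean via the
  growth trend; each variable is recentred by its mask's mean trend
  deviation (a constant, absorbed by equation intercepts).

Bone (and muscle) residuals at the two sites share half of their
participant-level and a quarter of their session-level variance
(`cross_site_share`): the two sites of one skeleton plausibly share
unmeasured factors, and this is exactly the dependence the pooled model's
shared intercepts represent.

**What the generator does not emulate** — and hence what passing tests do
not certify about real data: seasonal bone variation (season is a design
label only), non-Gaussian tails and floor/ceiling effects of questionnaire
scores (PAQ-C is treated as an arbitrary-scale score; its calibrated scale,
mean 0.1 and SD 0.3, cannot be positive-supported, so high-CV markers may
cross zero in the synthetic tail), informative missingness, measurement
error correlated with maturity, secular drift between measurement series,
and any covariate cross-correlations beyond the single maturity-bone-age
loading. Parameter-recovery results certify the estimation pipeline under
the model's own assumptions, not robustness to their violation.

## Numerical and reporting choices

* Profile-search bracket $[10^{-8}, 10^{8}]$ on the variance ratio,
  tolerance $10^{-10}$; 2-D searches restart from all boundary solutions;
  degenerate inputs fail loudly (rank-deficient designs name the collinear
  columns; constant columns are a degenerate-scale error; non-positive SEs
  are domain errors).
* Report tables round half-away-from-zero to 3 decimals, cells formatted as
  `estimate stars(se)`, blank where no path exists.
* `run_pipeline()` writes every artifact with an md5 in `manifest.json`;
  identical config and seed reproduce byte-identical numeric outputs.

## Test-suite problem sizes

Deliberate choices balancing statistical resolution against a desk-scale
run: moment calibration over 50 replicate seeds with a Bonferroni-style
3.2-MC-SE per-comparison bound across the 36 simultaneous statistics (a
2-SE bound per statistic would false-alarm on ~84% of runs for a perfectly
calibrated generator); parameter recovery over 1000 replicates at the
180-participant design (95% CI coverage within [0.93, 0.97] per path,
|bias| < 0.02); Chow size over 500 replicates; Sobel-vs-bootstrap with 500
refits. The full suite runs in a few minutes on one CPU.

## Known limitations

One random intercept per level (no random slopes, no growth-curve
modelling); exchangeable rather than unstructured cross-outcome covariance
in the pooled fit; complete-case estimation; Sobel SEs are first-order (see
above) — the parametric bootstrap flag is the alternative at small n; no
causal sensitivity analysis for confounding of the mediator; the Chow test
compares exactly two strata.
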