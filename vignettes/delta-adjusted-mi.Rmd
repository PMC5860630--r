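---
title: "Delta-adjusted multiple imputation for MNAR sensitivity analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Delta-adjusted multiple imputation for MNAR sensitivity analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(deltami)
```

## The problem

Population surveys that test for a stigmatised condition — the motivating
case is HIV serostatus in a large tuberculosis/HIV prevalence survey —
routinely lose a third of their outcome measurements to refusal, and the
refusers are unlikely to be a random slice of the population: people who
already know or suspect their status refuse differently from people who have
never tested.  Analyses that assume the data are missing at random (MAR:
missingness independent of the unobserved value given the observed data) may
then be biased, and the MAR assumption itself is untestable from the observed
data.  What *can* be done is a structured sensitivity analysis: impute the
missing values under a family of missing-not-at-random (MNAR) mechanisms
indexed by an interpretable sensitivity parameter, and trace how the
inference moves.

`deltami` implements the delta-adjustment version of this programme for a
single incomplete binary variable \(Y\), with fully observed covariates
\(X\), an optional fully observed categorical auxiliary \(Z\) (e.g. 4-level
self-reported HIV status), and a missingness indicator \(R\) (\(R = 1\)
observed).

## The model

The imputation model under MAR is an ordinary logistic regression fitted to
the observed rows:

\[
\mathrm{logit}\,\Pr(Y = 1 \mid X) = \Phi_0 + \Phi_X' X .
\]

Delta adjustment turns this into a pattern-mixture MNAR model by adding a
fixed log-odds offset \(\delta\) to the linear predictor *of the rows being
imputed only*:

\[
\mathrm{logit}\,\Pr(Y = 1 \mid X, R) = \Phi_0 + \Phi_X' X + \delta (1 - R) .
\]

\(\exp(\delta)\) is the odds ratio of \(Y = 1\) comparing refusers to
otherwise-identical testers; \(\delta = 0\) is exactly MAR.  The group-specific
extension lets the departure vary with the auxiliary category:

\[
\mathrm{logit}\,\Pr(Y = 1 \mid X, Z, R) = \Phi_0 + \Phi_X' X + \Phi_Z Z +
\sum_{z} \delta_z\, I\{Z = z\}\,(1 - R),
\]

so, for instance, self-reported negatives (who may include people concealing
a positive status) can be assigned a stronger departure than self-reported
positives (whose missingness is plausibly MAR given their self-report).
Crucially, \(\delta\) enters at *prediction* time only: the model is always
fitted to observed rows under MAR first, so the offsets never contaminate the
fit ([impute_mnar()]).

## Proper imputation and pooling

Each of the \(M\) imputations uses a fresh draw of the model parameters from
the approximate posterior — a multivariate normal centred at the MLE with the
estimated covariance.  This is the standard proper-imputation device for
logistic models; a published analysis would typically delegate it to generic
MI software, which does the same thing.  The draw for imputation \(m\) in
stratum \(s\) comes from an RNG substream keyed on (seed, \(s\), \(m\)), so
increasing \(M\) never perturbs earlier imputations.

Scalar estimands are pooled with Rubin's rules
(`pool_scalar()`): point estimate \(\bar Q\) = mean of the per-imputation
estimates, total variance \(T = \bar W + (1 + 1/M) B\), and degrees of
freedom \((M-1)\{1 + \bar W / ((1+1/M)B)\}^2\).  Whole coefficient vectors
with their covariance matrices are pooled the same way (`pool_glm()`), which
is what the mediation analysis consumes.

Prevalences are pooled on the proportion scale with binomial within-imputation
variance \(p(1-p)/n\); whether the original survey used binomial or
model-based within-variance is not stated anywhere, so binomial is the
default and a logit-scale option exists for prevalences near 0 or 1.
Displayed percentages are rounded half-up to one decimal, matching the
convention of the survey tables this layout mirrors (ordinary banker's
rounding differs on exact halves).

## Separation

A strongly predictive auxiliary is the whole point of the design — and it is
also a numerical hazard, because self-report nearly determines the serological
result (odds ratios in the hundreds), which pushes the MLE toward separation.
Whenever a fit fails to converge, produces a coefficient above 15 in absolute
value, or has a singular information matrix, the package refits with a small
ridge penalty (\(\lambda = 10^{-4} n\) on standardised non-intercept columns)
and records `engine = "penalized"` in the provenance.  The same fallback
serves the descriptive odds-ratio tables and the mediation fits.

## Sensitivity grids, common random numbers, tipping points

`delta_grid_spec()` builds the Cartesian product of per-group
\(\exp(\delta_z)\) ranges; the default grid pairs a strongly-MNAR range
(1.00–5.00, ten values) for the self-reported-negative and refused-to-disclose
groups, MAR (exactly 1) for self-reported positives, and a weak range
(0.75–1.33) for the never-tested group — 500 points in all.

Grid runs reuse one uniform per missing row per imputation across all grid
points (common random numbers).  The uniforms are keyed on (seed, \(m\))
only, and the parameter draws on (seed, stratum, \(m\)) only, so moving a
delta component changes nothing but the imputation probabilities.  Two exact
consequences: the number of imputed positives is non-decreasing
coordinate-wise in each \(\delta_z\) (per imputation, not merely in
expectation), and sensitivity surfaces are smooth enough for contour
plotting.  Whether the original analysis shared uniforms across its grid is
unknown; independent draws remain available (`common_rng = FALSE`) and the
choice is recorded in the provenance.

`tipping_point()` scans a grid for threshold crossings along each delta axis,
holding the other axes fixed, and reports every bracketing pair of adjacent
grid points together with a linear interpolation on the
estimate-versus-\(\log\delta\) scale.  The crossing is deliberately reported
as an interval plus an interpolate, never a bare point: the grid resolution,
not the interpolation rule, is the real precision limit.

## Mediation under MNAR

The mediation component follows the two-regression counterfactual framework
for a binary outcome, binary mediator and categorical exposure: a logistic
outcome model (outcome on exposure, mediator, confounders, optional
exposure–mediator interaction) and a logistic mediator model (mediator on
exposure and confounders).  On the odds-ratio scale, with
\(\eta(a, a^*) = \theta_m + \theta_{am} a + \beta_0 + \beta_a a^* + \beta_c' c\),

\[
\mathrm{OR}^{\mathrm{NDE}} = e^{\theta_a (a - a^*)}
\frac{1 + e^{\eta(a, a^*)}}{1 + e^{\eta(a^*, a^*)}},
\qquad
\mathrm{OR}^{\mathrm{NIE}} =
\frac{\{1 + e^{\beta_0 + \beta_a a^* + \beta_c' c}\}\{1 + e^{\eta(a, a)}\}}
     {\{1 + e^{\beta_0 + \beta_a a + \beta_c' c}\}\{1 + e^{\eta(a, a^*)}\}},
\]

and the total effect factorises exactly as
\(\mathrm{OR}^{\mathrm{TE}} = \mathrm{OR}^{\mathrm{NDE}} \times
\mathrm{OR}^{\mathrm{NIE}}\).  These are rare-outcome approximations; the
package documents them as such and they should be interpreted cautiously if
the outcome is common.  Implementation notes:

* Arbitrary factor codings are handled by evaluating the formulas through
  model-matrix *row differences* rather than by naming coefficients, and all
  `1 + e^x` terms go through a saturating `log1pexp`.
* Standard errors use the multivariate delta method on the stacked
  \((\theta, \beta)\) vector with a block-diagonal covariance (the models are
  fitted separately, so the cross block is zero).  Gradients are central
  differences with relative step \(10^{-6}\); they agree with hand-derived
  analytic gradients to six significant figures on the no-confounder case,
  and with a nonparametric bootstrap to well within 15% at \(n = 2000\).
* "Average" effects are weighted means of the per-pattern log odds ratios
  with observed-frequency weights (a weighted geometric mean of ORs).  No
  definition of the averaging is printed in the source material, so this
  choice is explicit here and recorded in the output metadata.
* Under MI the default ordering is *pool first*: fit both models per
  imputation, Rubin-pool coefficients and covariances, then evaluate the
  effect formulas once at the pooled values — the ordering the source
  analysis states.  Computing effects per imputation and pooling the log-ORs
  afterwards is available (`order = "compute_first"`) for comparison; the two
  coincide when the between-imputation variance vanishes and differ only
  mildly otherwise because the effect formulas are smooth.
* Pooled-fit confidence intervals use the normal quantile; a per-coefficient
  Rubin df is not well defined for a nonlinear functional of two pooled
  vectors, and with \(M = 25\) the difference is negligible.

## The synthetic world

No record-level data from the motivating survey are distributable, so the
package ships a generator (`generate_study()`, `default_params()`) whose
defaults *state* a world resembling the survey's margins: 34%/66% men/women;
six age bands; four regions; five education levels; a four-level self-report
auxiliary whose distribution shifts with sex, age and region; about 32%
missingness with refusal ordered non-disclosers > self-reported positives >
never-tested > self-reported negatives; overall target prevalence about 18%
with self-reported positives above 0.9; a low-prevalence binary outcome (TB)
coupled to the target with log-odds \(\ln 3\); and true pattern-mixture
deltas \(\exp(\delta) = (2.5, 1, 2.5, 1)\) for the (negative, positive,
refused, never) groups.  The two intercepts were calibrated once, by exact
enumeration, to hit the stated 18% / 32% margins, and then frozen.

The generator is deliberately parameterised in *pattern-mixture* form: it
draws \(R\) first and then \(Y\) from
\(\mathrm{logit}^{-1}\{\Phi_0 + \Phi_X'X + \Phi_Z Z + \delta_z (1-R)\}\).
The true delta is therefore exact by construction — not an approximation to a
selection model — which is what makes parameter-recovery tests sharp: imputing
with the generating \(\delta_z\) must recover the enumerated truth to Monte
Carlo error, and imputing with \(\delta = 0\) must land below it.  Because
every covariate is discrete, all population quantities (prevalences overall
and by subgroup, the missingness fraction, closed-form natural effects when
the auxiliary coupling is switched off) are computed by exact enumeration
over the 1,920-cell lattice (`enumerate_truth()`), never by nested
simulation.

What the generator does *not* emulate: household/enumeration-area clustering,
survey weights, continuous covariates, multivariate missingness, and the real
survey's joint covariate distribution beyond its margins.  A green test
therefore establishes that the estimators do what their formulas promise in a
world where the assumptions hold exactly — not that the original survey's
published numbers are reproduced, which is impossible without its records.

## Numerical and interface choices

* Missing markers: empty string and `"NA"` accepted on input, `"NA"` written.
* Reference levels: first declared level, overridable through the role map
  (the mediation exposure defaults to "primary" education as referent).
* Rows missing a non-target variable are rejected at load unless
  `drop_incomplete_covariates = TRUE`, which deletes them and reports the
  count — the same univariate-missingness preprocessing the motivating
  analysis applied.
* Delta values are accepted on either the log-odds or the odds-ratio scale
  and stored internally as log-odds.  In by-group mode an auxiliary level
  without a mapped delta is an error unless `default_delta` is set
  explicitly: silent MAR defaults hide misconfiguration.
* Non-PSD covariance matrices (pooling artefacts, degenerate fits) are
  repaired by eigenvalue flooring at zero, with a warning.
* Configs and run metadata are JSON (`write_run_metadata()`); classical Rubin
  degrees of freedom are used throughout (a small-sample correction was
  considered and rejected as out of proportion to \(M = 25\) with \(n\) in
  the tens of thousands).

## Known limitations

Only a single incomplete *binary* variable is supported; delta adjustment
inside chained equations for multivariate missingness is deliberately out of
scope (its theoretical footing is weak).  Clustering is ignored, as in the
motivating analysis.  The natural-effect formulas are rare-outcome
approximations, and their causal reading rests on the usual no-unmeasured-
confounding assumptions, which no amount of missingness sensitivity analysis
can rescue.
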