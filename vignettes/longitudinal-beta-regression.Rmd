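---
title: "Mixed and marginal beta regression for longitudinal bounded scores"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mixed and marginal beta regression for longitudinal bounded scores}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Health-related quality-of-life (HRQL) instruments — utility indices such as
the SF-6D, or 0–100 subscales such as the Stroke Impact Scale mobility
score — produce outcomes that are bounded at both ends of their scale and
typically left-skewed, with variance that shrinks as the mean approaches
the upper bound.  In longitudinal studies the same subject is measured
repeatedly, so observations are correlated within subjects, and subjects
drop out, often in ways related to their health.  A Gaussian linear mixed
model (LMM) ignores the boundedness and the mean–variance coupling; this
package implements the two beta-regression alternatives, side by side with
the LMM baseline, so their conceptual and practical differences can be
studied directly:

* **`betaglmm()`** — a *subject-specific* beta generalized linear mixed
  model: `Y_ij | b_i ~ Beta(mu_ij phi, (1 - mu_ij) phi)` with
  `logit(mu_ij) = x_ij' beta + b_i` and `b_i ~ N(0, tau2)`, fitted by
  maximum likelihood with adaptive Gauss–Hermite quadrature.
* **`betagee()`** — a *population-averaged* marginal model: logit mean,
  working variance `phi mu (1 - mu)`, a working correlation
  (compound symmetry by default) and moment-based generalized estimating
  equations with a sandwich covariance.
* **`lmm_ml()`** — the Gaussian random-intercept LMM by full ML, which is
  also the reference model of the pseudo-R².

Because of the logit link these are *not* two parameterizations of one
model: GLMM coefficients describe within-individual change (holding `b_i`
fixed), and `logit E(Y_ij)` is **not** `x_ij' beta`.  GEE coefficients
describe differences between population means and are attenuated relative
to the subject-specific ones when `tau2 > 0`.  `predict(fit,
level = "population")` on a `betaglmm` fit integrates the inverse logit
over the random-effect distribution by quadrature rather than plugging in
`x'beta`.

## Boundary handling

The beta density excludes 0 and 1, but real score data contain them.  Two
transformations are provided:

* `epsilon_shift(y, epsilon)` moves exact zeros to `epsilon` and exact
  ones to `1 - epsilon`, leaving interior values untouched.  The default
  policy of all fitters is a shift with `epsilon = 0.005`.
* `compress_transform(y, N)` computes `(y (N - 1) + 0.5) / N`, shrinking
  the whole range slightly.  With large samples this pushes one-valued
  observations extremely close to 1 (at `N = 1945`, to 0.9997), which can
  destabilize the likelihood and inflate standard errors, so compression
  is provided mainly for sensitivity analysis.  `N` is taken to be the
  number of analyzed rows (after missingness deletion), since that is the
  sample the likelihood sees.

Large `epsilon` shrinks the data toward 0.5 and biases effects toward
zero; tiny `epsilon` leaves boundary mass so close to the bound that the
likelihood can develop spurious modes.  `sensitivity_sweep()` refits a
model over a grid of `epsilon` values (default 0.002–0.01) and tabulates
the coefficient spread against the standard errors.

Missing rows are deleted row-wise, never subject-wise
(`drop_incomplete()`), with response-missing and covariate-missing rows
counted separately (a row missing both counts as response-missing).

## Estimation choices

**Beta GLMM.**  The marginal likelihood integrates the random intercept
out subject by subject.  Each one-dimensional integral uses Gauss–Hermite
quadrature with 21 nodes by default, *adaptively* recentered at the
subject's posterior mode with a scale from the curvature there; the mode
search is a damped Newton iteration with per-subject backtracking, which
matters when responses sit within machine precision of a boundary and the
posterior is sharply peaked.  Non-adaptive quadrature is available
(`adaptive = FALSE`) but is inaccurate at large `tau2`; the accuracy of
the default is checked in the test suite against brute-force dense-grid
integration (20,001 trapezoid points over ±8 prior SDs) at
`tau2` up to 1.3.

Optimization runs unconstrained over `(beta, log phi, log tau)` (`tau` the
random-intercept SD): a 50-iteration Nelder–Mead warm-up from
cross-sectional starting values, then a box-bounded quasi-Newton stage
(`nlminb`) using the analytic posterior-weighted score, restarted until
the log-likelihood is stationary (a single quasi-Newton run can satisfy
its relative tolerance prematurely when the warm-up point is poorly
scaled; the restart loop removes that failure mode).  `log tau` is bounded
below at −8, so `tau2` estimates of about `1e-7` indicate a boundary fit
(flagged as `tau_boundary`).  Standard errors come from the
observed information, obtained as a central-difference Jacobian of the
analytic gradient at the optimum; `phi` and `tau2` SEs are delta-method
transforms of the `log` scale entries.

**Beta GEE.**  Classic moment-based estimating equations: Fisher-scoring
updates of `beta` alternate with moment re-estimation of the scale
(`sum r^2 / (n - p)` from Pearson residuals) and of the working
correlation (cross-product moments; lag-1 pairs for AR-1; per-pair
averages for unstructured).  Subjects with a single row contribute to
`beta` and the scale but not to the correlation.  Convergence is declared
when `max |delta beta| < 1e-8`.  The sandwich covariance
`A^{-1} M A^{-1}` is the default for inference; the model-based `A^{-1}`
is stored alongside.  Note the GEE scale is a dispersion
(`Var(Y|x) = phi mu (1 - mu)`), a different quantity from the beta-family
precision of the GLMM (`Var = mu(1-mu)/(1+phi)`); the package reports
both, labelled.  With only two occasions the exchangeable and AR-1
structures are identical, which the tests assert.

**LMM.**  `lme4::lmer(REML = FALSE)` supplies the ML fit; the package
recomputes AIC with `p = n_fixed + 2` and BIC with a `log(N_subjects)`
penalty (the number of independent units), and reports Wald normal
p-values — the small-sample df convention for mixed models is not uniquely
defined, so this is documented as an approximation.  ML rather than REML
is used because likelihoods are compared across model families.

**Model comparison.**  `pseudo_r2()` computes
`1 - exp((2/n)(l_0 - l_1))`; the baseline `l_0` used by the fitters and by
`comparison_report()` is a random-intercept-only Gaussian LMM on the same
rows, so that the baseline already absorbs within-subject correlation —
an intercept-only model without the random effect would overstate every
model's improvement.  GEE rows in `comparison_report()` carry `NA` in the
likelihood cells: no full likelihood is specified.
`decile_residual_summary()` ranks observations by the (subject-specific)
linear predictor, splits them into ten groups — ties broken by original
row order after a stable sort, group sizes differing by at most one — and
averages raw residuals `y - mu_hat` per group; raw-scale residuals are
used deliberately, as standardized and deviance residuals for beta
regression have no established mixed-model extension.

**Adjusted marginal means.**  `adjusted_means()` evaluates the linear
predictor at a standardized covariate profile per stratum: factors not in
the stratum are averaged with equal weight over their levels and
continuous covariates fixed at their sample mean (the least-squares-means
convention); an alternative `"observed"` policy averages per-row
predictions on the response scale.  Intervals use the 1.96 normal critical
value on the linear scale and are back-transformed, so they respect
`(0, 1)` and are asymmetric away from 0.5 — and at equal linear-scale SE
they are narrower for strata with means near the bound, reflecting the
mean–variance coupling of bounded scores.

## The synthetic-data generator

The raw cohort and trial data the models were designed for are not
publicly deposited, so `simulate_panel()` generates panels with the same
statistical structure, and every fitting module is tested against it.
Two covariate designs are built in:

* `preset_config("kora_like")` — 1000 subjects × 2 occasions, age
  N(66.2, 4.3²) centered, 50.9% male, a persistent time-varying diabetes
  indicator (prevalence 8.9% at baseline, 16.2% at follow-up), truths
  `phi = 14.45`, `tau2 = 0.3854` and the corresponding logit-scale
  coefficient vector.
* `preset_config("stroke_like")` — 200 subjects × 3 occasions, age
  N(57.2, 12.8²) centered, 54.3% male, 67.5% in rehabilitation phase D,
  truths `phi = 10.80`, `tau2 = 1.2782`.

The preset truths are the published beta-GLMM estimates for the two
motivating studies, so the generator emulates the *fitted* generative
model.  For that reason `boundary_mass` defaults to 0: an absolutely
continuous beta law produces no exact boundary values, and boundary mass
is an explicit option (`boundary_mass = p` censors a fraction `p` of draws
to the nearer boundary) used to exercise the transform pipeline.  Exact
0/1 values that arise from floating-point underflow of the beta sampler
(common when a shape parameter is below 1, as in the stroke-like preset
where high-mean subjects have `(1-mu) phi` near 0.1) are clamped to the
nearest representable interior values — they are artifacts of double
precision, not of the model.

Dropout mechanisms (`apply_missingness()`): `mcar(p)` drops post-baseline
rows independently with probability `p` (default 0.3); `mar(gamma0,
gamma1)` drops the row at occasion `j > 1` with probability
`plogis(gamma0 + gamma1 * y_prev)` where `y_prev` is the subject's most
recent *observed* response.  The defaults `gamma0 = 1.6`, `gamma1 = -3`
give roughly 30% follow-up dropout at scores around 0.8 — matching the
attrition of a typical multi-year cohort follow-up — with sicker subjects
dropping out more.  Baseline rows are never dropped.  Sub-streams for
covariates, random effects, responses, censoring and dropout are seeded
separately, so switching the missingness mechanism never perturbs the
responses.

What the generator does *not* emulate: genuine boundary mass as a separate
inflation process (the models under study treat boundary values as data to
be transformed), serial correlation beyond the shared intercept
(exchangeable dependence is exactly what the fitted models assume),
covariate measurement error, and item-level score construction.  Passing
tests therefore demonstrate correctness of the estimators under their own
assumptions, not robustness to misspecification.

## Missingness behavior

Likelihood-based fits with adaptive-quadrature ML remain valid when data
are missing at random (MAR); the GEE requires the stronger MCAR
assumption.  The test suite verifies this by simulation: under MAR
dropout the beta GLMM fixed effects stay unbiased within Monte-Carlo
error, while the complete-case GEE with *independence* working correlation
shows a clear systematic bias in the time effect (its follow-up sample is
selected toward healthier subjects).  A nuance worth recording: with
*exchangeable* working correlation and only two occasions, the GEE
implicitly conditions on the baseline response much like a paired
analysis, and in this design its MAR bias nearly cancels — consistent with
the general point that MAR-robustness of estimating equations depends on
the working correlation being right, which cannot be relied on in
practice.  Under MCAR both estimators are unbiased.

## Problem sizes used by the test suite

Simulation-based checks are run at desk scale, chosen once: parameter
recovery with 60 replicates of 300 subjects × 2 occasions for the beta
GLMM and LMM and 60 replicates of 500 subjects for the GEE (against the
population-averaged estimand computed from a single 30,000-subject
panel); the MAR study with 60 replicates (MCAR arm: 40) of 400 subjects;
sandwich coverage with 500 replicates of 500 subjects.  All recovery
checks use 3 Monte-Carlo standard errors of the replicate mean as their
acceptance band, so the band widens honestly with fewer replicates.

## Known limitations

* Only a random intercept is supported — no random slopes, and no
  covariate-dependent precision; with two or three occasions per subject
  richer structures are rarely identifiable anyway.
* The precision parameter is constant; data with covariate-driven
  dispersion will show misfit in the decile diagnostics.
* Boundary mass is handled by transformation, not by a zero/one-inflated
  mixture; heavy boundary mass makes estimates sensitive to `epsilon`,
  which `sensitivity_sweep()` makes visible but does not cure.
* GEE variants based on pseudo-likelihood or quadratic estimating
  equations (as in some commercial software) will differ numerically from
  the moment-based implementation here, though usually not materially.
* Wald inference throughout; no small-sample df corrections.
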