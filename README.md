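# betalong

Longitudinal beta regression for outcome scores bounded on the unit
interval — health utilities (SF-6D), 0–100 quality-of-life subscales
rescaled to [0, 1], proportions, and similar doubly bounded, typically
left-skewed measurements taken repeatedly on the same subjects.

Such scores violate the assumptions of the Gaussian linear mixed model in
two ways: predictions can leave the admissible range, and the variance of
a bounded score shrinks as its mean approaches a bound.  The beta
distribution in its mean–precision parameterization,

    f(y; mu, phi) = Gamma(phi) / (Gamma(mu phi) Gamma((1-mu) phi)) *
                    y^(mu phi - 1) (1-y)^((1-mu) phi - 1),
    E(Y) = mu,  Var(Y) = mu (1 - mu) / (1 + phi),

handles both.  The package provides the two longitudinal extensions a
practitioner must choose between, plus the LMM baseline they are compared
against:

| function | model | coefficients |
|---|---|---|
| `betaglmm()` | beta GLMM: `logit(mu_ij) = x_ij' beta + b_i`, `b_i ~ N(0, tau2)`, ML by adaptive Gauss–Hermite quadrature | subject-specific (within-individual change) |
| `betagee()` | beta GEE: logit mean, working variance `phi mu (1-mu)`, working correlation, sandwich covariance | population-averaged (group means) |
| `lmm_ml()` | Gaussian random-intercept LMM, full ML via lme4 | both (identity link) |

Around the fitters: boundary transforms for exact 0/1 observations
(`epsilon_shift()`, `compress_transform()`, `sensitivity_sweep()`),
row-wise missingness handling (`drop_incomplete()`), univariate beta vs
normal density comparison (`fit_univariate()`), adjusted marginal means
with back-transformed intervals (`adjusted_means()`), fit statistics with
a pseudo-R² against a random-intercept-only baseline
(`fit_statistics()`, `pseudo_r2()`, `comparison_report()`), decile
residual misfit diagnostics (`decile_residual_summary()`,
`out_of_range_count()`), and a seedable synthetic-panel generator with
MCAR/MAR dropout (`simulate_panel()`, `preset_config()`,
`apply_missingness()`).  The methods vignette
(`vignettes/longitudinal-beta-regression.Rmd`) documents the models,
numerical choices and limitations.

## Worked example

Simulate a two-occasion cohort-style panel (400 subjects; a persistent
binary "diabetes" indicator, centered age, sex; beta responses with a
logit-scale random intercept) and fit all three models:

```r
library(betalong)

cfg <- preset_config("kora_like", n_subjects = 400, seed = 2026)
sim <- simulate_panel(cfg)
f <- y ~ age + sex + time + diab + diab:time

lmm  <- lmm_ml(f, sim$data, "subject_id")
glmm <- betaglmm(f, sim$data, "subject_id")
gee  <- betagee(f, sim$data, "subject_id")

summary(glmm)
```

```
Beta GLMM (logit link, random intercept; ML by adaptive Gauss-Hermite quadrature)
Formula: y ~ age + sex + time + diab + diab:time   subject: subject_id
Subjects: 400   Observations: 800   Quadrature nodes: 21

                 Estimate Std. Error z value Pr(>|z|)
(Intercept)     1.4685795  0.0633260  23.191  < 2e-16 ***
age            -0.0005394  0.0091276  -0.059  0.95288
sexmale         0.2324825  0.0771652   3.013  0.00259 **
timet2         -0.1244403  0.0479121  -2.597  0.00940 **
diabyes        -0.4226807  0.1333425  -3.170  0.00152 **
timet2:diabyes  0.0762694  0.1336634   0.571  0.56827

Precision phi: 15.66  (SE 1.12 )
Random-intercept variance tau2: 0.4  (SE 0.0463 )
-2 logLik: -1247.86   AIC: -1231.86   BIC: -1199.93
Pseudo-R2 (vs random-intercept-only LMM): 0.263
```

The coefficients are on the logit scale and subject-specific: for one and
the same individual, being male multiplies the odds `mu/(1-mu)` of the
expected score by `exp(0.232) = 1.26` (`odds_ratio_table(glmm)`).  The
generating truths here were `phi = 14.45`, `tau2 = 0.3854`.

```r
comparison_report(LMM = lmm, `beta GLMM` = glmm, `beta GEE` = gee)
```

```
      model  neg2LogL       AIC        BIC  pseudo_R2 out_of_range
1       LMM -1041.600 -1025.600  -993.6686 0.04619835            0
2 beta GLMM -1247.861 -1231.861 -1199.9294 0.26296909            0
3  beta GEE        NA        NA         NA         NA            0
```

On beta-generated data the beta GLMM beats the LMM by every
likelihood-based criterion (the GEE specifies no likelihood, hence the
`NA` cells).  Population-level group means come from the marginal model:

```r
adjusted_means(gee, by = c("time", "diab"))
```

```
Adjusted marginal means (95% CI) by time x diab
 time diab estimate ci_low ci_high se_linear
   t1   no    0.812  0.798   0.825     0.046
   t2   no    0.794  0.779   0.808     0.045
   t1  yes    0.745  0.701   0.785     0.114
   t2  yes    0.736  0.702   0.767     0.085
```

Estimates and interval endpoints are back-transformed from the logit
scale, so they stay inside (0, 1) and the intervals are asymmetric; the
standard errors come from the sandwich estimator.

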