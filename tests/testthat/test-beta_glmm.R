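test_that("adaptive quadrature matches brute-force grid integration", {
  sim <- simulate_panel(preset_config("kora_like", n_subjects = 20,
                                      seed = 7))
  des <- build_design(kora_formula, sim$data, "subject_id")
  tr <- sim$truth
  ll_agq <- marginal_loglik(kora_formula, sim$data, "subject_id",
                            tr$beta, tr$phi, tr$tau2)
  ll_brute <- oracle_brute_marginal_loglik(des$X, des$y, des$id,
                                           tr$beta, tr$phi, tr$tau2)
  expect_equal(ll_agq, ll_brute, tolerance = 1e-8)
})

test_that("at tau2 = 0 the marginal likelihood is the independent beta
          log-likelihood", {
  sim <- simulate_panel(preset_config("kora_like", n_subjects = 30,
                                      seed = 12))
  des <- build_design(kora_formula, sim$data, "subject_id")
  tr <- sim$truth
  ll0 <- marginal_loglik(kora_formula, sim$data, "subject_id",
                         tr$beta, tr$phi, tau2 = 0)
  ll_ind <- sum(dbeta_mu(des$y, plogis(drop(des$X %*% tr$beta)), tr$phi,
                         log = TRUE))
  expect_equal(ll0, ll_ind, tolerance = 1e-6)
})

test_that("the log-likelihood stabilizes along a node-count ladder", {
  sim <- simulate_panel(preset_config("stroke_like", n_subjects = 40,
                                      seed = 13))
  tr <- sim$truth
  lls <- sapply(c(5, 11, 21, 41), function(nn)
    marginal_loglik(stroke_formula, sim$data, "subject_id",
                    tr$beta, tr$phi, tr$tau2, nodes = nn))
  d <- abs(diff(lls))
  expect_true(all(diff(d) <= 1e-10))   # successive differences shrink
  expect_lt(d[3], 1e-5)
})

test_that("fitting data generated without heterogeneity reduces to the
          cross-sectional beta regression", {
  # a replicate in which the heterogeneity estimate lands on its lower
  # boundary: the fit then coincides with the cross-sectional one
  sim <- simulate_panel(preset_config("kora_like", n_subjects = 150,
                                      seed = 17, tau2_true = 0))
  fit <- betaglmm(kora_formula, sim$data, "subject_id", hessian = FALSE)
  expect_lt(fit$tau2, 1e-6)
  expect_true(fit$tau_boundary)
  des <- build_design(kora_formula, sim$data, "subject_id")
  xs <- betalong:::beta_reg_xs(des$X, des$y)
  expect_equal(unname(coef(fit)), unname(xs$beta), tolerance = 1e-4)
  expect_equal(fit$phi, xs$phi, tolerance = 1e-3 * xs$phi)
  expect_equal(fit$loglik, xs$loglik, tolerance = 1e-4)
  # a replicate without boundary luck: the spurious heterogeneity stays
  # small relative to the preset scale (0.3854)
  sim2 <- simulate_panel(preset_config("kora_like", n_subjects = 150,
                                       seed = 14, tau2_true = 0))
  fit2 <- betaglmm(kora_formula, sim2$data, "subject_id", hessian = FALSE)
  expect_lt(fit2$tau2, 0.05)
})

test_that("the fit agrees with an independent Laplace implementation and
          attains a higher exact marginal likelihood", {
  sim <- simulate_panel(preset_config("kora_like", n_subjects = 300,
                                      seed = 15))
  fit <- betaglmm(kora_formula, sim$data, "subject_id")
  d <- as.data.frame(sim$data)
  tmb <- glmmTMB::glmmTMB(
    y ~ age + sex + time + diab + diab:time + (1 | subject_id),
    data = d, family = glmmTMB::beta_family())
  b_tmb <- glmmTMB::fixef(tmb)$cond
  expect_equal(unname(coef(fit)), unname(b_tmb), tolerance = 0.05)
  expect_equal(fit$phi, glmmTMB::sigma(tmb), tolerance = 0.1 * fit$phi)
  t2_tmb <- glmmTMB::VarCorr(tmb)$cond$subject_id[1, 1]
  expect_equal(fit$tau2, t2_tmb, tolerance = 0.15 * fit$tau2)
  # Wald SEs agree closely
  expect_equal(unname(fit$se),
               unname(sqrt(diag(stats::vcov(tmb)$cond))),
               tolerance = 0.05)
  # exact-likelihood comparison: the AGQ ML is at least as good as the
  # Laplace optimum under the AGQ objective
  ll_at_tmb <- marginal_loglik(kora_formula, sim$data, "subject_id",
                               b_tmb, glmmTMB::sigma(tmb), t2_tmb)
  expect_gte(fit$loglik, ll_at_tmb - 1e-6)
})

test_that("subject predictions stay in (0,1); population predictions
          integrate over the random effect", {
  sim <- simulate_panel(preset_config("stroke_like", n_subjects = 120,
                                      seed = 16))
  fit <- betaglmm(stroke_formula, sim$data, "subject_id", hessian = FALSE)
  ps <- predict(fit, level = "subject")
  pp <- predict(fit, level = "population")
  expect_true(all(ps > 0 & ps < 1))
  expect_true(all(pp > 0 & pp < 1))
  # Jensen direction at a concave point: with eta = 1, tau2 = 1, the
  # population mean is below plogis(1)
  pm <- betalong:::glmm_pop_mean(1, 1)
  expect_lt(pm, plogis(1))
  expect_gt(pm, 0.5)
  # tau2 at the boundary: population and subject predictions coincide at
  # plogis(x'b)
  sim0 <- simulate_panel(preset_config("kora_like", n_subjects = 150,
                                       seed = 17, tau2_true = 0))
  fit0 <- betaglmm(kora_formula, sim0$data, "subject_id", hessian = FALSE)
  expect_lt(fit0$tau2, 1e-6)
  expect_equal(predict(fit0, level = "population"),
               predict(fit0, level = "subject"), tolerance = 1e-4)
})

test_that("shifting a centered covariate moves only the intercept", {
  sim <- simulate_panel(preset_config("kora_like", n_subjects = 150,
                                      seed = 18))
  fit1 <- betaglmm(kora_formula, sim$data, "subject_id", hessian = FALSE,
                   control = list(reltol = 1e-12))
  d2 <- as.data.frame(sim$data)
  d2$age <- d2$age + 5
  fit2 <- betaglmm(kora_formula, d2, "subject_id", hessian = FALSE,
                   control = list(reltol = 1e-12))
  b1 <- coef(fit1); b2 <- coef(fit2)
  expect_equal(b2[["(Intercept)"]], b1[["(Intercept)"]] - 5 * b1[["age"]],
               tolerance = 1e-4)
  expect_equal(b2[-1], b1[-1], tolerance = 1e-4)
})

test_that("fit statistics, pseudo-R2 and odds ratios follow their
          closed forms", {
  ic <- info_criteria(loglik = 2739 / 2, n_par = 8, n_subjects = 1225)
  expect_equal(round(unname(ic["AIC"])), -2723)
  expect_equal(unname(ic["BIC"] - ic["AIC"]), 8 * (log(1225) - 2))
  expect_equal(unname(info_criteria(10, 0, 5)["AIC"]), -20)

  expect_equal(pseudo_r2(100, 100, 50), 0)
  expect_equal(pseudo_r2(100 + 25, 100, 50), 1 - exp(-1))
  # strictly increasing in the full-model likelihood
  r2 <- sapply(seq(90, 120, by = 2), function(l) pseudo_r2(l, 100, 40))
  expect_true(all(diff(r2) > 0))

  or <- odds_ratio_table(c(male = 0.3483, null = 0, diab = -0.1538),
                         diag(c(0.08, 0.05, 0.04)^2))
  expect_equal(round(or$odds_ratio[1], 2), 1.42)
  expect_equal(or$odds_ratio[2], 1)
  expect_equal(or$odds_ratio[3], exp(-0.1538))
  expect_true(all(or$ci_low < or$odds_ratio & or$odds_ratio < or$ci_high))
})

test_that("a fitted model exposes coherent accessors", {
  sim <- simulate_panel(preset_config("kora_like", n_subjects = 100,
                                      seed = 19))
  fit <- betaglmm(kora_formula, sim$data, "subject_id")
  expect_equal(length(fit$eb_modes), fit$n_subjects)
  expect_equal(attr(logLik(fit), "df"), length(coef(fit)) + 2L)
  expect_equal(dim(vcov(fit)), c(6L, 6L))
  expect_equal(dim(vcov(fit, full = TRUE)), c(8L, 8L))
  expect_true(all(is.finite(fit$se)))
  expect_gt(fit$phi_se, 0)
  expect_equal(residuals(fit), fit$y - fit$fitted_subject)
  expect_output(print(summary(fit)), "Beta GLMM")
  ort <- odds_ratio_table(fit)
  expect_equal(ort$odds_ratio, exp(unname(coef(fit))))
})
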