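gaussian_config <- function(n_subjects, seed, tau2 = 0.0095) {
  preset_config("kora_like", n_subjects = n_subjects, seed = seed,
                family = "gaussian", sigma2_true = 0.0091,
                tau2_true = tau2,
                beta_true = c(0.7808, -0.0036, 0.0525, -0.0140, -0.0267,
                              -0.0300))
}

test_that("with tau2 = 0 the LMM reduces to ordinary least squares", {
  # a replicate in which the ML variance estimate lands on its boundary:
  # the model then coincides with OLS exactly
  sim <- simulate_panel(gaussian_config(150, seed = 4, tau2 = 0))
  fit <- lmm_ml(kora_formula, sim$data, "subject_id", boundary = "none")
  expect_lt(fit$tau2, 1e-8)
  ols <- stats::lm(kora_formula, data = sim$data)
  expect_equal(unname(coef(fit)), unname(coef(ols)), tolerance = 1e-6)
  # subject-level prediction with tau2 = 0 equals the population level
  expect_equal(predict(fit, level = "subject"),
               predict(fit, level = "population"), tolerance = 1e-10)
  # replicates without boundary luck still estimate tau2 near zero
  # relative to the residual variance
  sim2 <- simulate_panel(gaussian_config(150, seed = 3, tau2 = 0))
  fit2 <- lmm_ml(kora_formula, sim2$data, "subject_id", boundary = "none")
  expect_lt(fit2$tau2, 0.2 * fit2$sigma2)
})

test_that("ML log-likelihood equals the block multivariate-normal oracle", {
  sim <- simulate_panel(gaussian_config(20, seed = 5))
  fit <- lmm_ml(kora_formula, sim$data, "subject_id", boundary = "none")
  des <- build_design(kora_formula, sim$data, "subject_id")
  ll <- oracle_mvn_loglik(des$X, des$y, des$id, coef(fit), fit$sigma2,
                          fit$tau2)
  expect_equal(fit$loglik, ll, tolerance = 1e-8)
  # the returned maximizer beats random perturbations of the parameters
  set.seed(6)
  for (k in 1:40) {
    th <- coef(fit) + rnorm(length(coef(fit)), 0, 0.02)
    s2 <- fit$sigma2 * exp(rnorm(1, 0, 0.1))
    t2 <- max(fit$tau2 * exp(rnorm(1, 0, 0.1)), 1e-8)
    expect_lte(oracle_mvn_loglik(des$X, des$y, des$id, th, s2, t2),
               fit$loglik + 1e-8)
  }
})

test_that("LMM parameter recovery over replicates", {
  truth <- c(0.7808, -0.0036, 0.0525, -0.0140, -0.0267, -0.0300)
  est <- sapply(1:60, function(s) {
    sim <- simulate_panel(gaussian_config(300, seed = 100 + s))
    fit <- lmm_ml(kora_formula, sim$data, "subject_id", boundary = "none")
    c(coef(fit), s2 = fit$sigma2, t2 = fit$tau2)
  })
  m <- rowMeans(est)
  mcse <- apply(est, 1, sd) / sqrt(ncol(est))
  expect_true(all(abs(m[1:6] - truth) < 3 * mcse[1:6]))
  expect_lt(abs(m["s2"] - 0.0091), 3 * mcse["s2"] + 1e-4)
  expect_lt(abs(m["t2"] - 0.0095), 3 * mcse["t2"] + 1e-4)
})

test_that("population and subject predictions behave as documented", {
  sim <- simulate_panel(gaussian_config(80, seed = 7))
  fit0 <- lmm_ml(y ~ 1, sim$data, "subject_id", boundary = "none")
  # intercept-only population prediction is the grand mean everywhere
  expect_equal(predict(fit0, level = "population"),
               rep(unname(coef(fit0)[1]), fit0$n_obs))
  fit <- lmm_ml(kora_formula, sim$data, "subject_id", boundary = "none")
  ps <- predict(fit, level = "subject")
  pp <- predict(fit, level = "population")
  expect_equal(ps - pp, unname(fit$eb_modes[as.character(fit$id)]))
  # new data with an unknown subject errors at subject level
  nd <- as.data.frame(sim$data)[1:2, ]
  nd$subject_id <- factor("zz")
  expect_error(predict(fit, nd, level = "subject"), "not in the fitted")
})

test_that("singular designs are reported with the collinear column", {
  sim <- simulate_panel(gaussian_config(40, seed = 8))
  d <- as.data.frame(sim$data)
  d$age2 <- d$age
  expect_error(lmm_ml(y ~ age + age2, d, "subject_id", boundary = "none"),
               "rank deficient")
})

test_that("information criteria use p fixed effects + 2 variance
          parameters and a subject-count BIC", {
  sim <- simulate_panel(gaussian_config(60, seed = 9))
  fit <- lmm_ml(kora_formula, sim$data, "subject_id", boundary = "none")
  p <- length(coef(fit)) + 2L
  expect_equal(fit$aic, -2 * fit$loglik + 2 * p)
  expect_equal(fit$bic, -2 * fit$loglik + p * log(fit$n_subjects))
  fs <- fit_statistics(fit)
  expect_equal(unname(fs["AIC"]), fit$aic)
})
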