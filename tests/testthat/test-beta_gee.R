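test_that("with one row per subject the GEE solves the cross-sectional
          quasi-beta score equations", {
  sim <- simulate_panel(preset_config("kora_like", n_subjects = 250,
                                      seed = 21))
  d <- as.data.frame(sim$data)
  d1 <- d[d$time == "t1", ]
  fit <- betagee(y ~ age + sex + diab, d1,
                 "subject_id", corstr = "independence")
  oracle <- oracle_quasibeta_coef(y ~ age + sex + diab, d1)
  expect_equal(unname(coef(fit)), unname(oracle), tolerance = 1e-8)
  # working-correlation choice is irrelevant with single rows
  fit2 <- betagee(y ~ age + sex + diab, d1, "subject_id",
                  corstr = "exchangeable")
  expect_equal(coef(fit), coef(fit2), tolerance = 1e-6)
})

test_that("with two occasions exchangeable and AR-1 fits coincide", {
  sim <- simulate_panel(preset_config("kora_like", n_subjects = 200,
                                      seed = 22))
  fe <- betagee(kora_formula, sim$data, "subject_id",
                corstr = "exchangeable")
  fa <- betagee(kora_formula, sim$data, "subject_id", corstr = "ar1")
  expect_equal(coef(fe), coef(fa), tolerance = 1e-8)
  expect_equal(fe$alpha, fa$alpha, tolerance = 1e-8)
})

test_that("moment estimators of scale and alpha behave at the limits", {
  id <- factor(rep(1:50, each = 2))
  set.seed(23)
  r <- rnorm(100)
  # independent residuals: alpha near zero
  sa <- estimate_scale_alpha(r, id, "exchangeable", p = 0)
  expect_lt(abs(sa$alpha), 3 / sqrt(50))
  # duplicated observations within subject: alpha near one
  r2 <- rep(rnorm(50), each = 2)
  sa2 <- estimate_scale_alpha(r2, id, "exchangeable", p = 0)
  expect_gt(sa2$alpha, 0.9)
  # all-zero residuals flag a degenerate scale
  expect_warning(sa0 <- estimate_scale_alpha(numeric(100), id,
                                             "exchangeable"),
                 "degenerate")
  expect_equal(sa0$scale, 0)
  # ar1 and unstructured agree with exchangeable on two occasions
  sa_ar <- estimate_scale_alpha(r2, id, "ar1", p = 0)
  expect_equal(sa_ar$alpha, sa2$alpha, tolerance = 1e-12)
  sa_un <- estimate_scale_alpha(r2, id, "unstructured", p = 0)
  expect_equal(sa_un$alpha[1, 2], sa2$alpha, tolerance = 1e-12)
})

test_that("GEE coefficients are consistent for the population-averaged
          estimand", {
  simbig <- simulate_panel(preset_config("kora_like", n_subjects = 30000,
                                         seed = 999))
  plim <- coef(betagee(kora_formula, simbig$data, "subject_id"))
  # the marginal slopes are attenuated relative to the subject-specific
  # truth because tau2 > 0
  tr <- simulate_panel(preset_config("kora_like", n_subjects = 10,
                                     seed = 1))$truth$beta
  expect_lt(abs(plim[["sexmale"]]), abs(tr[["sexmale"]]))
  expect_lt(abs(plim[["diabyes"]]), abs(tr[["diabyes"]]))

  est <- sapply(1:40, function(s) {
    sim <- simulate_panel(preset_config("kora_like", n_subjects = 500,
                                        seed = 300 + s))
    coef(betagee(kora_formula, sim$data, "subject_id"))
  })
  m <- rowMeans(est)
  mcse <- apply(est, 1, sd) / sqrt(ncol(est))
  expect_true(all(abs(m - plim) < 3 * mcse + 0.01 * abs(plim)))
})

test_that("sandwich and model-based covariances relate as theory
          predicts", {
  # correctly specified working correlation: the two covariances agree
  sim <- simulate_panel(preset_config("kora_like", n_subjects = 4000,
                                      seed = 25))
  fit <- betagee(kora_formula, sim$data, "subject_id")
  ratio <- sqrt(diag(fit$vcov_sandwich)) / sqrt(diag(fit$vcov_model))
  expect_true(all(ratio > 0.85 & ratio < 1.15))
  V <- vcov(fit)
  expect_equal(V, t(V), tolerance = 1e-12)
  expect_true(all(eigen(V, only.values = TRUE)$values > 0))
  # misspecified working independence on correlated data: the robust SE
  # of the within-subject time contrast exceeds the naive one
  fit_ind <- betagee(kora_formula, sim$data, "subject_id",
                     corstr = "independence")
  r_ind <- sqrt(diag(fit_ind$vcov_sandwich)) /
    sqrt(diag(fit_ind$vcov_model))
  expect_lt(r_ind[["timet2"]], 0.95)
  expect_gt(r_ind[["sexmale"]], 1.05)
})

test_that("adjusted marginal means respect the unit interval and the
          mean-variance relation", {
  sim <- simulate_panel(preset_config("stroke_like", n_subjects = 250,
                                      seed = 26))
  fit <- betagee(stroke_formula, sim$data, "subject_id")
  mm <- adjusted_means(fit, by = c("time", "phase"))
  expect_equal(nrow(mm), 6L)
  expect_true(all(mm$estimate > 0 & mm$estimate < 1))
  expect_true(all(mm$ci_low < mm$estimate & mm$estimate < mm$ci_high))
  expect_true(all(mm$ci_low > 0 & mm$ci_high < 1))
  # asymmetry of the back-transformed interval away from 0.5
  hi <- which.max(mm$estimate)
  expect_gt(mm$estimate[hi], 0.6)
  expect_lt(mm$ci_high[hi] - mm$estimate[hi],
            mm$estimate[hi] - mm$ci_low[hi])
  # equal linear-scale SE: the response-scale interval is narrower for a
  # stratum with mean nearer the bound
  w <- function(eta, se) plogis(eta + 1.96 * se) - plogis(eta - 1.96 * se)
  expect_lt(w(2.2, 0.2), w(0.3, 0.2))
  # observed-population policy gives estimates inside (0,1) too
  mo <- adjusted_means(fit, by = "phase", policy = "observed")
  expect_true(all(mo$estimate > 0 & mo$estimate < 1))
  # an intercept-only model with beta0 = 0 would give 0.5; check via a
  # symmetric synthetic fit
  d0 <- data.frame(subject_id = factor(rep(1:100, each = 2)),
                   g = factor(rep(c("u", "v"), 100)),
                   y = plogis(qlogis(rep(c(0.45, 0.55), 100)) +
                                rnorm(200, 0, 0.1)))
  f0 <- betagee(y ~ g, d0, "subject_id")
  m0 <- adjusted_means(f0, by = "g")
  expect_equal(mean(qlogis(m0$estimate)), mean(qlogis(d0$y)),
               tolerance = 0.05)
})

test_that("non-model strata and convergence failures raise errors", {
  sim <- simulate_panel(preset_config("kora_like", n_subjects = 60,
                                      seed = 27))
  fit <- betagee(kora_formula, sim$data, "subject_id")
  expect_error(adjusted_means(fit, by = "nothere"), "not model factors")
  expect_error(betagee(kora_formula, sim$data, "subject_id",
                       max_iter = 1L), "converge")
})
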