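test_that("presets carry the documented truth values and are
          deterministic", {
  k <- preset_config("kora_like")
  expect_equal(k$phi_true, 14.45)
  expect_equal(k$tau2_true, 0.3854)
  expect_equal(k$n_subjects, 1000L)
  expect_equal(length(k$occasions), 2L)
  s <- preset_config("stroke_like")
  expect_equal(s$phi_true, 10.80)
  expect_equal(s$tau2_true, 1.2782)
  expect_equal(length(s$occasions), 3L)
  expect_identical(preset_config("kora_like"), preset_config("kora_like"))
  expect_error(preset_config("nope"))
})

test_that("the generator is seed-deterministic and respects the unit
          interval", {
  cfg <- preset_config("kora_like", n_subjects = 80, seed = 5)
  s1 <- simulate_panel(cfg)
  s2 <- simulate_panel(cfg)
  expect_identical(s1$data$y, s2$data$y)
  expect_identical(s1$truth$b, s2$truth$b)
  expect_true(all(s1$data$y > 0 & s1$data$y < 1))  # no exact boundaries
  # boundary censoring produces exact boundary values
  s3 <- simulate_panel(preset_config("stroke_like", n_subjects = 200,
                                     seed = 5, boundary_mass = 0.10))
  frac <- mean(s3$data$y %in% c(0, 1))
  expect_gt(frac, 0.10 - 3 * sqrt(0.1 * 0.9 / 600))
  expect_lt(frac, 0.10 + 3 * sqrt(0.1 * 0.9 / 600))
})

test_that("tau2 = 0 kills the within-subject correlation; tau2 > 0
          attenuates the marginal slopes", {
  s0 <- simulate_panel(preset_config("kora_like", n_subjects = 3000,
                                     seed = 6, tau2_true = 0))
  d <- as.data.frame(s0$data)
  # shared covariates induce marginal cross-occasion correlation even
  # without a random effect, so correlate covariate-adjusted residuals
  r <- stats::residuals(stats::lm(kora_formula, data = d))
  r1 <- r[d$time == "t1"]; r2 <- r[d$time == "t2"]
  expect_lt(abs(cor(r1, r2)), 3 / sqrt(length(r1)))

  # empirical cell mean matches the quadrature-computed population mean
  sbig <- simulate_panel(preset_config("kora_like", n_subjects = 20000,
                                       seed = 7))
  db <- as.data.frame(sbig$data)
  cell <- db$time == "t1" & db$sex == "female" & db$diab == "no"
  eta_cell <- qlogis(sbig$truth$mu[cell]) -
    sbig$truth$b[as.integer(db$subject_id[cell])]
  pop <- mean(betalong:::glmm_pop_mean(eta_cell, sqrt(0.3854)))
  emp <- mean(db$y[cell])
  expect_lt(abs(emp - pop), 3 * sd(db$y[cell]) / sqrt(sum(cell)))
})

test_that("MCAR dropout hits its rate and never touches baseline rows", {
  sim <- simulate_panel(preset_config("kora_like", n_subjects = 5000,
                                      seed = 8))
  out <- apply_missingness(sim$data, "mcar", p = 0.2, seed = 99)
  d <- as.data.frame(out)
  expect_equal(sum(d$time == "t1"), 5000L)
  kept2 <- sum(d$time == "t2")
  dropped <- 5000L - kept2
  expect_lt(abs(dropped / 5000 - 0.2), 3 * sqrt(0.2 * 0.8 / 5000))
  out0 <- apply_missingness(sim$data, "mcar", p = 0, seed = 99)
  expect_equal(nrow(out0), nrow(sim$data))
})

test_that("MAR dropout depends on the previous observed response with the
          configured sign", {
  sim <- simulate_panel(preset_config("kora_like", n_subjects = 5000,
                                      seed = 9))
  out <- apply_missingness(sim$data, "mar", gamma0 = 1.6, gamma1 = -3,
                           seed = 77)
  d <- as.data.frame(sim$data)
  kept <- d$subject_id[d$time == "t2"] %in%
    as.data.frame(out)$subject_id[as.data.frame(out)$time == "t2"]
  y1 <- d$y[d$time == "t1"]
  # lower previous scores drop out more: missingness correlates
  # negatively with the lagged response
  expect_lt(cor(y1, as.numeric(!kept)), -0.05)
  expect_gt(mean(!kept), 0.15)  # substantial attrition at these defaults
  # three-occasion panels: dropout uses the last *observed* response
  sim3 <- simulate_panel(preset_config("stroke_like", n_subjects = 500,
                                       seed = 10))
  out3 <- apply_missingness(sim3$data, "mar", seed = 3)
  expect_equal(sum(as.data.frame(out3)$time == "t1"), 500L)
  expect_lt(nrow(out3), nrow(sim3$data))
})

test_that("invalid configurations are rejected", {
  expect_error(synth_config(10, c("t1", "t2"), rep(0, 5), 10, 0.3,
                            "kora_like"), "6 coefficients")
  expect_error(synth_config(10, c("t1", "t2", "t3"), rep(0, 6), 10, 0.3,
                            "kora_like"), "2 occasions")
  expect_error(synth_config(10, c("t1", "t2"), rep(0, 6), 10, 0.3,
                            "kora_like", family = "gaussian"),
               "sigma2_true")
  expect_error(synth_config(10, c("t1", "t2"), rep(0, 6), 10, 0.3,
                            "kora_like",
                            missingness = list(mechanism = "xx")),
               "mechanism")
})
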