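# Independent oracles used to validate the package's own implementations.
# These deliberately avoid the code paths they check.

# Marginal beta-GLMM log-likelihood by dense-grid trapezoid integration of
# the random intercept (no Gauss-Hermite machinery).
oracle_brute_marginal_loglik <- function(X, y, id, beta, phi, tau2,
                                         npts = 20001L, width = 8) {
  eta <- drop(X %*% beta)
  tau <- sqrt(tau2)
  bgrid <- seq(-width * tau, width * tau, length.out = npts)
  h <- bgrid[2L] - bgrid[1L]
  id <- droplevels(factor(id))
  tot <- 0
  for (lev in levels(id)) {
    ix <- which(id == lev)
    # rows x grid matrix of conditional log-densities
    M <- outer(eta[ix], bgrid, `+`)
    mu <- plogis(M)
    ld <- lgamma(phi) - lgamma(mu * phi) - lgamma((1 - mu) * phi) +
      (mu * phi - 1) * log(y[ix]) + ((1 - mu) * phi - 1) * log1p(-y[ix])
    lp <- colSums(ld) + dnorm(bgrid, 0, tau, log = TRUE)
    m <- max(lp)
    tot <- tot + m + log(sum(exp(lp - m)) * h)
  }
  tot
}

# Gaussian random-intercept marginal log-likelihood via explicit
# block multivariate-normal densities (compound-symmetry covariance).
oracle_mvn_loglik <- function(X, y, id, beta, sigma2, tau2) {
  id <- droplevels(factor(id))
  r <- y - drop(X %*% beta)
  tot <- 0
  for (lev in levels(id)) {
    ix <- which(id == lev)
    ni <- length(ix)
    S <- matrix(tau2, ni, ni) + diag(sigma2, ni)
    L <- chol(S)
    z <- backsolve(L, r[ix], transpose = TRUE)
    tot <- tot - 0.5 * (ni * log(2 * pi) + 2 * sum(log(diag(L))) +
                          sum(z^2))
  }
  tot
}

# Cross-sectional quasi-beta fit: with working variance phi*mu*(1-mu) and
# logit link, the score equations reduce to those of a quasibinomial GLM,
# which stats::glm solves by its own IRLS.
oracle_quasibeta_coef <- function(formula, data) {
  fit <- suppressWarnings(stats::glm(formula, data = data,
                                     family = stats::quasibinomial(),
                                     control = stats::glm.control(
                                       epsilon = 1e-13, maxit = 100)))
  stats::coef(fit)
}

# Small deterministic well-formed panel (3 subjects x 2 occasions).
make_small_panel <- function() {
  data.frame(id = rep(c("a", "b", "c"), each = 2L),
             occ = rep(c("t1", "t2"), 3L),
             y = c(0.70, 0.60, 0.80, 0.90, 0.50, 0.40),
             x = c(1.0, 1.0, 2.0, 2.0, 0.5, 0.5))
}

# Kora-style model formula used throughout the tests.
kora_formula <- y ~ age + sex + time + diab + diab:time
stroke_formula <- y ~ age + sex + time + phase + phase:time

# Population-averaged (marginal) coefficient truth for the kora-like
# generator: the large-sample limit of the GEE estimator, computed once on
# a 30000-subject panel and cached for the whole test run.
.plim_cache <- new.env(parent = emptyenv())
kora_marginal_plim <- function() {
  if (is.null(.plim_cache$plim)) {
    simbig <- simulate_panel(preset_config("kora_like", n_subjects = 30000,
                                           seed = 999))
    .plim_cache$plim <- coef(betagee(kora_formula, simbig$data,
                                     "subject_id"))
  }
  .plim_cache$plim
}
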