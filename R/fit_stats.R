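#' Likelihood-based information criteria
#'
#' `AIC = -2 logLik + 2 p` and `BIC = -2 logLik + p log(N_subjects)`, where
#' `p` counts all estimated parameters (fixed effects plus variance /
#' precision parameters) and the BIC penalty uses the number of independent
#' units — the subjects — rather than the number of rows.
#'
#' @param loglik maximized log-likelihood.
#' @param n_par number of estimated parameters `p`.
#' @param n_subjects number of subjects `N`.
#' @return named vector `c(neg2LogL, AIC, BIC)`.
#' @examples
#' info_criteria(1369.5, 8, 1225)  # AIC -2723
#' @export
info_criteria <- function(loglik, n_par, n_subjects) {
  stopifnot(n_par >= 0, n_subjects >= 1)
  c(neg2LogL = -2 * loglik,
    AIC = -2 * loglik + 2 * n_par,
    BIC = -2 * loglik + n_par * log(n_subjects))
}

#' Pseudo-R-squared from two log-likelihoods
#'
#' `1 - exp((2 / n_obs) * (loglik_baseline - loglik_full))`, the geometric
#' mean squared per-observation likelihood improvement of the full model
#' over a baseline.  For longitudinal bounded-outcome models the baseline
#' used throughout this package is the random-intercept-only Gaussian LMM
#' fitted by ML to the same rows, so that the baseline already accounts for
#' within-subject correlation.  Negative values (full model worse than the
#' baseline) are returned as-is.
#'
#' @param loglik_full log-likelihood of the model under assessment.
#' @param loglik_baseline log-likelihood of the baseline model on the same
#'   observations.
#' @param n_obs total number of observations.
#' @return numeric scalar.
#' @export
pseudo_r2 <- function(loglik_full, loglik_baseline, n_obs) {
  stopifnot(n_obs >= 1)
  1 - exp((2 / n_obs) * (loglik_baseline - loglik_full))
}

#' Fit statistics of a likelihood-based fit
#'
#' @param fit an `"lmm_ml"` or `"beta_glmm"` object.
#' @return named vector with `neg2LogL`, `AIC`, `BIC` and `pseudoR2`.
#' @export
fit_statistics <- function(fit) {
  stopifnot(inherits(fit, c("lmm_ml", "beta_glmm")))
  c(neg2LogL = -2 * fit$loglik, AIC = fit$aic, BIC = fit$bic,
    pseudoR2 = fit$pseudo_r2)
}

#' Odds ratios from logit-scale coefficients
#'
#' Exponentiates logit-link coefficients and their Wald interval endpoints.
#' For a logit-link beta model the exponentiated coefficient is the
#' multiplicative change in the odds `mu / (1 - mu)` of the expected score
#' relative to its distance from the upper bound.
#'
#' @param fit a fitted logit-link model (`"beta_glmm"` or `"betagee"`), or a
#'   named numeric vector of coefficients.
#' @param vcov covariance matrix of the coefficients; taken from the fit
#'   when `fit` is a model object.
#' @param conf_level confidence level for the Wald interval.
#' @return data frame with `term`, `estimate` (logit scale), `odds_ratio`,
#'   `ci_low`, `ci_high`.
#' @examples
#' odds_ratio_table(c(male = 0.3483), matrix(0.08^2))
#' @export
odds_ratio_table <- function(fit, vcov = NULL, conf_level = 0.95) {
  if (is.numeric(fit)) {
    cf <- fit
    V <- vcov
  } else {
    cf <- stats::coef(fit)
    V <- if (is.null(vcov)) stats::vcov(fit) else vcov
  }
  se <- if (is.null(V)) rep(NA_real_, length(cf)) else sqrt(diag(as.matrix(V)))
  zc <- stats::qnorm(1 - (1 - conf_level) / 2)
  data.frame(term = names(cf), estimate = unname(cf),
             odds_ratio = exp(unname(cf)),
             ci_low = exp(unname(cf) - zc * se),
             ci_high = exp(unname(cf) + zc * se),
             row.names = NULL, stringsAsFactors = FALSE)
}

## central-difference Hessian of f at x (f: numeric vector -> scalar);
## step 1e-4 scaled by parameter magnitude
fd_hessian <- function(f, x, h = NULL) {
  k <- length(x)
  if (is.null(h)) h <- 1e-4 * pmax(1, abs(x))
  H <- matrix(NA_real_, k, k)
  f0 <- f(x)
  for (i in seq_len(k)) {
    ei <- numeric(k); ei[i] <- h[i]
    H[i, i] <- (f(x + ei) - 2 * f0 + f(x - ei)) / h[i]^2
    if (i > 1L) for (j in seq_len(i - 1L)) {
      ej <- numeric(k); ej[j] <- h[j]
      H[i, j] <- H[j, i] <-
        (f(x + ei + ej) - f(x + ei - ej) - f(x - ei + ej) + f(x - ei - ej)) /
        (4 * h[i] * h[j])
    }
  }
  H
}

## row-wise log-sum-exp for a matrix
logsumexp_rows <- function(M) {
  m <- M[cbind(seq_len(nrow(M)), max.col(M, ties.method = "first"))]
  m + log(rowSums(exp(M - m)))
}
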