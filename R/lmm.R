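#' Gaussian random-intercept linear mixed model by maximum likelihood
#'
#' Fits `y_ij = x_ij' beta + b_i + e_ij`, `b_i ~ N(0, tau2)`,
#' `e_ij ~ N(0, sigma2)` by full maximum likelihood (not REML), as the
#' comparison baseline for the beta mixed model and the reference model of
#' the pseudo-R-squared.  Estimation is delegated to [lme4::lmer()] with
#' `REML = FALSE`; information criteria are recomputed here with
#' `p = n_fixed + 2` parameters (fixed effects plus the two variances) and a
#' BIC penalty of `log(N_subjects)` — the mixed-model convention in which
#' the effective number of independent units is the number of subjects.
#'
#' ML rather than REML is used throughout because log-likelihoods, AIC and
#' BIC are compared across model families with different fixed-effect
#' structures; REML likelihoods are not comparable in that way.  Coefficient
#' p-values use the Wald normal approximation.
#'
#' @param formula fixed-effects formula, e.g.
#'   `y ~ age + sex + time + diab + diab:time` (the random intercept is
#'   implicit).
#' @param data data frame or [long_panel()].
#' @param subject name of the subject identifier column.
#' @param boundary,epsilon boundary policy applied to the response before
#'   fitting, for comparability with the beta models fitted to the same
#'   rows; `"shift"` only moves exact 0/1 values.  Use `"none"` to fit the
#'   raw response.
#' @return object of class `"lmm_ml"`: coefficients, `sigma2`, `tau2` (with
#'   standard error), `loglik`, `aic`, `bic`, `pseudo_r2` (against a
#'   random-intercept-only LMM on the same rows), `vcov_beta`, empirical
#'   Bayes intercepts `eb_modes`, fitted values at both levels, and
#'   missingness counts.
#' @seealso [betaglmm()], [betagee()], [comparison_report()]
#' @export
lmm_ml <- function(formula, data, subject,
                   boundary = c("shift", "compress", "none"),
                   epsilon = 0.005) {
  boundary <- match.arg(boundary)
  cl <- match.call()
  dropped <- drop_incomplete(data, formula)
  d <- as.data.frame(dropped$data)
  des <- build_design(formula, d, subject)
  check_full_rank(des$X)
  y <- boundary_transform(des$y, boundary, epsilon)
  if (nrow(des$X) < ncol(des$X) + 2L)
    stop("need at least p + 2 rows to fit", call. = FALSE)

  d2 <- d
  d2[[".y"]] <- y
  d2[[".subject"]] <- des$id
  rhs <- paste(deparse(formula[[3L]]), collapse = " ")
  lf <- stats::as.formula(paste(".y ~", rhs, "+ (1 | .subject)"))
  fit <- lme4::lmer(lf, data = d2, REML = FALSE,
                    control = lme4::lmerControl(calc.derivs = FALSE,
                                                check.conv.singular = "ignore"))
  beta <- lme4::fixef(fit)
  vc <- lme4::VarCorr(fit)
  tau2 <- as.numeric(vc[[".subject"]][1L, 1L])
  sigma2 <- attr(vc, "sc")^2
  ll <- as.numeric(stats::logLik(fit))
  p <- length(beta) + 2L
  nsub <- nlevels(des$id)
  ic <- info_criteria(ll, p, nsub)
  re <- lme4::ranef(fit)[[".subject"]]
  eb <- stats::setNames(re[[1L]], rownames(re))
  eta_pop <- drop(des$X %*% beta)
  eta_sub <- eta_pop + eb[as.character(des$id)]

  base_ll <- baseline_loglik(y, des$id)
  out <- list(call = cl, coefficients = beta,
              vcov_beta = as.matrix(stats::vcov(fit)),
              sigma2 = sigma2, tau2 = tau2,
              tau2_se = variance_se_lmm(fit),
              loglik = ll, aic = ic[["AIC"]], bic = ic[["BIC"]], n_par = p,
              pseudo_r2 = pseudo_r2(ll, base_ll, length(y)),
              baseline_loglik = base_ll,
              eb_modes = eb, y = y, id = des$id,
              fitted_population = unname(eta_pop),
              fitted_subject = unname(eta_sub),
              n_obs = length(y), n_subjects = nsub,
              n_missing_response = dropped$n_missing_response,
              n_missing_covariate = dropped$n_missing_covariate,
              boundary = boundary, epsilon = epsilon,
              formula = formula, subject = subject,
              terms = des$terms, xlevels = des$xlevels,
              contrasts = des$contrasts,
              data_means = numeric_var_means(des$terms, d),
              model_frame = d[, intersect(union(all.vars(formula), subject),
                                          names(d)), drop = FALSE])
  class(out) <- "lmm_ml"
  out
}

## SE of the random-intercept variance tau2 = sd_b^2 from the Hessian of
## the profiled ML deviance on the (sd_b, sigma) scale (lme4::devfun2)
variance_se_lmm <- function(fit) {
  dd <- lme4::devfun2(fit, useSc = TRUE, signames = FALSE)
  pars <- attr(dd, "optimum")[1:2]          # (sd_b, sigma)
  if (pars[1L] < 1e-8) return(NA_real_)     # boundary: no Wald SE
  f <- function(p) dd(p) / 2                # negative profiled loglik
  H <- fd_hessian(f, pars, h = 1e-5 * pmax(0.01, abs(pars)))
  V <- try(solve(H), silent = TRUE)
  if (inherits(V, "try-error") || any(!is.finite(V))) return(NA_real_)
  se2 <- 4 * pars[1L]^2 * V[1L, 1L]         # delta: d tau2/d sd_b = 2 sd_b
  if (!is.finite(se2) || se2 < 0) NA_real_ else sqrt(se2)
}

## random-intercept-only Gaussian LMM log-likelihood (ML), the reference
## model of the pseudo-R2
baseline_loglik <- function(y, id) {
  d0 <- data.frame(.y = y, .subject = id)
  f0 <- lme4::lmer(.y ~ 1 + (1 | .subject), data = d0, REML = FALSE,
                   control = lme4::lmerControl(calc.derivs = FALSE,
                                               check.conv.singular = "ignore"))
  as.numeric(stats::logLik(f0))
}

#' @export
coef.lmm_ml <- function(object, ...) object$coefficients

#' @export
vcov.lmm_ml <- function(object, ...) object$vcov_beta

#' @export
logLik.lmm_ml <- function(object, ...)
  structure(object$loglik, df = object$n_par, nobs = object$n_obs,
            class = "logLik")

#' @export
residuals.lmm_ml <- function(object, level = c("subject", "population"), ...) {
  level <- match.arg(level)
  object$y - switch(level, subject = object$fitted_subject,
                    population = object$fitted_population)
}

#' Predictions from a Gaussian random-intercept LMM
#'
#' Population-level predictions are `X beta`; subject-level predictions add
#' the empirical-Bayes intercept of the matching subject.  Note that on the
#' identity scale these predictions are not confined to `[0, 1]`; see
#' [out_of_range_count()].
#'
#' @param object an `"lmm_ml"` fit.
#' @param newdata optional data frame; defaults to the training rows.
#' @param level `"population"` or `"subject"`.
#' @param ... unused.
#' @return numeric vector of predictions.
#' @export
predict.lmm_ml <- function(object, newdata = NULL,
                           level = c("population", "subject"), ...) {
  level <- match.arg(level)
  if (is.null(newdata)) {
    return(switch(level, population = object$fitted_population,
                  subject = object$fitted_subject))
  }
  X <- design_for_newdata(object, newdata)
  eta <- drop(X %*% object$coefficients)
  if (level == "subject") {
    ids <- as.character(newdata[[object$subject]])
    unknown <- setdiff(unique(ids), names(object$eb_modes))
    if (length(unknown))
      stop("subject(s) not in the fitted data: ",
           paste(utils::head(unknown, 5L), collapse = ", "), call. = FALSE)
    eta <- eta + object$eb_modes[ids]
  }
  unname(eta)
}

## rebuild the fixed design for new data using stored terms/xlevels
design_for_newdata <- function(object, newdata) {
  newdata <- as.data.frame(newdata)
  for (j in seq_along(newdata))
    if (is.character(newdata[[j]]))
      newdata[[j]] <- factor(newdata[[j]], levels = unique(newdata[[j]]))
  tt <- stats::delete.response(object$terms)
  mf <- stats::model.frame(tt, newdata, na.action = stats::na.fail,
                           xlev = object$xlevels)
  stats::model.matrix(tt, mf, contrasts.arg = object$contrasts)
}

## sample means of the numeric model variables, for adjusted-means profiles
numeric_var_means <- function(terms, data) {
  vars <- attr(terms, "term.labels")
  vars <- unique(unlist(lapply(vars, function(v) all.vars(str2lang(v)))))
  vars <- intersect(vars, names(data))
  num <- vars[vapply(vars, function(v) is.numeric(data[[v]]), logical(1L))]
  vapply(num, function(v) mean(data[[v]]), numeric(1L))
}

#' @export
print.lmm_ml <- function(x, digits = 4, ...) {
  cat("Linear mixed model (random intercept, ML)\n")
  cat("  subjects:", x$n_subjects, " observations:", x$n_obs, "\n")
  print(round(x$coefficients, digits))
  cat("  sigma2:", format(x$sigma2, digits = digits),
      " tau2:", format(x$tau2, digits = digits), "\n")
  cat("  -2 logLik:", format(-2 * x$loglik, digits = 6),
      " AIC:", format(x$aic, digits = 6),
      " BIC:", format(x$bic, digits = 6), "\n")
  invisible(x)
}

#' @export
summary.lmm_ml <- function(object, ...) {
  se <- sqrt(diag(object$vcov_beta))
  z <- object$coefficients / se
  tab <- cbind(Estimate = object$coefficients, `Std. Error` = se,
               `z value` = z, `Pr(>|z|)` = 2 * stats::pnorm(-abs(z)))
  structure(list(fit = object, coefficients = tab), class = "summary.lmm_ml")
}

#' @export
print.summary.lmm_ml <- function(x, digits = 4, ...) {
  f <- x$fit
  cat("Linear mixed model (random intercept, ML)\n")
  cat("Formula:", deparse(f$formula), "  subject:", f$subject, "\n")
  cat("Subjects:", f$n_subjects, "  Observations:", f$n_obs, "\n\n")
  stats::printCoefmat(x$coefficients, digits = digits, P.values = TRUE,
                      has.Pvalue = TRUE)
  cat("\nResidual variance sigma2:", format(f$sigma2, digits = digits), "\n")
  cat("Random-intercept variance tau2:", format(f$tau2, digits = digits),
      " (SE", format(f$tau2_se, digits = 3), ")\n")
  cat("-2 logLik:", format(-2 * f$loglik, digits = 6),
      "  AIC:", format(f$aic, digits = 6),
      "  BIC:", format(f$bic, digits = 6), "\n")
  cat("Pseudo-R2 (vs random-intercept-only LMM):",
      format(f$pseudo_r2, digits = 4), "\n")
  invisible(x)
}
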