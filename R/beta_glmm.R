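## ---------------------------------------------------------------------------
## Beta GLMM: logit-link beta regression with a subject-level random
## intercept, fitted by maximum likelihood with (adaptive) Gauss-Hermite
## quadrature over the random effect.
##
## Model: logit(mu_ij) = x_ij' beta + b_i,  b_i ~ N(0, tau2),
##        Y_ij | b_i ~ Beta(mu_ij phi, (1 - mu_ij) phi).
## The marginal likelihood integrates b_i out subject by subject; adaptive
## quadrature recenters the nodes at each subject's posterior mode with a
## scale from the curvature there, which keeps a modest node count accurate
## even at large tau2.
## ---------------------------------------------------------------------------

## quadrature engine factory.  Returns a function(theta) -> loglik where
## theta = c(beta, log phi, log tau); posterior modes are cached between
## calls (warm starts) in `state`.
agq_engine <- function(X, y, id, nodes = 21L, adaptive = TRUE) {
  stopifnot(nodes >= 3L)
  gh <- pracma::gaussHermite(nodes)
  z <- gh$x
  lw <- log(gh$w) + z^2               # weights for exp-kernel-free integrand
  idx <- as.integer(id)
  N <- nlevels(id)
  n <- length(y)
  logity <- log(y) - log1p(-y)
  state <- new.env(parent = emptyenv())
  state$modes <- numeric(N)

  ## posterior mode + curvature of b_i given (beta, phi, tau), Newton with
  ## damping, vectorized across subjects
  clamp_mu <- function(m) pmin(pmax(m, 1e-12), 1 - 1e-12)

  ## per-subject posterior log-density of b (up to a constant), gradient
  ## and curvature; all vectorized over subjects via rowsum
  post_obj <- function(b, eta, phi, tau2) {
    mu <- clamp_mu(stats::plogis(eta + b[idx]))
    rowsum(ldbeta_mu(y, mu, phi), idx)[, 1L] - b^2 / (2 * tau2)
  }
  post_grad_curv <- function(b, eta, phi, tau2) {
    mu <- clamp_mu(stats::plogis(eta + b[idx]))
    w <- mu * (1 - mu)
    s <- logity - digamma(mu * phi) + digamma((1 - mu) * phi)
    g_row <- phi * w * s
    h_row <- phi * ((1 - 2 * mu) * w * s -
                      phi * w^2 * (trigamma(mu * phi) +
                                     trigamma((1 - mu) * phi)))
    list(g = rowsum(g_row, idx)[, 1L] - b / tau2,
         h = rowsum(h_row, idx)[, 1L] - 1 / tau2)
  }

  ## damped Newton with per-subject backtracking: the per-subject posterior
  ## can be sharply peaked (responses within machine precision of a
  ## boundary), where undamped Newton oscillates
  find_modes <- function(eta, phi, tau2, b0) {
    b <- b0
    f0 <- post_obj(b, eta, phi, tau2)
    for (it in 1:50) {
      gc_ <- post_grad_curv(b, eta, phi, tau2)
      if (!all(is.finite(gc_$g)) || !all(is.finite(gc_$h)))
        return(list(b = rep(NA_real_, N), sigma = rep(NA_real_, N)))
      if (max(abs(gc_$g)) < 1e-9) break
      h <- pmin(gc_$h, -1e-8)
      step <- gc_$g / h
      step <- sign(step) * pmin(abs(step), 10)
      b_prev <- b
      lam <- rep(1, N)
      active <- rep(TRUE, N)
      for (bt in 1:12) {
        b_try <- b - ifelse(active, lam, 0) * step
        f_try <- post_obj(b_try, eta, phi, tau2)
        good <- !active | (is.finite(f_try) & f_try >= f0 - 1e-12)
        accept <- active & good
        b[accept] <- b_try[accept]
        f0[accept] <- f_try[accept]
        active <- active & !good
        if (!any(active)) break
        lam[active] <- lam[active] / 2
      }
      if (max(abs(b - b_prev)) < 1e-11) break   # stagnation: done
    }
    gc_ <- post_grad_curv(b, eta, phi, tau2)
    h <- pmin(gc_$h, -1e-8)
    sigma <- sqrt(-1 / h)
    ## a genuine mode has negative curvature; where the curvature estimate
    ## is degenerate, fall back to the prior scale
    bad <- !is.finite(sigma) | sigma > 10 * sqrt(tau2) + 1
    sigma[bad] <- sqrt(tau2)
    list(b = b, sigma = sigma)
  }

  ## one pass computing the log-likelihood and (optionally) its gradient
  ## with respect to theta = (beta, log phi, log tau).  The gradient
  ## differentiates under the integral at the fixed node positions
  ## (posterior-weighted score); node-position dependence on theta is a
  ## higher-order quadrature effect.
  compute <- function(theta, want_grad = FALSE) {
    bad <- list(value = -1e10,
                grad = rep(NA_real_, length(theta)))
    if (!all(is.finite(theta))) return(bad)
    p <- length(theta) - 2L
    beta <- theta[seq_len(p)]
    phi <- exp(theta[p + 1L])
    tau <- max(exp(theta[p + 2L]), 1e-6)
    tau2 <- tau^2
    eta <- drop(X %*% beta)
    if (!all(is.finite(eta)) || !is.finite(phi) || phi > 1e8 || tau > 1e4)
      return(bad)
    agq_pass <- function(ctr, sc, want_grad) {
      Bk <- ctr + outer(sc * sqrt(2), z)             # N x K node positions
      EtaK <- matrix(eta, n, nodes) + Bk[idx, , drop = FALSE]
      MuK <- clamp_mu(stats::plogis(EtaK))
      LK <- ldbeta_mu(y, MuK, phi)                   # y recycled columnwise
      S <- rowsum(LK, idx)                           # N x K data log-lik
      A <- sweep(S + stats::dnorm(Bk, 0, tau, log = TRUE), 2L, lw, `+`)
      m <- A[cbind(seq_len(N), max.col(A, ties.method = "first"))]
      P <- exp(A - m)
      rs <- rowSums(P)
      val <- sum(log(sqrt(2) * sc) + m + log(rs))
      Pn <- P / rs                                   # posterior node weights
      out <- list(value = val, Pn = Pn, Bk = Bk, grad = NULL)
      if (!want_grad || !is.finite(val)) return(out)
      Prow <- Pn[idx, , drop = FALSE]                # n x K
      dig1 <- digamma(MuK * phi)
      dig2 <- digamma((1 - MuK) * phi)
      WsK <- MuK * (1 - MuK) * (logity - dig1 + dig2)
      g_beta <- drop(crossprod(X, phi * rowSums(Prow * WsK)))
      dphiK <- digamma(phi) - MuK * dig1 - (1 - MuK) * dig2 +
        MuK * log(y) + (1 - MuK) * log1p(-y)
      g_lphi <- phi * sum(Prow * dphiK)
      g_ltau <- sum(Pn * (Bk^2 / tau2 - 1))
      out$grad <- c(g_beta, g_lphi, g_ltau)
      out
    }

    if (adaptive) {
      md <- find_modes(eta, phi, tau2, state$modes)
      if (!all(is.finite(md$b)) || !all(is.finite(md$sigma))) return(bad)
      state$modes <- md$b
      ## first pass centered at the posterior modes, then one
      ## moment-matching refinement (recenters at the posterior mean with
      ## the posterior SD as scale), which sharpens the quadrature when
      ## the posterior is skewed
      p1 <- agq_pass(md$b, md$sigma, FALSE)
      if (!is.finite(p1$value)) return(bad)
      m1 <- rowSums(p1$Pn * p1$Bk)
      v1 <- rowSums(p1$Pn * p1$Bk^2) - m1^2
      ok <- is.finite(m1) & is.finite(v1) & v1 > 1e-14
      ctr <- ifelse(ok, m1, md$b)
      sc <- ifelse(ok, sqrt(pmax(v1, 1e-14)), md$sigma)
    } else {
      ctr <- numeric(N); sc <- rep(tau, N)
    }
    p2 <- agq_pass(ctr, sc, want_grad)
    if (!is.finite(p2$value)) return(bad)
    list(value = p2$value, grad = p2$grad)
  }

  last <- new.env(parent = emptyenv())
  last$theta <- NULL
  memo <- function(theta) {
    if (!is.null(last$theta) && identical(theta, last$theta) &&
        !is.null(last$res$grad)) return(last$res)
    res <- compute(theta, want_grad = TRUE)
    last$theta <- theta; last$res <- res
    res
  }
  list(fn = function(theta) compute(theta)$value,
       fn_gr = function(theta) memo(theta)$value,
       gr = function(theta) memo(theta)$grad,
       state = state)
}

## cross-sectional beta regression ignoring clustering (starting values)
beta_reg_xs <- function(X, y, maxit = 300) {
  b0 <- qr.solve(X, log(y) - log1p(-y))
  mu0 <- stats::plogis(drop(X %*% b0))
  v <- stats::var(y - mu0)
  phi0 <- max(mean(mu0 * (1 - mu0)) / max(v, 1e-10) - 1, 0.5)
  par0 <- c(b0, log(phi0))
  p <- ncol(X)
  negll <- function(th) {
    mu <- stats::plogis(drop(X %*% th[seq_len(p)]))
    -sum(ldbeta_mu(y, mu, exp(th[p + 1L])))
  }
  grad <- function(th) {
    mu <- stats::plogis(drop(X %*% th[seq_len(p)]))
    phi <- exp(th[p + 1L])
    s <- log(y) - log1p(-y) - digamma(mu * phi) + digamma((1 - mu) * phi)
    gb <- drop(crossprod(X, phi * mu * (1 - mu) * s))
    gp <- sum(digamma(phi) - mu * digamma(mu * phi) -
                (1 - mu) * digamma((1 - mu) * phi) +
                mu * log(y) + (1 - mu) * log1p(-y)) * phi
    -c(gb, gp)
  }
  opt <- stats::optim(par0, negll, grad, method = "BFGS",
                      control = list(maxit = maxit, reltol = 1e-10))
  list(beta = unname(opt$par[seq_len(p)]), phi = unname(exp(opt$par[p + 1L])),
       loglik = -opt$value)
}

#' Marginal log-likelihood of the beta GLMM
#'
#' Evaluates, at user-supplied parameter values, the marginal
#' log-likelihood obtained by integrating the logit-scale random intercept
#' out of the beta likelihood subject by subject:
#' \deqn{\ell = \sum_i \log \int \prod_j f\{y_{ij};
#'   \mathrm{logit}^{-1}(x_{ij}'\beta + b), \phi\}\,
#'   \varphi(b; 0, \tau^2)\, db,}
#' each integral approximated by Gauss-Hermite quadrature, by default
#' adaptively recentered at the subject's posterior mode.
#'
#' @inheritParams lmm_ml
#' @param beta fixed-effect coefficient vector (design-matrix order; see
#'   [build_design()]).
#' @param phi beta precision, positive.
#' @param tau2 random-intercept variance, non-negative (`0` gives the
#'   independent beta log-likelihood).
#' @param nodes number of quadrature nodes (>= 3; default 21).
#' @param adaptive recenter/scale nodes at per-subject posterior modes
#'   (default `TRUE`); `FALSE` uses nodes scaled by the prior SD only.
#' @return log-likelihood value.
#' @export
marginal_loglik <- function(formula, data, subject, beta, phi, tau2,
                            nodes = 21L, adaptive = TRUE,
                            boundary = c("shift", "compress", "none"),
                            epsilon = 0.005) {
  boundary <- match.arg(boundary)
  stopifnot(phi > 0, tau2 >= 0)
  des <- build_design(formula, as.data.frame(data), subject)
  y <- boundary_transform(des$y, boundary, epsilon)
  if (any(y <= 0 | y >= 1))
    stop("responses must lie strictly inside (0, 1) after the boundary ",
         "transform", call. = FALSE)
  if (length(beta) != ncol(des$X))
    stop("beta has length ", length(beta), " but the design has ",
         ncol(des$X), " columns", call. = FALSE)
  eng <- agq_engine(des$X, y, des$id, nodes = nodes, adaptive = adaptive)
  eng$fn(c(beta, log(phi), log(max(sqrt(tau2), 1e-8))))
}

#' Subject-specific beta regression (beta GLMM) for longitudinal bounded
#' outcomes
#'
#' Fits the logit-link beta generalized linear mixed model
#' `logit(mu_ij) = x_ij' beta + b_i`, `b_i ~ N(0, tau2)`, with constant
#' precision `phi`, by maximum likelihood.  The marginal likelihood is
#' approximated by adaptive Gauss-Hermite quadrature (default 21 nodes);
#' optimization runs over the unconstrained parameterization
#' `(beta, log phi, log tau)` — a short Nelder-Mead warm-up followed by
#' BFGS — and standard errors come from the numerically differentiated
#' observed information at the optimum.
#'
#' Coefficients have a subject-specific interpretation: they describe
#' within-individual change on the logit scale, holding the individual's
#' random intercept fixed; `logit(E(Y_ij))` is *not* `x_ij' beta` (see
#' `predict(..., level = "population")`, which integrates over the random
#' effect).  Exponentiated coefficients are odds ratios on
#' `mu / (1 - mu)`; see [odds_ratio_table()].
#'
#' Starting values: `beta` and `phi` from a cross-sectional beta regression
#' ignoring clustering; `tau` from a moment decomposition of logit-scale
#' residuals.  `tau` is floored at `1e-6` (SD scale); an estimate at the
#' floor is flagged as a boundary fit.
#'
#' @inheritParams lmm_ml
#' @param nodes quadrature nodes (default 21).
#' @param adaptive adaptive (posterior-mode-centered) quadrature, default
#'   `TRUE`.
#' @param control list of optimizer settings: `nm_iter` (Nelder-Mead
#'   warm-up iterations, default 50), `maxit` (BFGS iterations, 200),
#'   `reltol` (relative log-likelihood tolerance, 1e-9).
#' @param hessian compute the observed-information covariance (default
#'   `TRUE`; disable for speed inside simulations).
#' @return object of class `"beta_glmm"` with components `coefficients`,
#'   `phi`, `tau2` (plus delta-method SEs), `loglik`, `aic`, `bic`,
#'   `pseudo_r2`, full-parameter covariance `vcov_all`, empirical-Bayes
#'   modes `eb_modes`, fitted values at both levels, quadrature settings,
#'   convergence information, and the design metadata needed by `predict`.
#' @seealso [marginal_loglik()], [lmm_ml()], [betagee()]
#' @examples
#' sim <- simulate_panel(preset_config("kora_like", n_subjects = 150))
#' fit <- betaglmm(y ~ age + sex + time + diab + diab:time, sim$data,
#'                 subject = "subject_id", hessian = FALSE)
#' coef(fit)
#' @export
betaglmm <- function(formula, data, subject, nodes = 21L, adaptive = TRUE,
                     boundary = c("shift", "compress", "none"),
                     epsilon = 0.005, control = list(), hessian = TRUE) {
  boundary <- match.arg(boundary)
  ctl <- list(nm_iter = 50L, maxit = 200L, reltol = 1e-9)
  ctl[names(control)] <- control
  cl <- match.call()

  dropped <- drop_incomplete(data, formula)
  d <- as.data.frame(dropped$data)
  des <- build_design(formula, d, subject)
  check_full_rank(des$X)
  y <- boundary_transform(des$y, boundary, epsilon)
  if (any(y <= 0 | y >= 1))
    stop("responses at the boundary remain after the '", boundary,
         "' transform; use boundary = \"shift\" or \"compress\"",
         call. = FALSE)
  p <- ncol(des$X)
  if (length(y) < p + 2L)
    stop("need at least p + 2 rows to fit", call. = FALSE)

  ## starting values
  xs <- beta_reg_xs(des$X, y)
  eta0 <- drop(des$X %*% xs$beta)
  r <- (log(y) - log1p(-y)) - eta0
  mi <- rowsum(r, des$id)[, 1L] / tabulate(as.integer(des$id))
  ni <- tabulate(as.integer(des$id))
  vw <- stats::var(r - mi[as.integer(des$id)])
  tau2_0 <- max(stats::var(mi) - vw / mean(ni), 0.02)
  theta0 <- c(xs$beta, log(xs$phi), 0.5 * log(tau2_0))

  eng <- agq_engine(des$X, y, des$id, nodes = nodes, adaptive = adaptive)
  negll <- function(th) -eng$fn_gr(th)
  neggrad <- function(th) {
    g <- -eng$gr(th)
    if (!all(is.finite(g))) g <- rep(0, length(th))  # penalty plateau
    g
  }
  o1 <- stats::optim(theta0, function(th) -eng$fn(th),
                     method = "Nelder-Mead",
                     control = list(maxit = ctl$nm_iter))
  ## quasi-Newton stage with finite-difference gradients, box-bounded on
  ## the log-scale nuisance parameters; restarted until the log-likelihood
  ## is stationary (a single run can satisfy its tolerance prematurely
  ## when the problem is poorly scaled at the warm-up point)
  lower <- c(rep(-30, p), -5, -8)
  upper <- c(rep(30, p), 12, 4)
  par <- pmin(pmax(o1$par, lower), upper)
  val <- negll(par)
  for (rs in 1:10) {
    o2 <- stats::nlminb(par, negll, gradient = neggrad,
                        lower = lower, upper = upper,
                        control = list(iter.max = ctl$maxit,
                                       eval.max = 4L * ctl$maxit,
                                       rel.tol = ctl$reltol))
    if (o2$objective > val + 1e-8) break   # keep the better iterate
    improved <- val - o2$objective
    par <- o2$par; val <- o2$objective
    if (improved < 1e-7 * (abs(val) + 1)) break
  }
  if (!is.finite(val) || val >= 1e9)
    stop("beta GLMM optimization failed to find a finite optimum; ",
         "message: ", o2$message, call. = FALSE)
  th <- par
  ll <- -val
  beta <- stats::setNames(th[seq_len(p)], colnames(des$X))
  phi <- unname(exp(th[p + 1L]))
  tau <- unname(max(exp(th[p + 2L]), 1e-6))
  tau_boundary <- th[p + 2L] <= lower[p + 2L] + 1e-6

  ## observed-information covariance on (beta, log phi, log tau), from a
  ## central-difference Jacobian of the analytic gradient
  vcov_all <- matrix(NA_real_, p + 2L, p + 2L)
  if (hessian) {
    hstep <- 1e-5 * pmax(1, abs(th))
    J <- matrix(NA_real_, p + 2L, p + 2L)
    for (j in seq_len(p + 2L)) {
      ej <- numeric(p + 2L); ej[j] <- hstep[j]
      J[, j] <- (neggrad(th + ej) - neggrad(th - ej)) / (2 * hstep[j])
    }
    H <- (J + t(J)) / 2
    Vt <- try(solve(H), silent = TRUE)
    if (!inherits(Vt, "try-error") && all(is.finite(Vt)))
      vcov_all <- Vt
    else warning("observed information not invertible; ",
                 "standard errors unavailable")
  }
  dimnames(vcov_all) <- list(c(names(beta), "log_phi", "log_tau"),
                             c(names(beta), "log_phi", "log_tau"))
  se_beta <- sqrt(pmax(diag(vcov_all)[seq_len(p)], 0))
  phi_se <- phi * sqrt(max(vcov_all[p + 1L, p + 1L], 0))
  tau2_se <- 2 * tau^2 * sqrt(max(vcov_all[p + 2L, p + 2L], 0))

  ## empirical-Bayes modes and fitted values at the optimum
  eng_final <- agq_engine(des$X, y, des$id, nodes = nodes, adaptive = TRUE)
  invisible(eng_final$fn(th))
  eb <- eng_final$state$modes
  names(eb) <- levels(des$id)
  eta_fix <- drop(des$X %*% beta)
  fitted_sub <- stats::plogis(eta_fix + eb[as.integer(des$id)])
  fitted_pop <- glmm_pop_mean(eta_fix, tau)

  base_ll <- baseline_loglik(y, des$id)
  n_par <- p + 2L
  ic <- info_criteria(ll, n_par, nlevels(des$id))

  out <- list(call = cl, coefficients = beta, se = se_beta,
              phi = phi, phi_se = phi_se,
              tau2 = tau^2, tau2_se = tau2_se,
              tau_boundary = tau_boundary,
              loglik = ll, aic = ic[["AIC"]], bic = ic[["BIC"]],
              n_par = n_par,
              pseudo_r2 = pseudo_r2(ll, base_ll, length(y)),
              baseline_loglik = base_ll,
              vcov_all = vcov_all,
              eb_modes = eb, y = y, id = des$id,
              fitted_subject = unname(fitted_sub),
              fitted_population = unname(fitted_pop),
              n_obs = length(y), n_subjects = nlevels(des$id),
              n_missing_response = dropped$n_missing_response,
              n_missing_covariate = dropped$n_missing_covariate,
              quad = list(nodes = nodes, adaptive = adaptive),
              boundary = boundary, epsilon = epsilon,
              optim = list(nm = o1$counts, bfgs = o2$counts,
                           convergence = o2$convergence),
              formula = formula, subject = subject,
              terms = des$terms, xlevels = des$xlevels,
              contrasts = des$contrasts,
              data_means = numeric_var_means(des$terms, d))
  class(out) <- "beta_glmm"
  out
}

## population-averaged mean E(Y | x) = int plogis(eta + b) dN(b; 0, tau2),
## by (non-adaptive) Gauss-Hermite; the integrand is bounded and smooth
glmm_pop_mean <- function(eta, tau, nodes = 41L) {
  if (tau < 1e-7) return(stats::plogis(eta))
  gh <- pracma::gaussHermite(nodes)
  drop(stats::plogis(outer(eta, sqrt(2) * tau * gh$x, `+`)) %*% gh$w) /
    sqrt(pi)
}

#' @export
coef.beta_glmm <- function(object, ...) object$coefficients

#' @export
vcov.beta_glmm <- function(object, full = FALSE, ...) {
  if (full) object$vcov_all
  else object$vcov_all[seq_along(object$coefficients),
                       seq_along(object$coefficients), drop = FALSE]
}

#' @export
logLik.beta_glmm <- function(object, ...)
  structure(object$loglik, df = object$n_par, nobs = object$n_obs,
            class = "logLik")

#' @export
residuals.beta_glmm <- function(object,
                                level = c("subject", "population"), ...) {
  level <- match.arg(level)
  object$y - switch(level, subject = object$fitted_subject,
                    population = object$fitted_population)
}

#' Predictions from a fitted beta GLMM
#'
#' Subject-level predictions are `plogis(x' beta + b_i)` with the
#' empirical-Bayes mode of the matching subject and always lie strictly
#' inside `(0, 1)`.  Population-level predictions integrate the inverse
#' logit over the random-effect distribution by quadrature — note that this
#' is *not* `plogis(x' beta)` unless `tau2 = 0`.
#'
#' @param object a `"beta_glmm"` fit.
#' @param newdata optional data frame; defaults to the training rows.
#' @param level `"subject"` or `"population"`.
#' @param nodes quadrature nodes for the population mean.
#' @param ... unused.
#' @return numeric vector of predictions in `(0, 1)`.
#' @export
predict.beta_glmm <- function(object, newdata = NULL,
                              level = c("subject", "population"),
                              nodes = 41L, ...) {
  level <- match.arg(level)
  if (is.null(newdata)) {
    return(switch(level, subject = object$fitted_subject,
                  population = object$fitted_population))
  }
  X <- design_for_newdata(object, newdata)
  eta <- drop(X %*% object$coefficients)
  if (level == "subject") {
    ids <- as.character(newdata[[object$subject]])
    unknown <- setdiff(unique(ids), names(object$eb_modes))
    if (length(unknown))
      stop("subject(s) not in the fitted data: ",
           paste(utils::head(unknown, 5L), collapse = ", "), call. = FALSE)
    stats::plogis(unname(eta + object$eb_modes[ids]))
  } else {
    unname(glmm_pop_mean(eta, sqrt(object$tau2), nodes = nodes))
  }
}

#' @export
print.beta_glmm <- function(x, digits = 4, ...) {
  cat("Beta GLMM (logit link, random intercept, adaptive GH quadrature,",
      x$quad$nodes, "nodes)\n")
  cat("  subjects:", x$n_subjects, " observations:", x$n_obs, "\n")
  print(round(x$coefficients, digits))
  cat("  phi:", format(x$phi, digits = digits),
      " tau2:", format(x$tau2, digits = digits),
      if (x$tau_boundary) " (at boundary)" else "", "\n")
  cat("  -2 logLik:", format(-2 * x$loglik, digits = 6),
      " AIC:", format(x$aic, digits = 6),
      " BIC:", format(x$bic, digits = 6), "\n")
  invisible(x)
}

#' @export
summary.beta_glmm <- function(object, ...) {
  z <- object$coefficients / object$se
  tab <- cbind(Estimate = object$coefficients, `Std. Error` = object$se,
               `z value` = z, `Pr(>|z|)` = 2 * stats::pnorm(-abs(z)))
  structure(list(fit = object, coefficients = tab),
            class = "summary.beta_glmm")
}

#' @export
print.summary.beta_glmm <- function(x, digits = 4, ...) {
  f <- x$fit
  cat("Beta GLMM (logit link, random intercept; ML by adaptive",
      "Gauss-Hermite quadrature)\n")
  cat("Formula:", deparse(f$formula), "  subject:", f$subject, "\n")
  cat("Subjects:", f$n_subjects, "  Observations:", f$n_obs,
      "  Quadrature nodes:", f$quad$nodes, "\n")
  if (f$n_missing_response + f$n_missing_covariate > 0)
    cat("Rows deleted for missingness: response", f$n_missing_response,
        ", covariate", f$n_missing_covariate, "\n")
  cat("\n")
  stats::printCoefmat(x$coefficients, digits = digits, P.values = TRUE,
                      has.Pvalue = TRUE)
  cat("\nPrecision phi:", format(f$phi, digits = digits),
      " (SE", format(f$phi_se, digits = 3), ")\n")
  cat("Random-intercept variance tau2:", format(f$tau2, digits = digits),
      " (SE", format(f$tau2_se, digits = 3), ")",
      if (f$tau_boundary) "  [estimate at lower boundary]" else "", "\n")
  cat("-2 logLik:", format(-2 * f$loglik, digits = 6),
      "  AIC:", format(f$aic, digits = 6),
      "  BIC:", format(f$bic, digits = 6), "\n")
  cat("Pseudo-R2 (vs random-intercept-only LMM):",
      format(f$pseudo_r2, digits = 4), "\n")
  invisible(x)
}
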