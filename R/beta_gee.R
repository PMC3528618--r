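## ---------------------------------------------------------------------------
## Beta GEE: population-averaged logit-link model with working variance
## Var(Y_ij | x_ij) = phi * mu_ij * (1 - mu_ij) and a working correlation
## (independence, exchangeable, AR-1, unstructured), solved by the
## moment-based estimating-equation iteration of Liang and Zeger:
##   sum_i D_i' V_i^{-1} (y_i - mu_i) = 0,
## alternating a Fisher-scoring beta update with moment re-estimation of
## the scale phi and correlation alpha from Pearson residuals.
## ---------------------------------------------------------------------------

#' Moment estimates of GEE scale and working-correlation parameters
#'
#' From Pearson residuals `r_ij = (y_ij - mu_ij) / sqrt(mu_ij (1 - mu_ij))`:
#' the scale is `sum(r^2) / (n - p)`; the exchangeable alpha averages
#' within-subject cross-products of residuals (standardized by the scale)
#' over all pairs; AR-1 uses adjacent-occasion pairs; unstructured averages
#' each occasion pair separately.  Subjects with a single row contribute to
#' the scale but not to alpha.
#'
#' @param r numeric vector of Pearson residuals.
#' @param id subject factor, same length as `r`.
#' @param structure `"independence"`, `"exchangeable"`, `"ar1"` or
#'   `"unstructured"`.
#' @param p number of regression parameters (subtracted from the degrees of
#'   freedom).
#' @param occ integer occasion positions within subject (needed for
#'   `"ar1"`/`"unstructured"`); defaults to row order within subject.
#' @return list with `scale` and `alpha` (scalar, or matrix for
#'   `"unstructured"`).
#' @export
estimate_scale_alpha <- function(r, id,
                                 structure = c("exchangeable",
                                               "independence", "ar1",
                                               "unstructured"),
                                 p = 0L, occ = NULL) {
  structure <- match.arg(structure)
  id <- droplevels(factor(id))
  n <- length(r)
  scale <- sum(r^2) / max(n - p, 1L)
  if (scale <= 0) {
    warning("degenerate fit: all Pearson residuals are zero")
    return(list(scale = 0, alpha = if (structure == "unstructured")
      matrix(NA_real_, 0L, 0L) else 0))
  }
  if (is.null(occ)) occ <- stats::ave(seq_len(n), id, FUN = seq_along)
  rs <- split(r, id)
  os <- split(occ, id)
  if (structure == "independence")
    return(list(scale = scale, alpha = 0))
  if (structure == "exchangeable") {
    num <- 0; npair <- 0L
    for (k in seq_along(rs)) {
      ri <- rs[[k]]; ni <- length(ri)
      if (ni < 2L) next
      num <- num + (sum(ri)^2 - sum(ri^2)) / 2
      npair <- npair + (ni * (ni - 1L)) %/% 2L
    }
    if (npair <= p)
      stop("too few within-subject pairs to estimate exchangeable alpha",
           call. = FALSE)
    return(list(scale = scale, alpha = num / ((npair - p) * scale)))
  }
  if (structure == "ar1") {
    num <- 0; npair <- 0L
    for (k in seq_along(rs)) {
      ri <- rs[[k]]; oi <- os[[k]]
      if (length(ri) < 2L) next
      ri <- ri[order(oi)]; oi <- sort(oi)
      lag1 <- which(diff(oi) == 1L)
      if (!length(lag1)) next
      num <- num + sum(ri[lag1] * ri[lag1 + 1L])
      npair <- npair + length(lag1)
    }
    if (npair <= p)
      stop("too few lag-1 pairs to estimate AR-1 alpha", call. = FALSE)
    return(list(scale = scale, alpha = num / ((npair - p) * scale)))
  }
  ## unstructured: per-occasion-pair averages
  T_ <- max(occ)
  num <- matrix(0, T_, T_); cnt <- matrix(0L, T_, T_)
  for (k in seq_along(rs)) {
    ri <- rs[[k]]; oi <- os[[k]]
    if (length(ri) < 2L) next
    for (a in seq_along(oi)) for (b in seq_along(oi)) if (a < b) {
      num[oi[a], oi[b]] <- num[oi[a], oi[b]] + ri[a] * ri[b]
      cnt[oi[a], oi[b]] <- cnt[oi[a], oi[b]] + 1L
    }
  }
  if (any(cnt[upper.tri(cnt)] == 0L))
    stop("some occasion pairs have no joint observations; ",
         "unstructured alpha not estimable", call. = FALSE)
  A <- num / pmax(cnt - p, 1L) / scale
  A <- A + t(A); diag(A) <- 1
  list(scale = scale, alpha = A)
}

## working correlation matrix for one subject's occasion positions
working_corr <- function(structure, alpha, oi) {
  ni <- length(oi)
  if (structure == "independence" || ni == 1L) return(diag(ni))
  R <- switch(structure,
              exchangeable = matrix(alpha, ni, ni),
              ar1 = alpha^abs(outer(oi, oi, `-`)),
              unstructured = alpha[oi, oi, drop = FALSE])
  diag(R) <- 1
  R
}

#' Population-averaged beta GEE for longitudinal bounded outcomes
#'
#' Solves the generalized estimating equations for a marginal logit-link
#' model with beta-type working variance `phi * mu * (1 - mu)` and a chosen
#' working correlation.  Coefficients have a population-averaged
#' interpretation — the effect of a covariate on the mean score in the
#' population, not within an individual — which is what adjusted group
#' means are built from (see [adjusted_means()]).  Robust standard errors
#' come from the sandwich estimator `A^{-1} M A^{-1}`; model-based ones are
#' also stored.  The scale `phi` here is a GEE dispersion (working
#' `Var(Y|x) = phi mu (1 - mu)`), *not* the beta-family precision of
#' [betaglmm()]; a large estimate can indicate unmodelled heterogeneity.
#'
#' No beta likelihood is evaluated, so boundary values are not intrinsically
#' a problem for the GEE; the boundary transform is nevertheless applied by
#' default for consistency with the likelihood-based fits (disable with
#' `boundary = "none"`).  Inference from the GEE requires MCAR missingness,
#' in contrast to the MAR-valid likelihood fits.
#'
#' @inheritParams lmm_ml
#' @param corstr working correlation structure: `"exchangeable"`
#'   (compound symmetry, the default — identical to AR-1 with only two
#'   occasions), `"independence"`, `"ar1"`, `"unstructured"`.
#' @param occasion optional name of the occasion column used to order and
#'   align rows within subject for `"ar1"`/`"unstructured"`; defaults to row
#'   order within subject.
#' @param max_iter maximum scoring iterations (default 50).
#' @param tol convergence tolerance on `max |delta beta|` (default 1e-8).
#' @return object of class `"betagee"` with `coefficients`, `scale`,
#'   `alpha`, `corstr`, `vcov_sandwich`, `vcov_model`, fitted means,
#'   iteration count and convergence flag, plus design metadata.
#' @examples
#' sim <- simulate_panel(preset_config("kora_like", n_subjects = 200))
#' fit <- betagee(y ~ age + sex + time + diab + diab:time, sim$data,
#'                subject = "subject_id")
#' summary(fit)
#' @export
betagee <- function(formula, data, subject,
                    corstr = c("exchangeable", "independence", "ar1",
                               "unstructured"),
                    occasion = NULL,
                    boundary = c("shift", "compress", "none"),
                    epsilon = 0.005, max_iter = 50L, tol = 1e-8) {
  corstr <- match.arg(corstr)
  boundary <- match.arg(boundary)
  cl <- match.call()
  dropped <- drop_incomplete(data, formula)
  d <- as.data.frame(dropped$data)
  des <- build_design(formula, d, subject)
  check_full_rank(des$X)
  y <- boundary_transform(des$y, boundary, epsilon)
  if (any(y < 0 | y > 1))
    stop("responses must lie in [0, 1]", call. = FALSE)
  X <- des$X; id <- des$id
  n <- length(y); p <- ncol(X)

  if (is.null(occasion)) {
    occ <- stats::ave(seq_len(n), id, FUN = seq_along)
  } else {
    if (!occasion %in% names(d))
      stop("occasion column '", occasion, "' not found", call. = FALSE)
    of <- d[[occasion]]
    if (!is.factor(of)) of <- factor(of, levels = unique(of))
    occ <- as.integer(of)
  }
  rows_by_id <- split(seq_len(n), id)

  beta <- qr.solve(X, log(pmin(pmax(y, 0.01), 0.99)) -
                     log1p(-pmin(pmax(y, 0.01), 0.99)))
  alpha <- 0; scale <- 1
  conv <- FALSE; it <- 0L
  for (it in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    mu <- stats::plogis(eta)
    a <- mu * (1 - mu)
    r <- (y - mu) / sqrt(a)
    if (corstr != "independence" && max(lengths(rows_by_id)) < 2L) {
      # no within-subject pairs: alpha is inestimable, fall back to the
      # identity working correlation (beta is then correlation-free anyway)
      sa <- list(scale = sum(r^2) / max(n - p, 1L), alpha = 0)
      if (corstr == "unstructured") sa$alpha <- diag(1L)
    } else {
      sa <- estimate_scale_alpha(r, id, corstr, p = p, occ = occ)
    }
    scale <- sa$scale; alpha <- sa$alpha
    alpha <- clip_alpha(alpha, corstr, rows_by_id)

    A_mat <- matrix(0, p, p); U <- numeric(p)
    for (k in seq_along(rows_by_id)) {
      ix <- rows_by_id[[k]]
      Ri <- working_corr(corstr, alpha, occ[ix])
      sai <- sqrt(a[ix])
      Xi <- X[ix, , drop = FALSE] * sai        # D_i scaled: V^-1/2-friendly
      Rinv <- solve(Ri)
      W <- Rinv / scale
      A_mat <- A_mat + crossprod(Xi, W %*% Xi)
      U <- U + drop(crossprod(Xi, W %*% r[ix]))
    }
    delta <- solve(A_mat, U)
    beta <- beta + delta
    if (max(abs(delta)) < tol) { conv <- TRUE; break }
  }
  if (!conv)
    stop("beta GEE did not converge in ", max_iter, " iterations; last ",
         "max |delta beta| = ", format(max(abs(delta))), call. = FALSE)

  ## covariance at the solution
  eta <- drop(X %*% beta); mu <- stats::plogis(eta)
  a <- mu * (1 - mu); r <- (y - mu) / sqrt(a)
  A_mat <- matrix(0, p, p); M <- matrix(0, p, p)
  for (k in seq_along(rows_by_id)) {
    ix <- rows_by_id[[k]]
    Ri <- working_corr(corstr, alpha, occ[ix])
    sai <- sqrt(a[ix])
    Xi <- X[ix, , drop = FALSE] * sai
    W <- solve(Ri) / scale
    A_mat <- A_mat + crossprod(Xi, W %*% Xi)
    u_i <- drop(crossprod(Xi, W %*% r[ix]))
    M <- M + tcrossprod(u_i)
  }
  Ainv <- solve(A_mat)
  vcov_sand <- Ainv %*% M %*% Ainv
  dimnames(vcov_sand) <- dimnames(Ainv) <- list(colnames(X), colnames(X))

  beta <- stats::setNames(beta, colnames(X))
  out <- list(call = cl, coefficients = beta,
              scale = scale, alpha = alpha, corstr = corstr,
              vcov_sandwich = vcov_sand, vcov_model = Ainv,
              n_iter = it, converged = conv,
              y = y, id = id, fitted_population = unname(mu),
              fitted_subject = unname(mu),
              loglik = NA_real_, aic = NA_real_, bic = NA_real_,
              pseudo_r2 = NA_real_,
              n_obs = n, n_subjects = nlevels(id),
              n_missing_response = dropped$n_missing_response,
              n_missing_covariate = dropped$n_missing_covariate,
              boundary = boundary, epsilon = epsilon,
              formula = formula, subject = subject,
              terms = des$terms, xlevels = des$xlevels,
              contrasts = des$contrasts,
              data_means = numeric_var_means(des$terms, d),
              model_frame = d[, intersect(union(all.vars(formula), subject),
                                          names(d)), drop = FALSE])
  class(out) <- "betagee"
  out
}

## keep the implied working correlation positive definite
clip_alpha <- function(alpha, corstr, rows_by_id) {
  if (corstr == "exchangeable") {
    nmax <- max(lengths(rows_by_id))
    lo <- -1 / max(nmax - 1L, 1L) + 1e-6
    min(max(alpha, lo), 0.999)
  } else if (corstr == "ar1") {
    min(max(alpha, -0.999), 0.999)
  } else alpha
}

#' @export
coef.betagee <- function(object, ...) object$coefficients

#' Covariance of beta GEE coefficients
#'
#' @param object a `"betagee"` fit.
#' @param type `"sandwich"` (robust, default) or `"model"` (model-based).
#' @param ... unused.
#' @return covariance matrix.
#' @export
vcov.betagee <- function(object, type = c("sandwich", "model"), ...) {
  type <- match.arg(type)
  switch(type, sandwich = object$vcov_sandwich, model = object$vcov_model)
}

#' @export
residuals.betagee <- function(object, type = c("response", "pearson"), ...) {
  type <- match.arg(type)
  r <- object$y - object$fitted_population
  if (type == "pearson")
    r <- r / sqrt(object$fitted_population * (1 - object$fitted_population))
  r
}

#' @export
predict.betagee <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$fitted_population)
  X <- design_for_newdata(object, newdata)
  unname(stats::plogis(drop(X %*% object$coefficients)))
}

#' @export
print.betagee <- function(x, digits = 4, ...) {
  cat("Beta GEE (logit link,", x$corstr, "working correlation)\n")
  cat("  subjects:", x$n_subjects, " observations:", x$n_obs,
      " iterations:", x$n_iter, "\n")
  print(round(x$coefficients, digits))
  cat("  scale:", format(x$scale, digits = digits))
  if (x$corstr %in% c("exchangeable", "ar1"))
    cat("  alpha:", format(x$alpha, digits = digits))
  cat("\n")
  invisible(x)
}

#' @export
summary.betagee <- function(object, ...) {
  se <- sqrt(diag(object$vcov_sandwich))
  z <- object$coefficients / se
  tab <- cbind(Estimate = object$coefficients, `Robust SE` = se,
               `z value` = z, `Pr(>|z|)` = 2 * stats::pnorm(-abs(z)))
  structure(list(fit = object, coefficients = tab),
            class = "summary.betagee")
}

#' @export
print.summary.betagee <- function(x, digits = 4, ...) {
  f <- x$fit
  cat("Beta GEE (logit link; working variance phi * mu * (1 - mu))\n")
  cat("Formula:", deparse(f$formula), "  subject:", f$subject, "\n")
  cat("Subjects:", f$n_subjects, "  Observations:", f$n_obs,
      "  Working correlation:", f$corstr, "\n\n")
  stats::printCoefmat(x$coefficients, digits = digits, P.values = TRUE,
                      has.Pvalue = TRUE)
  cat("\nScale (GEE dispersion):", format(f$scale, digits = digits), "\n")
  if (f$corstr %in% c("exchangeable", "ar1"))
    cat("Working correlation alpha:", format(f$alpha, digits = digits), "\n")
  cat("(standard errors from the sandwich estimator;",
      "likelihood-based fit statistics are not defined for GEE)\n")
  invisible(x)
}

#' Adjusted marginal means by stratum
#'
#' Model-based group means at a standardized covariate profile, with
#' confidence intervals.  For each combination of the levels of the factors
#' in `by`, the linear predictor is evaluated at a profile in which factors
#' not in `by` are averaged with equal weight over their levels and
#' continuous covariates are fixed at their sample mean
#' (`policy = "equal"`, the least-squares-means convention).  The
#' alternative `policy = "observed"` averages per-row predictions on the
#' response scale over the analyzed rows, with each row's `by` factors set
#' to the stratum.
#'
#' For the logit-link GEE the interval is computed on the linear-predictor
#' scale from the sandwich covariance and back-transformed, so its
#' endpoints always lie inside `(0, 1)` and the interval is asymmetric away
#' from 0.5.  For the Gaussian LMM the identity scale is used.
#'
#' @param fit a `"betagee"` or `"lmm_ml"` fit.
#' @param by character vector of factor names to stratify by (e.g.
#'   `c("time", "diab")`).
#' @param policy `"equal"` or `"observed"` covariate-averaging policy.
#' @param conf_level confidence level (default 0.95, normal critical
#'   value).
#' @param ... unused.
#' @return data frame of class `"marginal_means"`: one row per stratum with
#'   `estimate`, `ci_low`, `ci_high` and the linear-scale `se`.
#' @export
adjusted_means <- function(fit, by, policy = c("equal", "observed"),
                           conf_level = 0.95, ...) {
  UseMethod("adjusted_means")
}

adjusted_means_core <- function(fit, by, policy, conf_level, V, linkinv,
                                dlinkinv) {
  policy <- match.arg(policy, c("equal", "observed"))
  xlev <- fit$xlevels
  bad <- setdiff(by, names(xlev))
  if (length(bad))
    stop("not model factors: ", paste(bad, collapse = ", "), call. = FALSE)
  grid_by <- expand.grid(xlev[by], stringsAsFactors = TRUE)
  tt <- stats::delete.response(fit$terms)
  zc <- stats::qnorm(1 - (1 - conf_level) / 2)
  beta <- fit$coefficients
  rows <- lapply(seq_len(nrow(grid_by)), function(g) {
    if (policy == "equal") {
      other <- setdiff(names(xlev), by)
      prof <- expand.grid(c(lapply(grid_by[g, , drop = FALSE], as.character),
                            xlev[other]), stringsAsFactors = FALSE)
      for (v in names(xlev)) prof[[v]] <- factor(prof[[v]], levels = xlev[[v]])
      for (v in names(fit$data_means)) prof[[v]] <- fit$data_means[[v]]
      mm <- stats::model.matrix(tt, stats::model.frame(tt, prof,
                                                       xlev = xlev),
                                contrasts.arg = fit$contrasts)
      L <- colMeans(mm)
      eta <- sum(L * beta)
      se <- sqrt(drop(t(L) %*% V %*% L))
      c(estimate = linkinv(eta), ci_low = linkinv(eta - zc * se),
        ci_high = linkinv(eta + zc * se), se_linear = se)
    } else {
      prof <- fit$model_frame
      for (v in by) prof[[v]] <- factor(as.character(grid_by[g, v]),
                                        levels = xlev[[v]])
      mm <- stats::model.matrix(tt, stats::model.frame(tt, prof,
                                                       xlev = xlev),
                                contrasts.arg = fit$contrasts)
      eta_r <- drop(mm %*% beta)
      est <- mean(linkinv(eta_r))
      gr <- colMeans(dlinkinv(eta_r) * mm)
      se <- sqrt(drop(t(gr) %*% V %*% gr))
      c(estimate = est, ci_low = est - zc * se, ci_high = est + zc * se,
        se_linear = NA_real_)
    }
  })
  out <- cbind(grid_by, do.call(rbind, rows))
  class(out) <- c("marginal_means", "data.frame")
  attr(out, "by") <- by
  attr(out, "conf_level") <- conf_level
  out
}

#' @rdname adjusted_means
#' @export
adjusted_means.betagee <- function(fit, by, policy = c("equal", "observed"),
                                   conf_level = 0.95, ...) {
  policy <- match.arg(policy)
  adjusted_means_core(fit, by, policy, conf_level, fit$vcov_sandwich,
                      stats::plogis, function(e) stats::plogis(e) *
                        (1 - stats::plogis(e)))
}

#' @rdname adjusted_means
#' @export
adjusted_means.lmm_ml <- function(fit, by, policy = c("equal", "observed"),
                                  conf_level = 0.95, ...) {
  policy <- match.arg(policy)
  adjusted_means_core(fit, by, policy, conf_level, fit$vcov_beta,
                      identity, function(e) rep(1, length(e)))
}

#' @export
print.marginal_means <- function(x, digits = 3, ...) {
  cat("Adjusted marginal means (", attr(x, "conf_level") * 100,
      "% CI) by ", paste(attr(x, "by"), collapse = " x "), "\n", sep = "")
  y <- as.data.frame(x)
  num <- vapply(y, is.numeric, logical(1L))
  y[num] <- lapply(y[num], round, digits = digits)
  print(y, row.names = FALSE)
  invisible(x)
}
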