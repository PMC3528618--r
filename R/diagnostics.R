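#' Mean raw residuals across deciles of the linear predictor
#'
#' Ranks observations by their linear predictor, splits them into ten
#' groups of (near-)equal size, and reports the mean raw residual
#' `y - mu_hat` in each group.  For mixed models the linear predictor and
#' fitted mean should be at the subject-specific level.  Means not
#' randomly scattered around zero indicate a systematic misfit — e.g. a
#' positive trend across deciles means the model overestimates the mean at
#' the lower and underestimates it at the upper part of the distribution.
#'
#' Ties in `eta` are broken by original row order after a stable sort, and
#' group sizes differ by at most one when `n` is not divisible by 10.
#'
#' @param y observed responses.
#' @param eta linear predictors (same length).
#' @param mu_hat fitted means (same length).
#' @return data frame of class `"decile_summary"` with columns `decile`,
#'   `n`, `mean_eta`, `mean_residual`.
#' @examples
#' set.seed(1)
#' eta <- rnorm(100); mu <- plogis(eta)
#' decile_residual_summary(mu, eta, mu)  # perfect fit: all means zero
#' @export
decile_residual_summary <- function(y, eta, mu_hat) {
  n <- length(y)
  if (length(eta) != n || length(mu_hat) != n)
    stop("y, eta and mu_hat must have equal length", call. = FALSE)
  if (n < 10L)
    stop("need at least 10 observations for a decile summary", call. = FALSE)
  ord <- order(eta)                    # stable for numeric input
  sizes <- rep(n %/% 10L, 10L) + (seq_len(10L) <= n %% 10L)
  g <- rep.int(seq_len(10L), sizes)
  res <- (y - mu_hat)[ord]
  out <- data.frame(decile = seq_len(10L), n = sizes,
                    mean_eta = as.numeric(tapply(eta[ord], g, mean)),
                    mean_residual = as.numeric(tapply(res, g, mean)))
  class(out) <- c("decile_summary", "data.frame")
  out
}

#' @export
plot.decile_summary <- function(x, ...) {
  graphics::plot(x$decile, x$mean_residual, type = "b", pch = 19,
                 xlab = "decile of linear predictor",
                 ylab = "mean raw residual", ...)
  graphics::abline(h = 0, lty = 3)
  invisible(x)
}

#' Decile residual summary of a fitted model
#'
#' Convenience wrapper computing [decile_residual_summary()] from a fit's
#' subject-specific predictions (population-level for the GEE, which has no
#' subject level).
#'
#' @param fit an `"lmm_ml"`, `"beta_glmm"` or `"betagee"` object.
#' @return a `"decile_summary"` data frame.
#' @export
model_decile_summary <- function(fit) {
  stopifnot(inherits(fit, c("lmm_ml", "beta_glmm", "betagee")))
  mu <- fit$fitted_subject
  eta <- if (inherits(fit, "lmm_ml")) mu else stats::qlogis(mu)
  decile_residual_summary(fit$y, eta, mu)
}

#' Count predictions outside a range
#'
#' Counts predictions strictly below `low` or above `high`.  Subject-level
#' predictions from a Gaussian LMM for a bounded score can leave the
#' admissible range; logit-link predictions never do.
#'
#' @param predictions numeric vector of finite predictions.
#' @param low,high range limits, `low < high`.
#' @return integer count.
#' @examples
#' out_of_range_count(c(-0.1, 0.5, 1.2), 0, 1)  # 2
#' @export
out_of_range_count <- function(predictions, low = 0, high = 1) {
  if (low >= high) stop("low must be smaller than high", call. = FALSE)
  stopifnot(all(is.finite(predictions)))
  sum(predictions < low | predictions > high)
}

#' Side-by-side model comparison table
#'
#' One row per fitted model with `-2 logLik`, AIC, BIC, pseudo-R-squared
#' and the count of subject-level predictions outside `(0, 1)`.  The GEE
#' specifies no full likelihood, so its likelihood-based cells are `NA`.
#' All fits must be on the same observations (same rows, same response
#' values after their boundary transforms).
#'
#' @param ... named fits (`"lmm_ml"`, `"beta_glmm"`, `"betagee"`), or a
#'   single list of them.
#' @return data frame with columns `model`, `neg2LogL`, `AIC`, `BIC`,
#'   `pseudo_R2`, `out_of_range`.
#' @export
comparison_report <- function(...) {
  fits <- list(...)
  if (length(fits) == 1L && is.list(fits[[1L]]) &&
      !inherits(fits[[1L]], c("lmm_ml", "beta_glmm", "betagee")))
    fits <- fits[[1L]]
  if (!length(fits)) stop("no fits given", call. = FALSE)
  ok <- vapply(fits, inherits, logical(1L),
               what = c("lmm_ml", "beta_glmm", "betagee"))
  if (!all(ok)) stop("all arguments must be fitted model objects",
                     call. = FALSE)
  nm <- names(fits)
  if (is.null(nm) || any(nm == ""))
    nm <- vapply(fits, function(f) class(f)[1L], character(1L))
  n0 <- fits[[1L]]$n_obs
  y0 <- fits[[1L]]$y
  for (f in fits) {
    if (f$n_obs != n0 || max(abs(sort(f$y) - sort(y0))) > 1e-12)
      stop("fits are not on the same observations", call. = FALSE)
  }
  rows <- lapply(seq_along(fits), function(k) {
    f <- fits[[k]]
    oor <- out_of_range_count(f$fitted_subject, 0, 1)
    data.frame(model = nm[k],
               neg2LogL = if (is.na(f$loglik)) NA_real_ else -2 * f$loglik,
               AIC = f$aic, BIC = f$bic, pseudo_R2 = f$pseudo_r2,
               out_of_range = oor, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
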