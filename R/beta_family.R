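#' Beta density in mean-precision parameterization
#'
#' Density of the beta distribution written in terms of its mean `mu` and
#' precision `phi`, i.e. with classical shape parameters `a = mu * phi` and
#' `b = (1 - mu) * phi`:
#' \deqn{f(y; \mu, \phi) = \frac{\Gamma(\phi)}{\Gamma(\mu\phi)\,
#'   \Gamma((1-\mu)\phi)} y^{\mu\phi - 1} (1 - y)^{(1-\mu)\phi - 1},
#'   \quad 0 < y < 1.}
#' For fixed `mu`, larger `phi` means smaller variance:
#' `Var(Y) = mu (1 - mu) / (1 + phi)`.  Computed on the log scale via
#' `lgamma()` for stability.
#'
#' @param y values strictly inside `(0, 1)`; a value at the boundary is an
#'   error (apply a boundary transform first, see [epsilon_shift()]).
#' @param mu mean, in `(0, 1)`.
#' @param phi precision, positive.
#' @param log if `TRUE` return the log density.
#' @return density (or log density), recycled over the arguments.
#' @examples
#' dbeta_mu(0.3, 0.5, 2)         # Beta(1, 1): uniform, density 1
#' dbeta_mu(0.8, 0.7, 14.45, log = TRUE)
#' @export
dbeta_mu <- function(y, mu, phi, log = FALSE) {
  if (any(!is.na(y) & (y <= 0 | y >= 1)))
    stop("y must lie strictly inside (0, 1); transform boundary values first",
         call. = FALSE)
  if (any(!is.na(mu) & (mu <= 0 | mu >= 1)) || any(!is.na(phi) & phi <= 0))
    stop("require 0 < mu < 1 and phi > 0", call. = FALSE)
  ll <- lgamma(phi) - lgamma(mu * phi) - lgamma((1 - mu) * phi) +
    (mu * phi - 1) * log(y) + ((1 - mu) * phi - 1) * log1p(-y)
  if (log) ll else exp(ll)
}

## internal: no argument checking, matrix-friendly (mu may be a matrix,
## y a vector recycled down columns)
ldbeta_mu <- function(y, mu, phi) {
  lgamma(phi) - lgamma(mu * phi) - lgamma((1 - mu) * phi) +
    (mu * phi - 1) * log(y) + ((1 - mu) * phi - 1) * log1p(-y)
}

#' Moments of the mean-precision beta distribution
#'
#' @inheritParams dbeta_mu
#' @return list with `mean = mu` and `variance = mu (1 - mu) / (1 + phi)`.
#' @export
beta_moments <- function(mu, phi) {
  stopifnot(all(mu > 0 & mu < 1), all(phi > 0))
  list(mean = mu, variance = mu * (1 - mu) / (1 + phi))
}

#' Fit a univariate beta or normal distribution by maximum likelihood
#'
#' Fits a single density to a sample, for the classic overlay comparison of
#' a bounded left-skewed score distribution against the normal.  Normal
#' estimates are the closed-form sample mean and ML (divisor `n`) variance;
#' beta estimates maximize the likelihood numerically over
#' `(logit(mu), log(phi))`, started from method-of-moments values.
#'
#' @param y numeric sample; for `family = "beta"` all values must lie
#'   strictly inside `(0, 1)`.
#' @param family `"beta"` or `"normal"`.
#' @return object of class `"unifit"`: list with `family`, `estimate`
#'   (named vector: `mu`, `phi` or `mean`, `variance`), `loglik`, `n`,
#'   and the data range.
#' @examples
#' set.seed(1)
#' y <- rbeta(500, 0.8 * 12, 0.2 * 12)
#' fb <- fit_univariate(y, "beta")
#' fn <- fit_univariate(y, "normal")
#' fb$loglik > fn$loglik
#' @export
fit_univariate <- function(y, family = c("beta", "normal")) {
  family <- match.arg(family)
  y <- y[!is.na(y)]
  if (length(y) < 3L) stop("need at least 3 observations", call. = FALSE)
  if (family == "normal") {
    m <- mean(y); v <- mean((y - m)^2)
    ll <- sum(stats::dnorm(y, m, sqrt(v), log = TRUE))
    est <- c(mean = m, variance = v)
  } else {
    if (any(y <= 0 | y >= 1))
      stop("beta family requires all values strictly inside (0, 1)",
           call. = FALSE)
    m <- mean(y); v <- stats::var(y)
    phi0 <- max(m * (1 - m) / max(v, 1e-10) - 1, 0.5)
    par0 <- c(stats::qlogis(m), log(phi0))
    negll <- function(p) {
      mu <- stats::plogis(p[1L]); phi <- exp(p[2L])
      -sum(ldbeta_mu(y, mu, phi))
    }
    grad <- function(p) {
      mu <- stats::plogis(p[1L]); phi <- exp(p[2L])
      dmu <- phi * sum(log(y) - log1p(-y) - digamma(mu * phi) +
                         digamma((1 - mu) * phi))
      dphi <- sum(digamma(phi) - mu * digamma(mu * phi) -
                    (1 - mu) * digamma((1 - mu) * phi) +
                    mu * log(y) + (1 - mu) * log1p(-y))
      -c(dmu * mu * (1 - mu), dphi * phi)
    }
    opt <- stats::optim(par0, negll, grad, method = "BFGS",
                        control = list(maxit = 500, reltol = 1e-12))
    if (opt$convergence != 0)
      stop("beta ML did not converge (optim code ", opt$convergence, ")",
           call. = FALSE)
    est <- c(mu = stats::plogis(opt$par[1L]), phi = exp(opt$par[2L]))
    ll <- -opt$value
  }
  structure(list(family = family, estimate = est, loglik = ll,
                 n = length(y), range = range(y)),
            class = "unifit")
}

#' @export
print.unifit <- function(x, ...) {
  cat("Univariate", x$family, "fit (ML), n =", x$n, "\n")
  print(round(x$estimate, 4))
  cat("log-likelihood:", format(x$loglik, digits = 6), "\n")
  invisible(x)
}

#' Points of a fitted density curve
#'
#' Evaluates the density of a [fit_univariate()] fit on a grid, for
#' plotting or export.
#'
#' @param fit a `"unifit"` object.
#' @param n number of grid points.
#' @param from,to grid limits; defaults cover `(0, 1)` for the beta family
#'   and the data range widened by 3 SD for the normal.
#' @return data frame with columns `x`, `density`, `family`.
#' @export
density_curve_points <- function(fit, n = 512, from = NULL, to = NULL) {
  stopifnot(inherits(fit, "unifit"))
  if (fit$family == "beta") {
    if (is.null(from)) from <- 1e-4
    if (is.null(to)) to <- 1 - 1e-4
    x <- seq(from, to, length.out = n)
    d <- dbeta_mu(x, fit$estimate[["mu"]], fit$estimate[["phi"]])
  } else {
    s <- sqrt(fit$estimate[["variance"]])
    if (is.null(from)) from <- fit$range[1L] - 3 * s
    if (is.null(to)) to <- fit$range[2L] + 3 * s
    x <- seq(from, to, length.out = n)
    d <- stats::dnorm(x, fit$estimate[["mean"]], s)
  }
  data.frame(x = x, density = d, family = fit$family)
}

#' Overlay fitted beta and normal densities on a histogram
#'
#' @param y numeric sample strictly inside `(0, 1)`.
#' @param breaks passed to [graphics::hist()].
#' @param ... further plot arguments.
#' @return invisibly, a list with the two `"unifit"` objects.
#' @export
plot_density_fit <- function(y, breaks = 20, ...) {
  fb <- fit_univariate(y, "beta")
  fn <- fit_univariate(y, "normal")
  graphics::hist(y, breaks = breaks, freq = FALSE,
                 xlab = "score", main = "", ...)
  cb <- density_curve_points(fb)
  cn <- density_curve_points(fn)
  graphics::lines(cb$x, cb$density, lty = 1, lwd = 2)
  graphics::lines(cn$x, cn$density, lty = 2, lwd = 2)
  graphics::legend("topleft", c("beta", "normal"), lty = c(1, 2), lwd = 2,
                   bty = "n")
  invisible(list(beta = fb, normal = fn))
}
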