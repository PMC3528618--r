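#' Compress a bounded response into the open unit interval
#'
#' Applies the sample-size-based compression `y* = (y (N - 1) + 0.5) / N`,
#' which maps the whole of `[0, 1]` strictly inside `(0, 1)`.  `N` should be
#' the number of analyzed observations (after missingness deletion), so the
#' amount of compression shrinks as the sample grows.
#'
#' @param y numeric vector of responses in `[0, 1]`.
#' @param n_obs positive integer, the total number of observations `N`.
#' @return transformed vector, strictly inside `(0, 1)`.
#' @examples
#' compress_transform(1, 1945)   # 0.9997...
#' compress_transform(0.5, 200)  # 0.5 is a fixed point
#' @export
compress_transform <- function(y, n_obs) {
  if (length(n_obs) != 1L || is.na(n_obs) || n_obs < 1)
    stop("n_obs must be a positive integer", call. = FALSE)
  stopifnot(is.numeric(y))
  (y * (n_obs - 1) + 0.5) / n_obs
}

#' Shift boundary values away from 0 and 1
#'
#' Moves exact zeros to `epsilon` and exact ones to `1 - epsilon`; interior
#' values are untouched.  This is the default boundary policy of the fitting
#' functions (with `epsilon = 0.005`); large `epsilon` shrinks the data
#' toward 0.5 and can bias effects toward zero, while very small `epsilon`
#' can destabilize the likelihood, so a sensitivity sweep over `epsilon` is
#' recommended (see [sensitivity_sweep()]).
#'
#' @param y numeric vector of responses in `[0, 1]`.
#' @param epsilon shift amount, in `(0, 0.5)`; default `0.005`.
#' @return transformed vector, strictly inside `(0, 1)` when `y` is in
#'   `[0, 1]`.
#' @export
epsilon_shift <- function(y, epsilon = 0.005) {
  if (length(epsilon) != 1L || is.na(epsilon) || epsilon <= 0 || epsilon >= 0.5)
    stop("epsilon must lie in (0, 0.5)", call. = FALSE)
  stopifnot(is.numeric(y))
  y[!is.na(y) & y == 0] <- epsilon
  y[!is.na(y) & y == 1] <- 1 - epsilon
  y
}

#' Apply a boundary policy to a response vector
#'
#' Dispatcher used by the fitters: `"shift"` calls [epsilon_shift()],
#' `"compress"` calls [compress_transform()] with `n_obs = length(y)`,
#' `"none"` returns `y` unchanged.
#'
#' @param y numeric response vector.
#' @param method one of `"shift"`, `"compress"`, `"none"`.
#' @param epsilon shift amount for `"shift"`.
#' @param n_obs observation count for `"compress"`; defaults to `length(y)`.
#' @return transformed vector.
#' @export
boundary_transform <- function(y, method = c("shift", "compress", "none"),
                               epsilon = 0.005, n_obs = length(y)) {
  method <- match.arg(method)
  switch(method,
         shift = epsilon_shift(y, epsilon),
         compress = compress_transform(y, n_obs),
         none = y)
}

#' Sensitivity of estimates to the boundary shift amount
#'
#' Refits a model once per value of `epsilon_grid`, each time transforming
#' exact 0/1 responses by [epsilon_shift()], and tabulates coefficients and
#' standard errors so their spread can be compared with the estimation
#' uncertainty.  A failed fit is recorded per grid value and does not abort
#' the sweep.
#'
#' @param formula model formula.
#' @param data data frame or `long_panel`.
#' @param subject subject identifier column name.
#' @param fitter `"glmm"` (see [betaglmm()]) or `"gee"` (see [betagee()]).
#' @param epsilon_grid numeric vector of shift values in `(0, 0.5)`.
#' @param ... further arguments passed to the fitter.
#' @return data frame with columns `epsilon`, `term`, `estimate`, `se`,
#'   `converged`; one block of rows per grid value, in grid order.
#' @export
sensitivity_sweep <- function(formula, data, subject,
                              fitter = c("glmm", "gee"),
                              epsilon_grid = c(0.002, 0.005, 0.01), ...) {
  fitter <- match.arg(fitter)
  if (!length(epsilon_grid)) stop("epsilon_grid is empty", call. = FALSE)
  if (any(epsilon_grid <= 0 | epsilon_grid >= 0.5))
    stop("epsilon_grid values must lie in (0, 0.5)", call. = FALSE)
  fit_fun <- if (fitter == "glmm") betaglmm else betagee
  out <- lapply(epsilon_grid, function(eps) {
    res <- tryCatch({
      f <- fit_fun(formula, data, subject, boundary = "shift",
                   epsilon = eps, ...)
      cf <- stats::coef(f)
      se <- sqrt(diag(stats::vcov(f)))
      data.frame(epsilon = eps, term = names(cf), estimate = unname(cf),
                 se = unname(se), converged = TRUE,
                 stringsAsFactors = FALSE)
    }, error = function(e)
      data.frame(epsilon = eps, term = NA_character_, estimate = NA_real_,
                 se = NA_real_, converged = FALSE, stringsAsFactors = FALSE))
    res
  })
  do.call(rbind, out)
}
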