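## ---------------------------------------------------------------------------
## Synthetic longitudinal bounded-outcome data.  The generator draws from
## the subject-specific model the mixed fits assume: a logit-scale random
## intercept b_i ~ N(0, tau2) shared across a subject's occasions, and
## occasion-level responses Y_ij ~ Beta(mu_ij phi, (1 - mu_ij) phi) with
## logit(mu_ij) = x_ij' beta + b_i.  Two covariate designs emulate the
## structure of common HRQL studies: a two-occasion older-age cohort with a
## binary time-varying disease indicator ("kora_like") and a three-occasion
## rehabilitation trial with a fixed binary group ("stroke_like").
## ---------------------------------------------------------------------------

#' Configuration for the synthetic panel generator
#'
#' @param n_subjects number of subjects.
#' @param occasions character vector of occasion labels, in time order.
#' @param beta_true fixed-effect coefficients on the logit scale, in the
#'   design order of the chosen `design` (see Details).
#' @param phi_true beta precision (positive).
#' @param tau2_true random-intercept variance on the logit scale
#'   (non-negative; `0` gives independent observations).
#' @param design `"kora_like"` (two occasions; centered age, sex, binary
#'   time-varying `diab`, `diab:time` interaction; design columns
#'   intercept, age, sexmale, timet2, diabyes, timet2:diabyes) or
#'   `"stroke_like"` (three occasions; centered age, sex, fixed binary
#'   `phase`, `phase:time` interactions; columns intercept, age, sexmale,
#'   timet2, timet3, phaseD, timet2:phaseD, timet3:phaseD).
#' @param family `"beta"` (default) or `"gaussian"` (identity-link Gaussian
#'   responses with residual variance `sigma2_true`, for exercising the
#'   linear mixed model).
#' @param sigma2_true residual variance for `family = "gaussian"`.
#' @param missingness list describing the dropout mechanism applied after
#'   generation: `list(mechanism = "none")` (default),
#'   `list(mechanism = "mcar", p = ...)` or
#'   `list(mechanism = "mar", gamma0 = ..., gamma1 = ...)`; see
#'   [apply_missingness()].
#' @param boundary_mass probability that a draw is censored to the nearer
#'   boundary (0 or 1, by rounding its mean), emulating the boundary
#'   observations of real score data; default 0.
#' @param seed integer seed; identical seed and configuration give an
#'   identical dataset.
#' @return object of class `"synth_config"` (a validated list).
#' @seealso [preset_config()], [simulate_panel()]
#' @export
synth_config <- function(n_subjects, occasions, beta_true, phi_true,
                         tau2_true, design = c("kora_like", "stroke_like"),
                         family = c("beta", "gaussian"), sigma2_true = NULL,
                         missingness = list(mechanism = "none"),
                         boundary_mass = 0, seed = 1L) {
  design <- match.arg(design)
  family <- match.arg(family)
  stopifnot(n_subjects >= 1, length(occasions) >= 2,
            phi_true > 0, tau2_true >= 0,
            boundary_mass >= 0, boundary_mass <= 1)
  p_expect <- switch(design, kora_like = 6L, stroke_like = 8L)
  if (length(occasions) != switch(design, kora_like = 2L, stroke_like = 3L))
    stop(design, " uses ", switch(design, kora_like = 2L, stroke_like = 3L),
         " occasions", call. = FALSE)
  if (length(beta_true) != p_expect)
    stop(design, " needs ", p_expect, " coefficients, got ",
         length(beta_true), call. = FALSE)
  if (family == "gaussian" && (is.null(sigma2_true) || sigma2_true <= 0))
    stop("family = \"gaussian\" needs a positive sigma2_true", call. = FALSE)
  if (!is.list(missingness) || is.null(missingness$mechanism) ||
      !missingness$mechanism %in% c("none", "mcar", "mar"))
    stop("missingness$mechanism must be 'none', 'mcar' or 'mar'",
         call. = FALSE)
  structure(list(n_subjects = as.integer(n_subjects), occasions = occasions,
                 beta_true = beta_true, phi_true = phi_true,
                 tau2_true = tau2_true, design = design, family = family,
                 sigma2_true = sigma2_true, missingness = missingness,
                 boundary_mass = boundary_mass, seed = as.integer(seed)),
            class = "synth_config")
}

#' @export
print.synth_config <- function(x, ...) {
  cat("Synthetic panel configuration (", x$design, ", ", x$family, ")\n",
      sep = "")
  cat("  subjects:", x$n_subjects, " occasions:",
      paste(x$occasions, collapse = ", "), "\n")
  cat("  beta_true:", paste(round(x$beta_true, 4), collapse = ", "), "\n")
  cat("  phi_true:", x$phi_true, " tau2_true:", x$tau2_true,
      " boundary_mass:", x$boundary_mass, "\n")
  cat("  missingness:", x$missingness$mechanism, " seed:", x$seed, "\n")
  invisible(x)
}

#' Preset generator configurations
#'
#' Fully populated [synth_config()]s whose truth magnitudes are the
#' published beta-GLMM estimates for the two motivating study designs: an
#' older-age two-occasion cohort with a time-varying diabetes indicator
#' (`"kora_like"`: 1000 subjects, `phi = 14.45`, `tau2 = 0.3854`) and a
#' three-occasion stroke-rehabilitation trial with a fixed phase group
#' (`"stroke_like"`: 200 subjects, `phi = 10.80`, `tau2 = 1.2782`).
#'
#' @param name `"kora_like"` or `"stroke_like"`.
#' @param ... overrides passed to [synth_config()] (e.g. `n_subjects`,
#'   `seed`, `missingness`).
#' @return a `"synth_config"`.
#' @examples
#' preset_config("kora_like")$phi_true
#' @export
preset_config <- function(name = c("kora_like", "stroke_like"), ...) {
  name <- match.arg(name)
  base <- if (name == "kora_like") {
    list(n_subjects = 1000L, occasions = c("t1", "t2"),
         beta_true = c(intercept = 1.3534, age = -0.0185, sexmale = 0.3483,
                       timet2 = -0.0788, diabyes = -0.1538,
                       `timet2:diabyes` = -0.1837),
         phi_true = 14.45, tau2_true = 0.3854, design = "kora_like")
  } else {
    list(n_subjects = 200L, occasions = c("t1", "t2", "t3"),
         beta_true = c(intercept = -0.0106, age = -0.0226, sexmale = 0.2931,
                       timet2 = 0.4637, timet3 = 0.9254, phaseD = 1.6160,
                       `timet2:phaseD` = -0.2005, `timet3:phaseD` = -0.5465),
         phi_true = 10.80, tau2_true = 1.2782, design = "stroke_like")
  }
  args <- utils::modifyList(base, list(...))
  do.call(synth_config, args)
}

## deterministic sub-stream seeds so that e.g. switching the missingness
## mechanism never perturbs covariates, random effects or responses
substream_seed <- function(seed, k) {
  (as.integer(seed) %% 2147480009L) + k * 10007L
}

#' Simulate a longitudinal bounded-outcome panel
#'
#' Draws subject covariates, a logit-scale random intercept
#' `b_i ~ N(0, tau2_true)`, and responses
#' `Y_ij ~ Beta(mu_ij phi, (1 - mu_ij) phi)` with
#' `logit(mu_ij) = x_ij' beta_true + b_i`; optionally censors a fraction of
#' draws to the nearer boundary and applies a dropout mechanism.  Separate
#' deterministic sub-streams are used for covariates, random effects,
#' responses, censoring and missingness.
#'
#' Covariates: `kora_like` draws age from N(66.2, 4.3^2) (centered at the
#' sample mean), male sex with probability 0.509, baseline diabetes with
#' prevalence 0.089 and an incident-diabetes probability that brings the
#' follow-up prevalence to 0.162 (diabetes, once present, persists);
#' `stroke_like` draws age from N(57.2, 12.8^2) (centered), male sex with
#' probability 0.543, and phase D membership with probability 0.675.
#'
#' @param config a [synth_config()] or [preset_config()].
#' @return list with `data` (a [long_panel()]; columns `subject_id`,
#'   `time`, covariates, `y`) and `truth` (list: `beta`, `phi`, `tau2`,
#'   realized random intercepts `b`, per-row conditional means `mu`, and
#'   the `config`).  For `family = "gaussian"`, `data` is a plain data
#'   frame (identity-scale responses are not range-restricted) and `truth`
#'   carries `sigma2`.
#' @examples
#' sim <- simulate_panel(preset_config("kora_like", n_subjects = 50))
#' head(sim$data)
#' @export
simulate_panel <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  N <- config$n_subjects
  occ <- config$occasions
  T_ <- length(occ)

  set.seed(substream_seed(config$seed, 1L))
  if (config$design == "kora_like") {
    age <- stats::rnorm(N, 66.2, 4.3)
    sex <- factor(ifelse(stats::runif(N) < 0.509, "male", "female"),
                  levels = c("female", "male"))
    diab0 <- stats::runif(N) < 0.089
    incident <- (0.162 - 0.089) / (1 - 0.089)
    diab1 <- diab0 | (stats::runif(N) < incident)
    subj <- data.frame(subject_id = factor(sprintf("s%06d", seq_len(N)),
                                           levels = sprintf("s%06d", seq_len(N))),
                       age = age - mean(age), sex = sex)
    rows <- subj[rep(seq_len(N), each = T_), , drop = FALSE]
    rows$time <- factor(rep(occ, N), levels = occ)
    i <- rep(seq_len(N), each = T_)
    j <- rep(seq_len(T_), N)
    diab_tv <- ifelse(j == 1L, diab0[i], diab1[i])
    rows$diab <- factor(ifelse(diab_tv, "yes", "no"), levels = c("no", "yes"))
    X <- stats::model.matrix(~ age + sex + time + diab + diab:time, rows)
  } else {
    age <- stats::rnorm(N, 57.2, 12.8)
    sex <- factor(ifelse(stats::runif(N) < 0.543, "male", "female"),
                  levels = c("female", "male"))
    phase <- factor(ifelse(stats::runif(N) < 0.675, "D", "C"),
                    levels = c("C", "D"))
    subj <- data.frame(subject_id = factor(sprintf("s%06d", seq_len(N)),
                                           levels = sprintf("s%06d", seq_len(N))),
                       age = age - mean(age), sex = sex, phase = phase)
    rows <- subj[rep(seq_len(N), each = T_), , drop = FALSE]
    rows$time <- factor(rep(occ, N), levels = occ)
    X <- stats::model.matrix(~ age + sex + time + phase + phase:time, rows)
  }
  if (ncol(X) != length(config$beta_true))
    stop("internal design mismatch", call. = FALSE)

  set.seed(substream_seed(config$seed, 2L))
  b <- stats::rnorm(N, 0, sqrt(config$tau2_true))
  idx <- rep(seq_len(N), each = T_)
  eta <- drop(X %*% config$beta_true) + b[idx]

  set.seed(substream_seed(config$seed, 3L))
  if (config$family == "beta") {
    mu <- stats::plogis(eta)
    y <- stats::rbeta(length(eta), mu * config$phi_true,
                      (1 - mu) * config$phi_true)
    ## the beta law is absolutely continuous, so exact 0/1 draws are
    ## floating-point underflow (common when a shape parameter is < 1);
    ## clamp them to the nearest representable interior values
    y <- pmin(pmax(y, 1e-300), 1 - .Machine$double.eps)
  } else {
    mu <- eta
    y <- stats::rnorm(length(eta), eta, sqrt(config$sigma2_true))
  }

  if (config$boundary_mass > 0 && config$family == "beta") {
    set.seed(substream_seed(config$seed, 4L))
    cens <- stats::runif(length(y)) < config$boundary_mass
    y[cens] <- round(mu[cens])
  }
  rows$y <- y
  rownames(rows) <- NULL

  data <- if (config$family == "beta")
    long_panel(rows, "subject_id", "time", "y") else rows
  if (config$missingness$mechanism != "none") {
    m <- config$missingness
    data <- apply_missingness(data, mechanism = m$mechanism,
                              p = if (is.null(m$p)) 0.3 else m$p,
                              gamma0 = if (is.null(m$gamma0)) 1.6 else
                                m$gamma0,
                              gamma1 = if (is.null(m$gamma1)) -3 else
                                m$gamma1,
                              seed = substream_seed(config$seed, 5L),
                              subject = "subject_id", occasion = "time",
                              response = "y")
  }
  list(data = data,
       truth = list(beta = config$beta_true, phi = config$phi_true,
                    tau2 = config$tau2_true,
                    sigma2 = config$sigma2_true,
                    b = stats::setNames(b, levels(rows$subject_id)),
                    mu = mu, config = config))
}

#' Apply an MCAR or MAR dropout mechanism to a panel
#'
#' Baseline (first-occasion) rows are never dropped.  `"mcar"` drops each
#' post-baseline row independently with probability `p` — missingness
#' independent of all data.  `"mar"` drops the row at occasion `j > 1` with
#' probability `plogis(gamma0 + gamma1 * y_prev)`, where `y_prev` is the
#' most recent *observed* response of the same subject, so missingness
#' depends only on observed data (missing at random) but not on the
#' unobserved current response.  With `gamma1 < 0`, subjects with lower
#' previous scores are more likely to drop out.  The defaults
#' (`gamma0 = 1.6`, `gamma1 = -3`) give roughly 30% follow-up dropout for
#' scores around 0.8, a rate typical of multi-year cohort follow-ups.
#'
#' Likelihood-based fits ([lmm_ml()], [betaglmm()]) remain valid under MAR;
#' the GEE ([betagee()]) requires MCAR.
#'
#' @param data data frame or [long_panel()]; roles are taken from panel
#'   attributes or the `subject`/`occasion`/`response` arguments.
#' @param mechanism `"mcar"` or `"mar"`.
#' @param p MCAR per-row drop probability.
#' @param gamma0,gamma1 MAR logistic intercept and slope on the previous
#'   observed response.
#' @param seed integer seed for the dropout draws.
#' @param subject,occasion,response column names (defaults from panel
#'   attributes).
#' @return the panel with dropped rows removed.
#' @export
apply_missingness <- function(data, mechanism = c("mcar", "mar"), p = 0.3,
                              gamma0 = 1.6, gamma1 = -3, seed = 1L,
                              subject = attr(data, "subject"),
                              occasion = attr(data, "occasion"),
                              response = attr(data, "response")) {
  mechanism <- match.arg(mechanism)
  if (is.null(subject) || is.null(occasion) || is.null(response))
    stop("subject/occasion/response columns must be given for plain data ",
         "frames", call. = FALSE)
  stopifnot(p >= 0, p <= 1)
  occf <- data[[occasion]]
  if (!is.factor(occf)) occf <- factor(occf, levels = unique(occf))
  baseline <- levels(occf)[1L]
  n <- nrow(data)
  set.seed(seed)
  if (mechanism == "mcar") {
    u <- stats::runif(n)
    drop <- occf != baseline & u < p
  } else {
    drop <- logical(n)
    id <- data[[subject]]
    y <- data[[response]]
    ord <- order(as.integer(factor(id, levels = unique(id))),
                 as.integer(occf))
    last_obs <- new.env(parent = emptyenv())
    u <- stats::runif(n)
    for (r in ord) {
      key <- as.character(id[r])
      if (occf[r] == baseline) {
        assign(key, y[r], envir = last_obs)
      } else {
        yp <- get0(key, envir = last_obs, ifnotfound = NA_real_)
        if (is.na(yp)) { assign(key, y[r], envir = last_obs); next }
        pd <- stats::plogis(gamma0 + gamma1 * yp)
        if (u[r] < pd) drop[r] <- TRUE
        else assign(key, y[r], envir = last_obs)
      }
    }
  }
  out <- data[!drop, , drop = FALSE]
  attributes(out)[c("subject", "occasion", "response")] <-
    attributes(data)[c("subject", "occasion", "response")]
  class(out) <- class(data)
  out
}
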