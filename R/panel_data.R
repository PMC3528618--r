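#' Long-format longitudinal panel of bounded responses
#'
#' Validates and annotates a long-format data frame (one row per subject x
#' measurement occasion) holding a response on the closed unit interval and
#' arbitrary covariate columns.  The returned object is a plain data frame
#' carrying the column roles as attributes, so it can be passed directly to
#' the fitting functions ([lmm_ml()], [betaglmm()], [betagee()]).
#'
#' Character columns are converted to factors with levels in order of first
#' appearance, which fixes the reference level used in reference (treatment)
#' coding.  Unbalanced panels are allowed: subjects may simply lack rows for
#' some occasions.
#'
#' @param data data frame in long format.
#' @param subject name of the subject identifier column.
#' @param occasion name of the measurement-occasion column.
#' @param response name of the response column; values must lie in `[0, 1]`
#'   (missing values allowed, see [drop_incomplete()]).
#' @param check_range if `TRUE` (default) an out-of-range response is an
#'   error; scores on other scales (e.g. 0-100) must be rescaled first.
#' @return `data`, classed `"long_panel"`, with attributes `subject`,
#'   `occasion`, `response`.
#' @examples
#' d <- data.frame(id = rep(1:3, each = 2), occ = rep(c("t1", "t2"), 3),
#'                 y = c(.7, .6, .8, .9, .5, .4))
#' p <- long_panel(d, "id", "occ", "y")
#' attr(p, "response")
#' @export
long_panel <- function(data, subject, occasion, response, check_range = TRUE) {
  stopifnot(is.data.frame(data))
  for (nm in c(subject, occasion, response))
    if (!nm %in% names(data))
      stop("column '", nm, "' not found in data", call. = FALSE)
  data <- as.data.frame(data)
  for (j in seq_along(data))
    if (is.character(data[[j]]))
      data[[j]] <- factor(data[[j]], levels = unique(data[[j]]))
  if (!is.factor(data[[subject]]))
    data[[subject]] <- factor(data[[subject]], levels = unique(data[[subject]]))
  y <- data[[response]]
  if (!is.numeric(y))
    stop("response column '", response, "' is not numeric", call. = FALSE)
  if (check_range) {
    bad <- which(!is.na(y) & (y < 0 | y > 1))
    if (length(bad))
      stop("response values outside [0, 1] in rows ",
           paste(utils::head(bad, 10L), collapse = ", "),
           if (length(bad) > 10L) " ..." else "",
           "; rescale scores (e.g. divide 0-100 scores by 100)", call. = FALSE)
  }
  key <- paste(data[[subject]], data[[occasion]], sep = "\r")
  if (anyDuplicated(key))
    stop("duplicated (subject, occasion) pairs in rows ",
         paste(utils::head(which(duplicated(key)), 10L), collapse = ", "),
         call. = FALSE)
  structure(data, subject = subject, occasion = occasion, response = response,
            class = c("long_panel", "data.frame"))
}

#' @export
print.long_panel <- function(x, ...) {
  cat("Long-format panel:", length(unique(x[[attr(x, "subject")]])),
      "subjects,", nrow(x), "rows\n")
  cat("  subject:", attr(x, "subject"),
      " occasion:", attr(x, "occasion"),
      " response:", attr(x, "response"), "\n")
  NextMethod()
}

#' Read a long-format panel from CSV
#'
#' Reads a delimited text file (UTF-8, header row required; missing cells as
#' empty strings or `"NA"`) and validates it as a [long_panel()].
#'
#' @inheritParams long_panel
#' @param path path to a CSV file.
#' @return a `long_panel` data frame.
#' @seealso [write_long_csv()] for the inverse.
#' @export
read_long_csv <- function(path, subject, occasion, response,
                          check_range = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  d <- utils::read.csv(path, na.strings = c("", "NA"),
                       stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  long_panel(d, subject, occasion, response, check_range = check_range)
}

#' Write a panel back to CSV
#'
#' @param data data frame or `long_panel`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_long_csv <- function(data, path) {
  utils::write.csv(as.data.frame(data), path, row.names = FALSE, na = "")
  invisible(path)
}

#' Delete rows with missing response or covariates
#'
#' Removes individual observations (rows) that are missing the response or
#' any covariate used by `formula`; other rows of the same subject are kept.
#' A row missing both a response and a covariate is counted once, as
#' response-missing.
#'
#' @param data data frame or `long_panel`.
#' @param formula model formula; its left-hand side names the response and
#'   its right-hand side the covariates screened for missingness.
#' @return list with elements `data` (complete rows, original order),
#'   `n_missing_response` and `n_missing_covariate`.
#' @examples
#' d <- data.frame(id = 1:4, y = c(.5, NA, .7, .8), x = c(1, 2, NA, 4))
#' drop_incomplete(d, y ~ x)
#' @export
drop_incomplete <- function(data, formula) {
  stopifnot(inherits(formula, "formula"), length(formula) == 3L)
  resp <- all.vars(formula[[2L]])
  covs <- all.vars(formula[[3L]])
  miss <- setdiff(c(resp, covs), names(data))
  if (length(miss))
    stop("variables not found in data: ", paste(miss, collapse = ", "),
         call. = FALSE)
  miss_resp <- Reduce(`|`, lapply(resp, function(v) is.na(data[[v]])))
  if (length(covs)) {
    miss_cov <- Reduce(`|`, lapply(covs, function(v) is.na(data[[v]])))
  } else miss_cov <- rep(FALSE, nrow(data))
  keep <- !miss_resp & !miss_cov
  out <- data[keep, , drop = FALSE]
  attributes(out)[c("subject", "occasion", "response")] <-
    attributes(data)[c("subject", "occasion", "response")]
  class(out) <- class(data)
  list(data = out,
       n_missing_response = sum(miss_resp),
       n_missing_covariate = sum(miss_cov & !miss_resp))
}

#' Build fixed- and random-effect design matrices
#'
#' Expands a model formula on complete data into the fixed design matrix `X`
#' (reference-coded dummies for factors, elementwise products for
#' interactions), the random-intercept design `Z` (a column of ones), the
#' response vector and the subject index.  Column order is deterministic
#' given the formula and the factor levels.
#'
#' @param formula model formula, e.g. `y ~ age + sex + time + diab + diab:time`.
#' @param data complete data frame (see [drop_incomplete()]).
#' @param subject name of the subject identifier column.
#' @param xlev optional named list of factor levels from a previous fit;
#'   a level absent from these training levels is an error.
#' @return list with `X`, `Z`, `y`, `id` (factor), `terms`, `xlevels`,
#'   `contrasts`.
#' @export
build_design <- function(formula, data, subject, xlev = NULL) {
  if (!subject %in% names(data))
    stop("subject column '", subject, "' not found in data", call. = FALSE)
  vars <- all.vars(formula)
  miss <- setdiff(vars, names(data))
  if (length(miss))
    stop("variables not found in data: ", paste(miss, collapse = ", "),
         call. = FALSE)
  data <- as.data.frame(data)
  for (j in seq_along(data))
    if (is.character(data[[j]]))
      data[[j]] <- factor(data[[j]], levels = unique(data[[j]]))
  mf <- stats::model.frame(formula, data, na.action = stats::na.fail,
                           xlev = xlev, drop.unused.levels = FALSE)
  mt <- attr(mf, "terms")
  X <- stats::model.matrix(mt, mf)
  y <- stats::model.response(mf)
  id <- data[[subject]]
  if (!is.factor(id)) id <- factor(id, levels = unique(id))
  id <- droplevels(id)
  list(X = X, Z = matrix(1, nrow(X), 1L), y = as.numeric(y), id = id,
       terms = mt, xlevels = stats::.getXlevels(mt, mf),
       contrasts = attr(X, "contrasts"))
}

## rank check shared by the fitters; reports the offending columns
check_full_rank <- function(X) {
  q <- qr(X)
  if (q$rank < ncol(X)) {
    drop <- colnames(X)[q$pivot[(q$rank + 1L):ncol(X)]]
    stop("fixed-effect design is rank deficient; collinear column(s): ",
         paste(drop, collapse = ", "), call. = FALSE)
  }
  invisible(TRUE)
}
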