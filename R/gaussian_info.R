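#' Closed-form Gaussian information measures
#'
#' Under a multivariate Gaussian assumption every entropy-based quantity is a
#' function of the covariance matrix alone, so O-information and the
#' redundancy-synergy index (RSI) have closed forms in determinants of
#' \eqn{\Sigma} and its principal minors. All values are in nats.
#'
#' @name gaussian_info
NULL

#' Construct a covariance model directly
#'
#' Wraps a known covariance matrix (e.g. a population covariance implied by a
#' generator) in the object all information measures consume. Use
#' [estimate_covariance()] to build one from data.
#'
#' @param sigma symmetric numeric matrix with strictly positive diagonal.
#' @param variable_names column names; defaults to `colnames(sigma)`.
#' @param n_samples sample count backing the estimate (`NA` for population
#'   covariances).
#' @param ridge the nonnegative scalar actually added to the diagonal.
#' @return an object of class `covariance_model`.
#' @export
covariance_model <- function(sigma, variable_names = NULL, n_samples = NA_integer_,
                             ridge = 0) {
  if (!is.matrix(sigma) || !is.numeric(sigma) || nrow(sigma) != ncol(sigma))
    stop("'sigma' must be a square numeric matrix", call. = FALSE)
  rel <- max(abs(sigma - t(sigma))) / max(abs(sigma), 1e-300)
  if (rel > 1e-12)
    stop("'sigma' is not symmetric (relative asymmetry ", signif(rel, 3), ")",
         call. = FALSE)
  sigma <- (sigma + t(sigma)) / 2
  variable_names <- variable_names %||% colnames(sigma) %||%
    paste0("V", seq_len(ncol(sigma)))
  if (anyDuplicated(variable_names))
    stop("variable names must be unique", call. = FALSE)
  if (any(diag(sigma) <= 0))
    stop("all diagonal entries of 'sigma' must be strictly positive; ",
         "offending variable(s): ",
         paste(variable_names[diag(sigma) <= 0], collapse = ", "),
         call. = FALSE)
  dimnames(sigma) <- list(variable_names, variable_names)
  structure(list(sigma = sigma, variable_names = as.character(variable_names),
                 n_samples = n_samples, ridge = ridge),
            class = "covariance_model")
}

#' @export
print.covariance_model <- function(x, ...) {
  cat(sprintf("<covariance_model> %d variables, n = %s, ridge = %g\n",
              ncol(x$sigma), x$n_samples, x$ridge))
  invisible(x)
}

#' Estimate a covariance model from data
#'
#' Unbiased (n-1 denominator) sample covariance. An optional ridge adds
#' `ridge * trace(sigma) / n_vars` to every diagonal entry, a scale-aware
#' regularization for near-singular empirical covariances; the default is no
#' regularization, so duplicated variables surface as singularity errors in
#' downstream determinant-based measures rather than being silently smoothed.
#'
#' @param data a [data_matrix()] or numeric matrix.
#' @param ridge nonnegative relative ridge (default 0).
#' @return a [covariance_model()].
#' @examples
#' dm <- gen_independent(500, 4, seed = 1)$data
#' estimate_covariance(dm)
#' @export
estimate_covariance <- function(data, ridge = 0) {
  data <- as_data_matrix(data)
  assert_scalar_number(ridge, "ridge", min = 0)
  x <- data$values
  if (nrow(x) < 3L)
    stop("need at least 3 samples to estimate a covariance", call. = FALSE)
  v <- apply(x, 2L, stats::var)
  if (any(v == 0))
    stop("zero-variance column(s): ",
         paste(data$variable_names[v == 0], collapse = ", "), call. = FALSE)
  sigma <- cov(x)
  added <- 0
  if (ridge > 0) {
    added <- ridge * sum(diag(sigma)) / ncol(sigma)
    sigma <- sigma + diag(added, ncol(sigma))
  }
  covariance_model(sigma, data$variable_names, n_samples = nrow(x),
                   ridge = added)
}

# Resolve a character/integer subset to integer indices, with checks.
resolve_subset <- function(cov, subset, what = "subset") {
  if (length(subset) < 1L) stop(sprintf("'%s' must be non-empty", what),
                                call. = FALSE)
  if (is.character(subset)) {
    idx <- match(subset, cov$variable_names)
    if (anyNA(idx))
      stop(sprintf("unknown variable(s) in %s: %s", what,
                   paste(subset[is.na(idx)], collapse = ", ")), call. = FALSE)
  } else {
    idx <- as.integer(subset)
    if (any(idx < 1L | idx > length(cov$variable_names)))
      stop(sprintf("%s indices out of range", what), call. = FALSE)
  }
  if (anyDuplicated(idx))
    stop(sprintf("duplicated variables in %s", what), call. = FALSE)
  idx
}

# log-determinant via Cholesky, erroring on non-positive-definiteness.
logdet_pd <- function(m, context = "covariance submatrix") {
  R <- tryCatch(chol(m), error = function(e) NULL)
  # exactly collinear columns can pass floating-point Cholesky with a tiny
  # positive pivot; treat pivots below relative tolerance as singular too
  if (is.null(R) || min(diag(R))^2 < 1e-12 * max(diag(m)))
    stop("singular or non-positive-definite ", context,
         " (determinant <= 0); variables may be linearly dependent",
         call. = FALSE)
  2 * sum(log(diag(R)))
}

#' Gaussian joint entropy of a variable subset
#'
#' \eqn{h(X) = \frac12 \ln((2\pi e)^k |\Sigma_{subset}|)} nats.
#'
#' @param cov a [covariance_model()].
#' @param subset variable names or indices.
#' @return scalar entropy in nats.
#' @export
gaussian_entropy <- function(cov, subset = cov$variable_names) {
  stopifnot(inherits(cov, "covariance_model"))
  idx <- resolve_subset(cov, subset)
  k <- length(idx)
  ld <- if (k == 1L) {
    s <- cov$sigma[idx, idx]
    if (s <= 0) stop("non-positive variance", call. = FALSE)
    log(s)
  } else logdet_pd(cov$sigma[idx, idx, drop = FALSE])
  0.5 * (k * log(2 * pi * exp(1)) + ld)
}

#' Gaussian mutual information between two variables
#'
#' \eqn{I(a;b) = -\frac12 \ln(1-\rho^2)} nats, \eqn{\rho} the correlation.
#'
#' @param cov a [covariance_model()].
#' @param a,b distinct variable names or indices.
#' @return scalar MI in nats (always nonnegative).
#' @export
gaussian_mi <- function(cov, a, b) {
  stopifnot(inherits(cov, "covariance_model"))
  ia <- resolve_subset(cov, a, "a"); ib <- resolve_subset(cov, b, "b")
  if (length(ia) != 1L || length(ib) != 1L || ia == ib)
    stop("'a' and 'b' must be two distinct variables", call. = FALSE)
  s <- cov$sigma
  rho2 <- s[ia, ib]^2 / (s[ia, ia] * s[ib, ib])
  if (rho2 >= 1)
    stop("singular 2x2 covariance (|correlation| >= 1) for the pair",
         call. = FALSE)
  -0.5 * log1p(-rho2)
}

#' Total correlation of a subset
#'
#' \eqn{TC = \sum_i h(X_i) - h(X) = \frac12\ln(\prod_i \sigma_i^2 / |\Sigma|)};
#' nonnegative, zero iff the variables are (jointly Gaussian) independent.
#'
#' @inheritParams gaussian_entropy
#' @return scalar TC in nats.
#' @export
total_correlation <- function(cov, subset = cov$variable_names) {
  stopifnot(inherits(cov, "covariance_model"))
  idx <- resolve_subset(cov, subset)
  sub <- cov$sigma[idx, idx, drop = FALSE]
  0.5 * (sum(log(diag(sub))) - logdet_pd(sub))
}

#' Dual total correlation of a subset
#'
#' \eqn{DTC = \frac12\ln(\prod_i |\Sigma_{-i}| / |\Sigma|^{k-1})} where
#' \eqn{\Sigma_{-i}} drops variable \eqn{i}; nonnegative.
#'
#' @inheritParams gaussian_entropy
#' @return scalar DTC in nats.
#' @export
dual_total_correlation <- function(cov, subset = cov$variable_names) {
  stopifnot(inherits(cov, "covariance_model"))
  idx <- resolve_subset(cov, subset)
  sub <- cov$sigma[idx, idx, drop = FALSE]
  k <- length(idx)
  ld <- logdet_pd(sub)
  ldm <- vapply(seq_len(k), function(i) {
    m <- sub[-i, -i, drop = FALSE]
    if (k == 2L) {
      if (m[1, 1] <= 0) stop("non-positive variance", call. = FALSE)
      log(m[1, 1])
    } else {
      tryCatch(logdet_pd(m),
               error = function(e)
                 stop("singular minor when omitting variable '",
                      cov$variable_names[idx[i]], "'", call. = FALSE))
    }
  }, numeric(1))
  0.5 * (sum(ldm) - (k - 1) * ld)
}

#' An information measure value record
#'
#' Carrier for a single computed measure; printed by the JSON exporters.
#' @param measure one of `entropy`, `mi`, `tc`, `dtc`, `oinfo`, `rsi`.
#' @param value scalar value in nats.
#' @param subset ordered variable names the measure was computed on.
#' @param target target variable (RSI only).
#' @param convention RSI sign convention tag.
#' @return an object of class `info_value`.
#' @export
info_value <- function(measure, value, subset, target = NULL,
                       convention = NULL) {
  structure(list(measure = measure, value = value, subset = subset,
                 target = target, convention = convention),
            class = "info_value")
}

#' @export
print.info_value <- function(x, ...) {
  cat(sprintf("<info_value> %s = %.6g nats  [%s]%s%s\n", x$measure, x$value,
              paste(x$subset, collapse = ", "),
              if (!is.null(x$target)) paste0(" -> ", x$target) else "",
              if (!is.null(x$convention)) paste0(" (", x$convention, ")") else ""))
  invisible(x)
}

#' @export
as.double.info_value <- function(x, ...) x$value

#' O-information of a variable subset
#'
#' For a Gaussian system,
#' \deqn{O(X) = \tfrac12 \ln\frac{|\Sigma|^{k-2}\,\prod_i \sigma_i^2}
#'                               {\prod_i |\Sigma_{-i}|},}
#' equal to total correlation minus dual total correlation. Positive values
#' indicate net redundancy, negative values net synergy. Invariant to
#' variable order and per-variable rescaling.
#'
#' @inheritParams gaussian_entropy
#' @param subset at least 3 variable names or indices.
#' @return an [info_value()] (coerce with `as.double()` for the scalar).
#' @examples
#' sg <- matrix(c(1, 0, 1, 0, 1, 1, 1, 1, 3), 3, 3)
#' as.double(o_info(covariance_model(sg), 1:3))  # 0.5 * log(3/4)
#' @export
o_info <- function(cov, subset = cov$variable_names) {
  stopifnot(inherits(cov, "covariance_model"))
  idx <- resolve_subset(cov, subset)
  if (length(idx) < 3L)
    stop("O-information requires a subset of at least 3 variables",
         call. = FALSE)
  v <- oinfo_batch_cpp(cov$sigma, matrix(idx, ncol = 1L))
  if (is.na(v))
    stop("singular covariance submatrix or minor for subset {",
         paste(cov$variable_names[idx], collapse = ", "), "}", call. = FALSE)
  info_value("oinfo", as.double(v), cov$variable_names[idx])
}

#' Conditional covariance of a subset given a target
#'
#' Schur complement \eqn{\Sigma_{S|Y} = \Sigma_S - \sigma_{SY}\sigma_{YY}^{-1}
#' \sigma_{YS}}.
#'
#' @param cov a [covariance_model()].
#' @param subset predictor variables (target excluded).
#' @param target single conditioning variable.
#' @return a [covariance_model()] of the conditional covariance (same
#'   `n_samples` bookkeeping).
#' @export
conditional_covariance <- function(cov, subset, target) {
  stopifnot(inherits(cov, "covariance_model"))
  idx <- resolve_subset(cov, subset)
  it <- resolve_subset(cov, target, "target")
  if (length(it) != 1L) stop("'target' must be a single variable", call. = FALSE)
  if (it %in% idx) stop("'target' must not be part of 'subset'", call. = FALSE)
  syy <- cov$sigma[it, it]
  if (syy <= 0) stop("target variance must be positive", call. = FALSE)
  ssy <- cov$sigma[idx, it, drop = FALSE]
  cc <- cov$sigma[idx, idx, drop = FALSE] - tcrossprod(ssy) / syy
  cc <- (cc + t(cc)) / 2
  if (any(diag(cc) <= 0))
    stop("conditional covariance has non-positive variance(s): target ",
         "explains (at least) one predictor exactly", call. = FALSE)
  covariance_model(cc, cov$variable_names[idx], n_samples = cov$n_samples,
                   ridge = cov$ridge)
}

#' Conditional variance of one variable given a target
#'
#' \eqn{\sigma^2_{x|Y} = \sigma_x^2 (1 - \rho^2)}.
#'
#' @inheritParams conditional_covariance
#' @param x single variable name or index.
#' @return scalar conditional variance.
#' @export
conditional_variance <- function(cov, x, target) {
  stopifnot(inherits(cov, "covariance_model"))
  ix <- resolve_subset(cov, x, "x")
  it <- resolve_subset(cov, target, "target")
  if (length(ix) != 1L || length(it) != 1L || ix == it)
    stop("'x' and 'target' must be two distinct single variables",
         call. = FALSE)
  syy <- cov$sigma[it, it]
  if (syy <= 0) stop("target variance must be positive", call. = FALSE)
  cov$sigma[ix, ix] - cov$sigma[ix, it]^2 / syy
}

#' Redundancy-synergy index of a predictor set for a target
#'
#' The Gaussian RSI is
#' \deqn{\tfrac12 \ln \frac{|\Sigma_S| \prod_i \sigma^2_{X_i|Y}}
#'                          {|\Sigma_{S|Y}| \prod_i \sigma^2_{X_i}}
#'       \;=\; I(S;Y) - \sum_{X_i \in S} I(X_i;Y).}
#' Two sign conventions are in circulation and both are provided, because
#' they genuinely disagree: the formula above (`convention = "printed"`) is
#' positive for the canonical synergistic construction
#' \eqn{Y = X_1 + X_2 + \varepsilon}, whereas the interpretive convention
#' used when reading trajectories (`"results"`, the default) negates it so
#' that negative values indicate synergy and positive values redundancy,
#' matching the sign language of O-information. The two are exact negations;
#' the package does not silently reconcile them.
#'
#' @param cov a [covariance_model()].
#' @param predictors predictor variable names or indices (>= 1).
#' @param target single target variable, not among the predictors.
#' @param convention `"results"` (negative = synergy, default) or
#'   `"printed"` (the raw formula).
#' @return an [info_value()].
#' @examples
#' # Y = X1 + X2 + noise: pure synergy
#' sg <- diag(3); sg[1, 3] <- sg[3, 1] <- 1; sg[2, 3] <- sg[3, 2] <- 1
#' sg[3, 3] <- 3
#' cm <- covariance_model(sg, c("x1", "x2", "y"))
#' as.double(rsi(cm, c("x1", "x2"), "y"))            # ~ -0.1438
#' as.double(rsi(cm, c("x1", "x2"), "y", "printed")) # ~ +0.1438
#' @export
rsi <- function(cov, predictors, target,
                convention = c("results", "printed")) {
  stopifnot(inherits(cov, "covariance_model"))
  convention <- match.arg(convention)
  idx <- resolve_subset(cov, predictors, "predictors")
  it <- resolve_subset(cov, target, "target")
  if (length(it) != 1L) stop("'target' must be a single variable", call. = FALSE)
  if (it %in% idx)
    stop("'target' must not be among the predictors", call. = FALSE)
  v <- rsi_batch_cpp(cov$sigma, matrix(idx, ncol = 1L), it)
  if (is.na(v))
    stop("singular predictor covariance (marginal or conditional on the ",
         "target) for {", paste(cov$variable_names[idx], collapse = ", "),
         "}", call. = FALSE)
  value <- if (convention == "printed") as.double(v) else -as.double(v)
  info_value("rsi", value, cov$variable_names[idx],
             target = cov$variable_names[it], convention = convention)
}
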