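#' High-covariance sub-ensemble selection by PCA reconstruction error
#'
#' Samples lying closest to the subspace of the leading principal components
#' are, by construction, the ones whose variables covary most strongly: they
#' carry little variance in the trailing directions. Ranking samples by
#' residual L2 reconstruction error and keeping the lowest therefore selects
#' a high-covariance sub-ensemble, which is sufficient to flip an ensemble's
#' higher-order interaction balance from synergy toward redundancy.
#'
#' @name covariance_subset
NULL

#' Fit a PCA model
#'
#' Centered (and by default z-scored) principal component analysis via
#' [stats::prcomp()]; the cumulative explained variance of the retained
#' components is reported so the realized fraction can be inspected.
#'
#' @param data a [data_matrix()] or numeric matrix.
#' @param n_components components to retain (default 5).
#' @param standardize z-score variables before PCA (default TRUE; variables
#'   of heterogeneous physical scale should not compete by raw variance).
#' @return object of class `pca_model`: `components` (n_components x
#'   variables, orthonormal rows), `explained_variance_ratio`, `center`,
#'   `scale`, `cumulative_explained`.
#' @export
fit_pca <- function(data, n_components = 5L, standardize = TRUE) {
  data <- as_data_matrix(data)
  x <- data$values
  if (n_components < 1L || n_components > min(nrow(x) - 1L, ncol(x)))
    stop("'n_components' must be in [1, min(n_samples - 1, n_vars)]",
         call. = FALSE)
  if (standardize && any(apply(x, 2L, sd) == 0))
    stop("zero-variance column(s) cannot be standardized: ",
         paste(data$variable_names[apply(x, 2L, sd) == 0], collapse = ", "),
         call. = FALSE)
  p <- prcomp(x, center = TRUE, scale. = standardize)
  evr <- p$sdev^2 / sum(p$sdev^2)
  structure(list(
    components = t(p$rotation[, seq_len(n_components), drop = FALSE]),
    explained_variance_ratio = evr[seq_len(n_components)],
    all_variance_ratio = evr,
    center = p$center,
    scale = if (standardize) p$scale else NULL,
    cumulative_explained = sum(evr[seq_len(n_components)]),
    n_components = as.integer(n_components),
    variable_names = data$variable_names),
    class = "pca_model")
}

#' @export
print.pca_model <- function(x, ...) {
  cat(sprintf("<pca_model> %d components over %d variables, %.1f%% variance\n",
              x$n_components, length(x$variable_names),
              100 * x$cumulative_explained))
  invisible(x)
}

#' Per-sample PCA reconstruction residuals
#'
#' Euclidean norm of the difference between each (standardized, if the model
#' was standardized) sample and its reconstruction from the retained
#' components; zero for samples lying exactly in the component span.
#'
#' @param data a [data_matrix()] on the model's variables.
#' @param model a [fit_pca()] model.
#' @return nonnegative numeric vector, one residual per sample.
#' @export
reconstruction_residuals <- function(data, model) {
  stopifnot(inherits(model, "pca_model"))
  data <- as_data_matrix(data)
  if (!identical(data$variable_names, model$variable_names))
    stop("variables of 'data' do not match the fitted model", call. = FALSE)
  z <- sweep(data$values, 2L, model$center, "-")
  if (!is.null(model$scale)) z <- sweep(z, 2L, model$scale, "/")
  scores <- z %*% t(model$components)
  resid <- z - scores %*% model$components
  sqrt(rowSums(resid^2))
}

#' Select the high-covariance subset
#'
#' Fits a PCA, ranks samples by residual L2 reconstruction error from the
#' top `n_components` components, and retains the `n_keep` samples with the
#' lowest error (ties broken by original sample order).
#'
#' @param data a [data_matrix()] or numeric matrix.
#' @param n_components PCA components (default 5).
#' @param n_keep samples to retain (default 1000).
#' @param standardize see [fit_pca()].
#' @return object of class `subset_selection`: `indices` (length `n_keep`),
#'   `residuals` (all samples), `model`, `n_components`, `n_keep`, and
#'   `subset` (a [data_matrix()] of the retained samples).
#' @export
select_high_covariance <- function(data, n_components = 5L, n_keep = 1000L,
                                   standardize = TRUE) {
  data <- as_data_matrix(data)
  n <- nrow(data$values)
  if (n_keep < 1L || n_keep > n)
    stop("'n_keep' must be in [1, n_samples]", call. = FALSE)
  model <- fit_pca(data, n_components = n_components, standardize = standardize)
  res <- reconstruction_residuals(data, model)
  idx <- order(res)[seq_len(n_keep)]  # order() is stable: ties keep row order
  idx <- sort(idx)
  sub <- data_matrix(data$values[idx, , drop = FALSE],
                     variable_names = data$variable_names,
                     variable_annotations = data$variable_annotations,
                     sample_labels = data$sample_labels[idx])
  structure(list(indices = idx, residuals = res, model = model,
                 n_components = as.integer(n_components),
                 n_keep = as.integer(n_keep), subset = sub),
            class = "subset_selection")
}

#' @export
print.subset_selection <- function(x, ...) {
  cat(sprintf(
    "<subset_selection> kept %d of %d samples (%d PCs, %.1f%% variance)\n",
    x$n_keep, length(x$residuals), x$n_components,
    100 * x$model$cumulative_explained))
  invisible(x)
}
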