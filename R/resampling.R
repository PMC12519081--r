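#' Bootstrap bands, shuffle surrogates, and trajectory AUC summaries
#'
#' Inference machinery around the tuple scans: subsample-without-replacement
#' bootstrap bands for per-order statistics, column-shuffle surrogate extrema
#' (the "no cross-variable dependence" null), absolute area-under-curve
#' summaries of O-information trajectories, and a rank-sum group comparison.
#'
#' @name resampling
NULL

#' Dataset guard against resampling artifacts
#'
#' Small or strongly class-imbalanced datasets produce unstable resampled
#' information estimates and are excluded: fail if fewer than `min_samples`
#' samples, or if per-sample labels are present and the smallest class holds
#' less than `imbalance_ratio` of the samples.
#'
#' @param data a [data_matrix()] or expression matrix (anything with
#'   sample labels and a `values` matrix), or a plain matrix.
#' @param min_samples minimum sample count (default 100).
#' @param imbalance_ratio minimum smallest-class fraction (default 0.1).
#' @return list with `pass` (logical) and `reason` (`NULL` when passing).
#' @export
dataset_guard <- function(data, min_samples = 100L, imbalance_ratio = 0.1) {
  values <- if (is.matrix(data)) data else data$values
  labels <- if (is.matrix(data)) NULL else
    (data$sample_labels %||% data$cell_labels)
  n <- nrow(values)
  if (n < min_samples)
    return(list(pass = FALSE,
                reason = sprintf("too few samples (%d < %d)", n, min_samples)))
  if (!is.null(labels)) {
    fr <- min(table(labels)) / n
    if (fr < imbalance_ratio)
      return(list(pass = FALSE,
                  reason = sprintf(
                    "strongly imbalanced classes (smallest fraction %.3g < %.3g)",
                    fr, imbalance_ratio)))
  }
  list(pass = TRUE, reason = NULL)
}

# Evaluate a fixed per-order tuple list on a covariance matrix.
eval_tuple_list <- function(sigma, tuple_list, config, target_idx = NULL) {
  vapply(seq_along(tuple_list), function(i) {
    tuples <- tuple_list[[i]]
    values <- if (config$measure == "oinfo") {
      oinfo_batch_cpp(sigma, tuples)
    } else {
      v <- rsi_batch_cpp(sigma, tuples, target_idx)
      if (config$convention == "results") -v else v
    }
    values <- values[!is.na(values)]
    c(min = if (length(values)) min(values) else NA_real_,
      max = if (length(values)) max(values) else NA_real_,
      mean = if (length(values)) mean(values) else NA_real_)
  }, numeric(3))
}

# Draw the per-order tuple list once (same enumeration rule as scan()).
fixed_tuple_list <- function(n_vars, config, target_idx = NULL) {
  pool <- if (is.null(target_idx)) seq_len(n_vars) else
    setdiff(seq_len(n_vars), target_idx)
  lapply(config$orders, function(k) {
    dr <- draw_tuples(length(pool), k, config$budget, child_seed(config$seed, k))
    matrix(pool[dr$tuples], nrow = k)
  })
}

#' Bootstrap band for a per-order scan statistic
#'
#' Each replicate draws `sample_size` rows without replacement, re-estimates
#' the covariance, and re-evaluates the scan on a tuple list drawn once from
#' the configuration, so the band width reflects sampling of rows rather
#' than of tuples. The 95% band is the percentile interval across
#' replicates.
#'
#' @param data a [data_matrix()] (or generator output).
#' @param config a [scan_config()].
#' @param n_reps bootstrap repetitions (default 50).
#' @param sample_size rows drawn per replicate, without replacement (default
#'   `min(1000, n)`).
#' @param statistic per-order statistic to band: `"min"`, `"max"`, `"mean"`.
#' @param seed integer seed.
#' @param guard apply [dataset_guard()] first (default TRUE).
#' @return object of class `bootstrap_band`: data frame (order, mean, sd,
#'   ci_low, ci_high) plus settings and the replicate matrix.
#' @export
bootstrap_band <- function(data, config, n_reps = 50L, sample_size = NULL,
                           statistic = c("min", "max", "mean"), seed = 1L,
                           guard = TRUE) {
  data <- as_data_matrix(data)
  statistic <- match.arg(statistic)
  if (guard) {
    g <- dataset_guard(data)
    if (!g$pass)
      stop("dataset excluded from resampling: ", g$reason, call. = FALSE)
  }
  n <- nrow(data$values)
  sample_size <- as.integer(sample_size %||% min(1000L, n))
  if (sample_size > n)
    stop("'sample_size' exceeds the number of samples", call. = FALSE)
  if (n_reps < 2L) stop("'n_reps' must be >= 2", call. = FALSE)
  target_idx <- if (config$measure == "rsi")
    match(config$target, data$variable_names) else NULL
  tl <- fixed_tuple_list(ncol(data$values), config, target_idx)
  reps <- with_seed(seed, {
    vapply(seq_len(n_reps), function(r) {
      rows <- sample.int(n, sample_size)
      sg <- cov(data$values[rows, , drop = FALSE])
      eval_tuple_list(sg, tl, config, target_idx)[statistic, ]
    }, numeric(length(config$orders)))
  })
  reps <- matrix(reps, nrow = length(config$orders))  # orders x reps
  band <- data.frame(
    order = config$orders,
    mean = rowMeans(reps),
    sd = apply(reps, 1L, sd),
    ci_low = apply(reps, 1L, quantile, probs = 0.025, na.rm = TRUE),
    ci_high = apply(reps, 1L, quantile, probs = 0.975, na.rm = TRUE))
  structure(list(band = band, replicates = reps, statistic = statistic,
                 n_reps = as.integer(n_reps), sample_size = sample_size,
                 seed = as.integer(seed)),
            class = "bootstrap_band")
}

#' @export
print.bootstrap_band <- function(x, ...) {
  cat(sprintf("<bootstrap_band> statistic '%s', %d reps of %d samples\n",
              x$statistic, x$n_reps, x$sample_size))
  print(x$band, row.names = FALSE)
  invisible(x)
}

#' Column-shuffle surrogate extrema band
#'
#' Each surrogate independently permutes every column of the data,
#' destroying all cross-variable dependence while preserving each marginal
#' exactly, then re-estimates the covariance and re-evaluates the scan on a
#' fixed tuple list. Reports per-order extrema over surrogates: the band an
#' observed trajectory must escape to indicate genuine structure.
#'
#' @inheritParams bootstrap_band
#' @param n_surrogates number of shuffled surrogates (default 100).
#' @return object of class `surrogate_band`: data frame (order,
#'   max_positive, min_negative, mean) plus settings.
#' @export
shuffle_surrogates <- function(data, config, n_surrogates = 100L, seed = 1L) {
  data <- as_data_matrix(data)
  if (n_surrogates < 1L) stop("'n_surrogates' must be >= 1", call. = FALSE)
  x <- data$values
  target_idx <- if (config$measure == "rsi")
    match(config$target, data$variable_names) else NULL
  tl <- fixed_tuple_list(ncol(x), config, target_idx)
  res <- with_seed(seed, {
    lapply(seq_len(n_surrogates), function(s) {
      xs <- apply(x, 2L, sample)
      eval_tuple_list(cov(xs), tl, config, target_idx)
    })
  })
  maxs <- sapply(res, function(m) m["max", ])
  mins <- sapply(res, function(m) m["min", ])
  means <- sapply(res, function(m) m["mean", ])
  maxs <- matrix(maxs, nrow = length(config$orders))
  mins <- matrix(mins, nrow = length(config$orders))
  means <- matrix(means, nrow = length(config$orders))
  band <- data.frame(order = config$orders,
                     max_positive = apply(maxs, 1L, max, na.rm = TRUE),
                     min_negative = apply(mins, 1L, min, na.rm = TRUE),
                     mean = rowMeans(means, na.rm = TRUE))
  structure(list(band = band, n_surrogates = as.integer(n_surrogates),
                 seed = as.integer(seed)),
            class = "surrogate_band")
}

#' @export
print.surrogate_band <- function(x, ...) {
  cat(sprintf("<surrogate_band> %d column-shuffle surrogates\n",
              x$n_surrogates))
  print(x$band, row.names = FALSE)
  invisible(x)
}

# Trapezoidal areas of the positive and negative parts of a piecewise-linear
# curve, handling zero crossings exactly.
split_auc <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  pos <- 0; neg <- 0
  for (i in seq_len(length(x) - 1L)) {
    x1 <- x[i]; x2 <- x[i + 1L]; y1 <- y[i]; y2 <- y[i + 1L]
    if (is.na(y1) || is.na(y2)) next
    if (y1 * y2 >= 0) {
      a <- (y1 + y2) / 2 * (x2 - x1)
      if (y1 + y2 >= 0) pos <- pos + a else neg <- neg + a
    } else {
      xc <- x1 + (x2 - x1) * y1 / (y1 - y2)
      a1 <- y1 / 2 * (xc - x1)
      a2 <- y2 / 2 * (x2 - xc)
      if (y1 > 0) { pos <- pos + a1; neg <- neg + a2 }
      else { neg <- neg + a1; pos <- pos + a2 }
    }
  }
  c(pos = pos, neg = abs(neg))
}

#' Absolute AUC summary of an O-information trajectory
#'
#' Trapezoidal area under the per-order curve across tuple orders, split
#' into a redundancy AUC (area of the positive part) and a synergy AUC
#' (absolute area of the negative part). By default (`statistic =
#' "extrema"`) the synergy AUC is computed from the per-order minima and the
#' redundancy AUC from the per-order maxima; a single statistic may be used
#' for both parts instead.
#'
#' @param curve an `info_curve`.
#' @param statistic `"extrema"` (default), `"min"`, `"max"`, or `"mean"`.
#' @return object of class `auc_summary`: `synergy_auc`, `redundancy_auc`
#'   (both nonnegative), `order_range`, `statistic`.
#' @export
oinfo_auc <- function(curve, statistic = c("extrema", "min", "max", "mean")) {
  stopifnot(inherits(curve, "info_curve"))
  statistic <- match.arg(statistic)
  x <- curve$orders
  if (statistic == "extrema") {
    syn <- split_auc(x, curve_statistic(curve, "min"))[["neg"]]
    red <- split_auc(x, curve_statistic(curve, "max"))[["pos"]]
  } else {
    a <- split_auc(x, curve_statistic(curve, statistic))
    syn <- a[["neg"]]; red <- a[["pos"]]
  }
  structure(list(synergy_auc = syn, redundancy_auc = red,
                 order_range = range(x), statistic = statistic),
            class = "auc_summary")
}

#' @export
print.auc_summary <- function(x, ...) {
  cat(sprintf(
    "<auc_summary> synergy %.4g, redundancy %.4g (orders %d-%d, %s)\n",
    x$synergy_auc, x$redundancy_auc, x$order_range[1], x$order_range[2],
    x$statistic))
  invisible(x)
}

#' Two-sided rank-sum comparison of two AUC groups
#'
#' Mann-Whitney U (Wilcoxon rank-sum) test via [stats::wilcox.test()]; exact
#' when sample sizes permit and there are no ties.
#'
#' @param auc_group_a,auc_group_b numeric vectors (non-empty).
#' @return two-sided p-value.
#' @export
compare_groups <- function(auc_group_a, auc_group_b) {
  if (!length(auc_group_a) || !length(auc_group_b))
    stop("both groups must be non-empty", call. = FALSE)
  suppressWarnings(
    wilcox.test(auc_group_a, auc_group_b, alternative = "two.sided")$p.value)
}
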