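#' Histogram mutual information with permutation significance
#'
#' Model-free pairwise dependence screening: plug-in mutual information on an
#' equal-width binning, a column-shuffle permutation null, and
#' Benjamini-Hochberg FDR control with a minimum effect-size threshold. Used
#' for parameter-parameter and parameter-feature maps.
#'
#' @name empirical_mi
NULL

#' Equal-width binning scheme for a set of variables
#'
#' @param x numeric matrix (samples x variables) or vector.
#' @param n_bins number of equal-width bins per variable (>= 2).
#' @return an object of class `binning_scheme`: per-variable edges plus a
#'   flag for constant (zero-range) variables.
#' @export
binning_scheme <- function(x, n_bins = 10L) {
  if (!is.numeric(n_bins) || n_bins < 2L)
    stop("'n_bins' must be an integer >= 2", call. = FALSE)
  n_bins <- as.integer(n_bins)
  if (is.vector(x)) x <- matrix(x, ncol = 1L)
  edges <- lapply(seq_len(ncol(x)), function(j) {
    r <- range(x[, j])
    if (r[1] == r[2]) return(NULL)  # constant variable
    seq(r[1], r[2], length.out = n_bins + 1L)
  })
  structure(list(n_bins = n_bins, strategy = "equal_width",
                 per_variable_edges = edges,
                 constant = vapply(edges, is.null, logical(1))),
            class = "binning_scheme")
}

# 1-based equal-width bin indices; constant vectors map to bin 1.
bin_indices <- function(x, n_bins) {
  r <- range(x)
  if (r[1] == r[2]) return(structure(rep(1L, length(x)), constant = TRUE))
  edges <- seq(r[1], r[2], length.out = n_bins + 1L)
  findInterval(x, edges, rightmost.closed = TRUE, all.inside = TRUE)
}

#' Plug-in histogram mutual information
#'
#' MI of the 2-D histogram of `x` and `y` under equal-width binning, in
#' nats. A constant input yields MI 0 with a warning (not an error).
#'
#' @param x,y numeric vectors of equal length (>= 10).
#' @param n_bins bins per variable (default 10).
#' @return scalar MI in nats.
#' @export
histogram_mi <- function(x, y, n_bins = 10L) {
  if (length(x) != length(y)) stop("'x' and 'y' lengths differ", call. = FALSE)
  if (length(x) < 10L) stop("need at least 10 observations", call. = FALSE)
  if (!all(is.finite(x)) || !all(is.finite(y)))
    stop("non-finite values in input", call. = FALSE)
  bx <- bin_indices(x, n_bins); by <- bin_indices(y, n_bins)
  if (isTRUE(attr(bx, "constant")) || isTRUE(attr(by, "constant")))
    warning("constant input vector: MI is 0 by construction")
  hist_mi_cpp(as.integer(bx), as.integer(by), n_bins, n_bins)
}

#' Permutation test for histogram mutual information
#'
#' Shuffles `y` (`n_perm` times) to form the null; the add-one estimate
#' p = (1 + #\{MI_perm >= MI_obs\}) / (1 + n_perm) never returns exactly 0.
#' Bit-reproducible for a fixed seed.
#'
#' @inheritParams histogram_mi
#' @param n_perm number of permutations (default 1000).
#' @param seed integer seed.
#' @return list with `mi` (observed, nats) and `p`.
#' @export
permutation_test_mi <- function(x, y, n_bins = 10L, n_perm = 1000L, seed = 1L) {
  if (length(x) != length(y)) stop("'x' and 'y' lengths differ", call. = FALSE)
  if (n_perm < 1L) stop("'n_perm' must be >= 1", call. = FALSE)
  bx <- bin_indices(x, n_bins); by <- bin_indices(y, n_bins)
  perm_test_mi_cpp(as.integer(bx), as.integer(by), as.integer(n_bins),
                   as.integer(n_bins), as.integer(n_perm), as.integer(seed))
}

#' Benjamini-Hochberg FDR step-up
#'
#' Standard BH adjustment (via [stats::p.adjust()]) plus the rejection mask
#' at level `alpha`.
#'
#' @param p_values vector of p-values in (0, 1].
#' @param alpha FDR level (default 0.05).
#' @return list with `rejected` (logical) and `q_values`.
#' @export
bh_fdr <- function(p_values, alpha = 0.05) {
  if (length(p_values) == 0L)
    return(list(rejected = logical(0), q_values = numeric(0)))
  if (any(!is.na(p_values) & (p_values <= 0 | p_values > 1)))
    stop("p-values must lie in (0, 1]", call. = FALSE)
  q <- p.adjust(p_values, method = "BH")
  list(rejected = !is.na(q) & q <= alpha, q_values = q)
}

#' Significant-pair mutual information map
#'
#' Tests all unordered variable pairs of `data` (or, if `features` is given,
#' all variable-by-feature pairs) with the permutation null, applies BH FDR
#' at `alpha`, and additionally requires `mi > mi_threshold` (nats) as a
#' minimum effect size for a pair to be called significant. Also reports how
#' many variables participate in at least one significant pair.
#'
#' @param data a [data_matrix()] of variables.
#' @param features optional [data_matrix()] of targets aligned to the same
#'   samples (rectangular map).
#' @param alpha FDR level (default 0.05).
#' @param mi_threshold minimum MI effect size in nats (default 0.1).
#' @param n_bins equal-width bins per variable (default 10).
#' @param n_perm permutations per pair (default 1000).
#' @param seed integer seed.
#' @return an object of class `mi_matrix`: `mi`, `p_values`, `q_values`,
#'   `significant`, `n_significant_variables`, plus settings.
#' @export
significant_pair_map <- function(data, features = NULL, alpha = 0.05,
                                 mi_threshold = 0.1, n_bins = 10L,
                                 n_perm = 1000L, seed = 1L) {
  data <- as_data_matrix(data)
  x <- data$values
  XB <- vapply(seq_len(ncol(x)), function(j) as.integer(bin_indices(x[, j], n_bins)),
               integer(nrow(x)))
  nbX <- rep(as.integer(n_bins), ncol(x))
  cross <- !is.null(features)
  if (cross) {
    features <- as_data_matrix(features)
    if (nrow(features$values) != nrow(x))
      stop("'features' sample count does not match 'data'", call. = FALSE)
    y <- features$values
    YB <- vapply(seq_len(ncol(y)), function(j) as.integer(bin_indices(y[, j], n_bins)),
                 integer(nrow(y)))
    nbY <- rep(as.integer(n_bins), ncol(y))
  } else {
    YB <- matrix(integer(0), nrow = nrow(x), ncol = 0)
    nbY <- integer(0)
  }
  res <- mi_perm_pairs_cpp(XB, nbX, YB, nbY, as.integer(n_perm),
                           as.integer(seed))
  mi <- res$mi; p <- res$p
  if (cross) {
    dimnames(mi) <- dimnames(p) <-
      list(data$variable_names, features$variable_names)
    pv <- as.vector(p)
    adj <- bh_fdr(pv, alpha)
    q <- matrix(adj$q_values, nrow(p), ncol(p), dimnames = dimnames(p))
  } else {
    dimnames(mi) <- dimnames(p) <-
      list(data$variable_names, data$variable_names)
    ut <- upper.tri(p)
    adj <- bh_fdr(p[ut], alpha)
    q <- matrix(NA_real_, nrow(p), ncol(p), dimnames = dimnames(p))
    q[ut] <- adj$q_values
    q[lower.tri(q)] <- t(q)[lower.tri(q)]
  }
  significant <- !is.na(q) & q <= alpha & mi > mi_threshold
  participating <- if (cross) {
    sum(rowSums(significant) > 0L)
  } else {
    sum(rowSums(significant, na.rm = TRUE) > 0L)
  }
  structure(list(mi = mi, p_values = p, q_values = q, significant = significant,
                 n_significant_variables = participating,
                 n_permutations = as.integer(n_perm), alpha = alpha,
                 mi_threshold = mi_threshold, n_bins = as.integer(n_bins),
                 seed = as.integer(seed)),
            class = "mi_matrix")
}

#' @export
print.mi_matrix <- function(x, ...) {
  cat(sprintf(
    "<mi_matrix> %d x %d, %d significant pair(s) (q <= %g & MI > %g), %d variable(s) participating\n",
    nrow(x$mi), ncol(x$mi), sum(x$significant, na.rm = TRUE) /
      (if (isTRUE(all.equal(rownames(x$mi), colnames(x$mi)))) 2L else 1L),
    x$alpha, x$mi_threshold, x$n_significant_variables))
  invisible(x)
}

#' Export a significance map as a long table
#'
#' @param x an `mi_matrix`.
#' @return data frame (var_a, var_b, mi_nats, p, q, significant), one row per
#'   tested pair.
#' @export
mi_map_table <- function(x) {
  stopifnot(inherits(x, "mi_matrix"))
  square <- identical(rownames(x$mi), colnames(x$mi))
  if (square) {
    ij <- which(upper.tri(x$mi), arr.ind = TRUE)
  } else {
    ij <- as.matrix(expand.grid(seq_len(nrow(x$mi)), seq_len(ncol(x$mi))))
  }
  data.frame(var_a = rownames(x$mi)[ij[, 1]], var_b = colnames(x$mi)[ij[, 2]],
             mi_nats = x$mi[ij], p = x$p_values[ij], q = x$q_values[ij],
             significant = x$significant[ij], stringsAsFactors = FALSE)
}
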