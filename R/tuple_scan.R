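#' Tuple scans across interaction orders
#'
#' Evaluates O-information (or RSI against a target) over variable tuples of
#' increasing order, exhaustively when the number of combinations fits the
#' budget and by seeded uniform sampling of distinct tuples otherwise. The
#' resulting per-order curves are the package's central object: their
#' extrema trace synergy/redundancy growth, their top fraction defines
#' variable frequency maps, and their plateaus define minimal synergistic
#' sets and stabilization orders.
#'
#' @name tuple_scan
NULL

#' Scan configuration
#'
#' @param orders integer vector of tuple orders to evaluate (min 3 for
#'   O-information, min 1 for RSI predictor sets).
#' @param budget maximum tuples evaluated per order; orders with
#'   `choose(n, k) <= budget` are enumerated exhaustively, larger orders are
#'   sampled uniformly without replacement (default 20000).
#' @param seed integer seed for tuple sampling.
#' @param measure `"oinfo"` or `"rsi"`.
#' @param target target variable name (required for RSI; excluded from
#'   tuples).
#' @param convention RSI sign convention (see [rsi()]).
#' @return an object of class `scan_config`.
#' @export
scan_config <- function(orders, budget = 20000L, seed = 1L,
                        measure = c("oinfo", "rsi"), target = NULL,
                        convention = c("results", "printed")) {
  measure <- match.arg(measure)
  convention <- match.arg(convention)
  orders <- sort(unique(as.integer(orders)))
  min_order <- if (measure == "oinfo") 3L else 1L
  if (length(orders) == 0L || any(orders < min_order))
    stop(sprintf("orders must be >= %d for measure '%s'", min_order, measure),
         call. = FALSE)
  if (budget < 1L) stop("'budget' must be >= 1", call. = FALSE)
  if (measure == "rsi" && is.null(target))
    stop("RSI scans require a 'target'", call. = FALSE)
  structure(list(orders = orders, budget = as.integer(budget),
                 seed = as.integer(seed), measure = measure, target = target,
                 convention = convention),
            class = "scan_config")
}

# Distinct k-subsets of 1..n as a k x m matrix: exhaustive if feasible,
# else seeded uniform sampling without replacement.
draw_tuples <- function(n, k, budget, seed) {
  total <- choose(n, k)
  if (total <= budget) {
    return(list(tuples = if (k == n) matrix(seq_len(n), ncol = 1L)
                         else combn(n, k),
                exhaustive = TRUE))
  }
  tuples <- with_seed(seed, {
    seen <- new.env(hash = TRUE)
    out <- matrix(0L, nrow = k, ncol = budget)
    got <- 0L
    tries <- 0L
    max_tries <- budget * 50L
    while (got < budget && tries < max_tries) {
      tries <- tries + 1L
      t_ <- sort(sample.int(n, k))
      key <- paste(t_, collapse = ",")
      if (is.null(seen[[key]])) {
        seen[[key]] <- TRUE
        got <- got + 1L
        out[, got] <- t_
      }
    }
    out[, seq_len(got), drop = FALSE]
  })
  list(tuples = tuples, exhaustive = FALSE)
}

#' Scan O-information or RSI across tuple orders
#'
#' @param x a [covariance_model()], [data_matrix()], numeric matrix, or
#'   generator output.
#' @param config a [scan_config()].
#' @return an object of class `info_curve`: per order the evaluated tuples
#'   (k x m index matrix into `variable_names`) and their values (nats), a
#'   `summary` data frame (order, min, max, mean, sd, n_evaluated,
#'   exhaustive, n_skipped), and the scan settings. Tuples whose covariance
#'   submatrix is singular are skipped and tallied, not errors.
#' @examples
#' dm <- gen_redundant(400, 6, seed = 1)$data
#' curve <- scan(dm, scan_config(3:6, seed = 1))
#' curve$summary
#' @export
scan <- function(x, config) {
  stopifnot(inherits(config, "scan_config"))
  cov <- if (inherits(x, "covariance_model")) x else estimate_covariance(x)
  vars <- cov$variable_names
  if (config$measure == "rsi") {
    it <- resolve_subset(cov, config$target, "target")
    pool <- setdiff(seq_along(vars), it)
  } else {
    it <- NULL
    pool <- seq_along(vars)
  }
  n_pool <- length(pool)
  if (max(config$orders) > n_pool)
    stop(sprintf("largest order (%d) exceeds the %d available variables",
                 max(config$orders), n_pool), call. = FALSE)
  per_order <- vector("list", length(config$orders))
  names(per_order) <- as.character(config$orders)
  sm <- vector("list", length(config$orders))
  for (i in seq_along(config$orders)) {
    k <- config$orders[i]
    dr <- draw_tuples(n_pool, k, config$budget,
                      child_seed(config$seed, k))
    tuples <- matrix(pool[dr$tuples], nrow = k)
    values <- if (config$measure == "oinfo") {
      oinfo_batch_cpp(cov$sigma, tuples)
    } else {
      v <- rsi_batch_cpp(cov$sigma, tuples, it)
      if (config$convention == "results") -v else v
    }
    ok <- !is.na(values)
    per_order[[i]] <- list(tuples = tuples[, ok, drop = FALSE],
                           values = values[ok])
    vv <- values[ok]
    sm[[i]] <- data.frame(
      order = k,
      min = if (length(vv)) min(vv) else NA_real_,
      max = if (length(vv)) max(vv) else NA_real_,
      mean = if (length(vv)) mean(vv) else NA_real_,
      sd = if (length(vv) > 1) sd(vv) else NA_real_,
      n_evaluated = length(vv),
      exhaustive = dr$exhaustive,
      n_skipped = sum(!ok))
  }
  structure(list(per_order = per_order, summary = do.call(rbind, sm),
                 orders = config$orders, measure = config$measure,
                 target = if (!is.null(it)) vars[it] else NULL,
                 convention = if (config$measure == "rsi") config$convention else NULL,
                 variable_names = vars, config = config),
            class = "info_curve")
}

#' @export
print.info_curve <- function(x, ...) {
  cat(sprintf("<info_curve> %s%s over orders %s\n", x$measure,
              if (!is.null(x$target)) paste0(" -> ", x$target) else "",
              paste(range(x$orders), collapse = "-")))
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Per-order curve of a scan statistic
#'
#' @param curve an `info_curve`.
#' @param statistic `"min"`, `"max"`, or `"mean"`.
#' @return numeric vector named by order.
#' @export
curve_statistic <- function(curve, statistic = c("min", "max", "mean")) {
  stopifnot(inherits(curve, "info_curve"))
  statistic <- match.arg(statistic)
  setNames(curve$summary[[statistic]], curve$summary$order)
}

#' Top-fraction variable frequency map
#'
#' For each order, selects the `ceiling(fraction * n_evaluated)` most extreme
#' tuples (`side = "min"` for synergy, `"max"` for redundancy; at least one
#' tuple) and reports how often each variable appears among them, normalized
#' by the number of selected tuples. Each selected tuple contributes `order`
#' memberships, so every column sums to its order.
#'
#' @param curve an `info_curve`.
#' @param fraction fraction of tuples per order to keep (default 0.05).
#' @param side extremum side: `"min"` (default) or `"max"`.
#' @return an object of class `frequency_map`: a variables x orders matrix
#'   of frequencies in \[0, 1\].
#' @export
top_fraction_frequency <- function(curve, fraction = 0.05,
                                   side = c("min", "max")) {
  stopifnot(inherits(curve, "info_curve"))
  side <- match.arg(side)
  if (!is.numeric(fraction) || fraction <= 0 || fraction > 1)
    stop("'fraction' must be in (0, 1]", call. = FALSE)
  vars <- curve$variable_names
  freq <- matrix(0, nrow = length(vars), ncol = length(curve$orders),
                 dimnames = list(vars, as.character(curve$orders)))
  for (i in seq_along(curve$orders)) {
    po <- curve$per_order[[i]]
    m <- length(po$values)
    if (m == 0L) stop("empty curve at order ", curve$orders[i], call. = FALSE)
    nsel <- max(1L, ceiling(fraction * m))
    ord <- order(po$values, decreasing = (side == "max"))[seq_len(nsel)]
    counts <- tabulate(po$tuples[, ord, drop = FALSE], nbins = length(vars))
    freq[, i] <- counts / nsel
  }
  structure(freq, class = c("frequency_map", "matrix"),
            fraction = fraction, side = side)
}

#' Minimal set achieving the curve's extremum
#'
#' Finds the smallest order whose per-order extremum comes within `tolerance`
#' of the global extremum across all scanned orders (the plateau criterion),
#' and returns that order's best tuple; ties between equal-valued tuples are
#' broken lexicographically.
#'
#' @param curve an `info_curve` over contiguous orders.
#' @param tolerance absolute tolerance; default 1% of the magnitude of the
#'   global extremum.
#' @param side `"min"` (default, maximum synergy under the results
#'   convention) or `"max"`.
#' @return an object of class `minimal_set`: `order`, `tuple` (variable
#'   names), `value_nats`, `tolerance`.
#' @export
minimal_synergistic_set <- function(curve, tolerance = NULL,
                                    side = c("min", "max")) {
  stopifnot(inherits(curve, "info_curve"))
  side <- match.arg(side)
  stat <- curve_statistic(curve, side)
  if (!length(stat) || all(is.na(stat))) stop("empty curve", call. = FALSE)
  global <- if (side == "min") min(stat, na.rm = TRUE) else max(stat, na.rm = TRUE)
  tolerance <- tolerance %||% (0.01 * abs(global))
  hit <- if (side == "min") stat <= global + tolerance else stat >= global - tolerance
  i <- which(hit)[1L]
  po <- curve$per_order[[i]]
  best_val <- if (side == "min") min(po$values) else max(po$values)
  cand <- which(po$values == best_val)
  if (length(cand) > 1L) {  # lexicographically first tuple
    keys <- apply(po$tuples[, cand, drop = FALSE], 2L,
                  function(t_) paste(sprintf("%06d", t_), collapse = ","))
    cand <- cand[order(keys)][1L]
  }
  structure(list(order = curve$orders[i],
                 tuple = curve$variable_names[po$tuples[, cand[1L]]],
                 value_nats = best_val, tolerance = tolerance),
            class = "minimal_set")
}

#' @export
print.minimal_set <- function(x, ...) {
  cat(sprintf("<minimal_set> order %d: {%s} = %.6g nats (tolerance %.3g)\n",
              x$order, paste(x$tuple, collapse = ", "), x$value_nats,
              x$tolerance))
  invisible(x)
}

#' Detect the stabilization point of a per-order trajectory
#'
#' Applies the discrete second-difference rule: for interior positions
#' \eqn{i}, \eqn{d_2[i] = s[i+1] - 2 s[i] + s[i-1]}; the stabilization point
#' is the position with the minimum second difference ("steepest
#' concavity"), marking the transition from rapid decay to plateau. Ties
#' take the first interior position. Positions are 1-based indices into
#' `series`. An alternative knee detector (`method = "max_abs_d2"`,
#' maximum curvature magnitude) is available but not the default.
#'
#' @param series numeric vector of per-order values (length >= 3).
#' @param method `"min_d2"` (default) or `"max_abs_d2"`.
#' @return integer position of the stabilization point in `series`.
#' @examples
#' detect_stabilization(c(0, -3, -4.5, -5, -5, -5))  # position 5
#' @export
detect_stabilization <- function(series, method = c("min_d2", "max_abs_d2")) {
  method <- match.arg(method)
  if (length(series) < 3L) stop("'series' must have length >= 3", call. = FALSE)
  if (!all(is.finite(series))) stop("non-finite values in 'series'", call. = FALSE)
  n <- length(series)
  i <- 2:(n - 1L)
  d2 <- series[i + 1L] - 2 * series[i] + series[i - 1L]
  j <- if (method == "min_d2") which.min(d2) else which.max(abs(d2))
  as.integer(i[j])
}
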