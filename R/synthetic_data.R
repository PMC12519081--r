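#' Seeded synthetic ensemble generators
#'
#' Generators that emulate the statistical structures higher-order
#' information analysis probes: independent baselines, latent-factor
#' coexpression (redundancy-rich), populations conditioned on a shared
#' phenotype constraint (anti-correlated, synergy-rich), mixtures of tight
#' clusters (the oversampling effect), feature maps from parameters to
#' electrophysiological targets, and zero-inflated count matrices with
#' subtype-informative gene panels. Every generator is bit-reproducible
#' under a fixed seed and records its full configuration in the returned
#' truth block.
#'
#' @name synthetic_data
NULL

new_labeled_dataset <- function(data, truth) {
  structure(list(data = data, truth = truth), class = "labeled_dataset")
}

#' @export
print.labeled_dataset <- function(x, ...) {
  cat(sprintf("<labeled_dataset> kind '%s'\n", x$truth$kind))
  print(x$data)
  invisible(x)
}

#' Independent Gaussian ensemble
#'
#' iid standard normal columns; the null ensemble whose O-information
#' fluctuates around zero at every order.
#'
#' @param n samples.
#' @param p variables.
#' @param seed integer seed (mandatory).
#' @return a `labeled_dataset` whose `data` is a [data_matrix()] and whose
#'   `truth` records the configuration and the population covariance.
#' @export
gen_independent <- function(n, p, seed) {
  x <- with_seed(seed, matrix(rnorm(n * p), n, p))
  colnames(x) <- paste0("V", seq_len(p))
  new_labeled_dataset(
    data_matrix(x),
    list(kind = "independent", n = n, p = p, seed = seed,
         sigma_pop = diag(p)))
}

#' Latent-factor coexpression ensemble (redundancy-rich)
#'
#' \eqn{X = Z L^\top + E} with iid standard normal factors \eqn{Z} and
#' independent noise; shared factors make all loaded variables covary, the
#' canonical redundancy structure. Population covariance
#' \eqn{L L^\top + \sigma^2 I}. The default (one factor, unit loadings,
#' unit noise) gives every triple an O-information of
#' \eqn{\frac12\ln(32/27) \approx +0.085} nats.
#'
#' @param n samples.
#' @param p variables.
#' @param n_factors latent factors (default 1).
#' @param loadings scalar, length-`n_factors` vector, or `p x n_factors`
#'   matrix of factor loadings (default 1).
#' @param noise_sd independent noise SD (default 1).
#' @param seed integer seed.
#' @return a `labeled_dataset` (truth holds the loadings matrix and the
#'   population covariance).
#' @export
gen_redundant <- function(n, p, n_factors = 1L, loadings = 1, noise_sd = 1,
                          seed = 1L) {
  if (!is.matrix(loadings)) {
    loadings <- matrix(rep_len(loadings, n_factors), nrow = p,
                       ncol = n_factors, byrow = TRUE)
  }
  stopifnot(nrow(loadings) == p, all(is.finite(loadings)), noise_sd >= 0)
  x <- with_seed(seed, {
    z <- matrix(rnorm(n * ncol(loadings)), n)
    z %*% t(loadings) + matrix(rnorm(n * p, sd = noise_sd), n, p)
  })
  colnames(x) <- paste0("V", seq_len(p))
  new_labeled_dataset(
    data_matrix(x),
    list(kind = "latent_factor", n = n, p = p, loadings = loadings,
         noise_sd = noise_sd, seed = seed,
         sigma_pop = tcrossprod(loadings) + diag(noise_sd^2, p)))
}

#' Constraint-conditioned ensemble (synergy-rich)
#'
#' Standard normal variables conditioned exactly (via the conditional
#' Gaussian, not accept-reject) on a soft linear phenotype constraint
#' \eqn{w^\top X = y_0 + \eta}, \eqn{\eta \sim N(0, \tau^2)}: the degenerate
#' solution-manifold structure of parameter populations that all realize one
#' electrical phenotype. Variables with zero weight are untouched, so a
#' constrained trio can be planted among independent background variables.
#' Population covariance \eqn{(I - ww^\top/\|w\|^2) + ww^\top\tau^2/\|w\|^4}.
#'
#' @param n samples.
#' @param p variables.
#' @param weights length-`p` constraint weights (zeros = unconstrained;
#'   default all 1).
#' @param y0 constraint target (default 0).
#' @param tau constraint looseness SD (default 0.5). `tau = sqrt(sum(w^2))`
#'   matches the unconstrained variance of \eqn{w^\top X} and reproduces the
#'   independent ensemble exactly; smaller values tighten the constraint
#'   (synergy), larger values over-disperse the constrained direction
#'   (redundancy along `w`).
#' @param seed integer seed.
#' @return a `labeled_dataset` (truth holds weights, tau, the constrained
#'   variable indices and the population covariance).
#' @export
gen_synergistic <- function(n, p, weights = rep(1, p), y0 = 0, tau = 0.5,
                            seed = 1L) {
  weights <- rep_len(as.numeric(weights), p)
  w2 <- sum(weights^2)
  if (w2 == 0) stop("'weights' must not be all zero", call. = FALSE)
  if (tau < 0) stop("'tau' must be nonnegative", call. = FALSE)
  x <- with_seed(seed, {
    x0 <- matrix(rnorm(n * p), n, p)
    t_ <- rnorm(n, mean = y0, sd = tau)
    x0 - outer(as.vector(x0 %*% weights) - t_, weights) / w2
  })
  colnames(x) <- paste0("V", seq_len(p))
  proj <- diag(p) - tcrossprod(weights) / w2
  new_labeled_dataset(
    data_matrix(x),
    list(kind = "constraint", n = n, p = p, weights = weights, y0 = y0,
         tau = tau, seed = seed, constrained = which(weights != 0),
         sigma_pop = proj + tcrossprod(weights) * tau^2 / w2^2))
}

#' Constraint looseness for a target equicorrelation
#'
#' For `p` exchangeable unit-weight constrained variables, returns the `tau`
#' of [gen_synergistic()] that yields pairwise correlation `rho`
#' (\eqn{\tau^2 = p(1 + \rho(p-1))/(1-\rho)}); useful for constructing
#' ensembles with a known closed-form O-information.
#'
#' @param p number of constrained variables.
#' @param rho target pairwise correlation in (-1/(p-1), 1).
#' @return scalar `tau`.
#' @export
constraint_tau_for_correlation <- function(p, rho) {
  if (rho <= -1 / (p - 1) || rho >= 1)
    stop("'rho' must be in (-1/(p-1), 1)", call. = FALSE)
  sqrt(p * (1 + rho * (p - 1)) / (1 - rho))
}

#' Cluster-mixture ensemble (the oversampling effect)
#'
#' A mixture of tight Gaussian clusters at distinct centers. Three sampling
#' modes mirror how model repositories get sampled: `"unique"` draws one
#' sample from each of the K clusters (diverse, synergy-preserving when the
#' centers follow a constraint structure), `"oversampled"` draws many
#' samples from a few clusters (the cluster-identity axis acts as a shared
#' factor, driving redundancy), `"pooled"` draws from the mixture at given
#' weights.
#'
#' @param p variables.
#' @param K number of clusters (default 72).
#' @param mode `"unique"`, `"oversampled"`, or `"pooled"`.
#' @param n samples for `"pooled"` mode.
#' @param n_per samples per used cluster for `"oversampled"` (default 36).
#' @param n_clusters_used clusters drawn from in `"oversampled"` mode
#'   (default 2).
#' @param within_sd within-cluster SD (default 0.05; clusters are tight
#'   relative to the unit-scale center spread).
#' @param within_structure `"isotropic"` (default) or `"constraint"`:
#'   within-cluster offsets drawn isotropically or from a
#'   constraint-conditioned Gaussian (scaled by `within_sd`), for mixtures
#'   whose clusters themselves carry synergistic structure.
#' @param within_tau constraint looseness of within-cluster offsets when
#'   `within_structure = "constraint"` (default 0.3).
#' @param center_structure `"constraint"` (default; centers drawn from
#'   [gen_synergistic()]'s conditional Gaussian, so the across-cluster
#'   ensemble is synergy-rich) or `"independent"`.
#' @param center_tau constraint looseness for the centers (default 0.3).
#' @param center_sd center SD for `"independent"` structure (default 1).
#' @param mix_weights mixing weights for `"pooled"` (default uniform).
#' @param seed integer seed.
#' @return a `labeled_dataset`; truth holds centers, cluster assignments,
#'   and the configuration. Cluster assignments are also exposed as
#'   `sample_labels` of the data matrix.
#' @export
gen_cluster_mixture <- function(p, K = 72L, mode = c("unique", "oversampled",
                                                     "pooled"),
                                n = NULL, n_per = 36L, n_clusters_used = 2L,
                                within_sd = 0.05,
                                center_structure = c("constraint",
                                                     "independent"),
                                center_tau = 0.3, center_sd = 1,
                                within_structure = c("isotropic",
                                                     "constraint"),
                                within_tau = 0.3,
                                mix_weights = NULL, seed = 1L) {
  mode <- match.arg(mode)
  center_structure <- match.arg(center_structure)
  within_structure <- match.arg(within_structure)
  if (K < 1L) stop("'K' must be >= 1", call. = FALSE)
  with_seed(seed, {
    centers <- if (center_structure == "constraint" && p >= 2L && K >= 2L) {
      gen_synergistic(K, p, tau = center_tau,
                      seed = child_seed(seed, 1L))$data$values
    } else {
      matrix(rnorm(K * p, sd = center_sd), K, p)
    }
    assign_ <- switch(mode,
      unique = seq_len(K),
      oversampled = {
        used <- sample.int(K, n_clusters_used)
        rep(used, each = n_per)
      },
      pooled = {
        if (is.null(n)) stop("'n' required for pooled mode", call. = FALSE)
        sample.int(K, n, replace = TRUE,
                   prob = mix_weights %||% rep(1 / K, K))
      })
    m <- length(assign_)
    offsets <- if (within_structure == "constraint" && p >= 2L && m >= 2L) {
      within_sd * gen_synergistic(m, p, tau = within_tau,
                                  seed = child_seed(seed, 2L))$data$values
    } else {
      matrix(rnorm(m * p, sd = within_sd), m, p)
    }
    x <- centers[assign_, , drop = FALSE] + offsets
    colnames(x) <- paste0("V", seq_len(p))
    new_labeled_dataset(
      data_matrix(x, sample_labels = paste0("c", assign_)),
      list(kind = "cluster_mixture", p = p, K = K, mode = mode,
           centers = centers, assignments = assign_, within_sd = within_sd,
           center_structure = center_structure, center_tau = center_tau,
           within_structure = within_structure, within_tau = within_tau,
           seed = seed))
  })
}

#' Feature map from parameters to a target e-feature
#'
#' Built-in functional forms emulating how electrophysiological features
#' depend on parameters: `"weighted_sum"` (a feature like resting membrane
#' potential, dominated by a 2-variable module: \eqn{Y = \sum w_i X_i +
#' \varepsilon}) and `"pairwise_products"` (a feature like the first
#' interspike interval, shaped by a broad multiplicative mix: \eqn{Y =
#' \sum_{i<j} (X_i + a)(X_j + a) + \varepsilon} over ~10 variables; the
#' offset `a` keeps the products linearly correlated with each variable).
#'
#' @param params a [data_matrix()] or generator output.
#' @param form `"weighted_sum"` or `"pairwise_products"`.
#' @param vars variable names used by the map (defaults: first 2 for
#'   `weighted_sum`, first `min(10, p)` for `pairwise_products`).
#' @param weights weights for `weighted_sum` (default all 1).
#' @param noise_sd additive Gaussian noise SD (default 0.1).
#' @param offset the `a` of `pairwise_products` (default 1).
#' @param seed integer seed.
#' @return list with `feature` (numeric vector, one value per sample) and
#'   `truth` (form, vars, weights, noise_sd, offset).
#' @export
gen_feature_map <- function(params, form = c("weighted_sum",
                                             "pairwise_products"),
                            vars = NULL, weights = NULL, noise_sd = 0.1,
                            offset = 1, seed = 1L) {
  form <- match.arg(form)
  params <- as_data_matrix(params)
  x <- params$values
  vars <- vars %||% params$variable_names[seq_len(
    if (form == "weighted_sum") 2L else min(10L, ncol(x)))]
  miss <- setdiff(vars, params$variable_names)
  if (length(miss))
    stop("unknown variable(s): ", paste(miss, collapse = ", "), call. = FALSE)
  xv <- x[, vars, drop = FALSE]
  y <- if (form == "weighted_sum") {
    weights <- rep_len(weights %||% 1, length(vars))
    as.vector(xv %*% weights)
  } else {
    xo <- xv + offset
    tot <- rowSums(xo)
    (tot^2 - rowSums(xo^2)) / 2  # sum over unordered pairs of products
  }
  y <- y + with_seed(seed, rnorm(nrow(x), sd = noise_sd))
  list(feature = y,
       truth = list(kind = "feature_map", form = form, vars = vars,
                    weights = if (form == "weighted_sum") weights else NULL,
                    noise_sd = noise_sd,
                    offset = if (form == "pairwise_products") offset else NULL,
                    seed = seed))
}

#' Append a feature column to a data matrix
#'
#' Convenience for RSI scans: binds a generated (or measured) target feature
#' as an extra named column.
#'
#' @param data a [data_matrix()].
#' @param feature numeric vector, one value per sample.
#' @param name column name for the feature.
#' @return a [data_matrix()] with one more variable.
#' @export
bind_feature <- function(data, feature, name = "feature") {
  data <- as_data_matrix(data)
  if (length(feature) != nrow(data$values))
    stop("'feature' length must equal the number of samples", call. = FALSE)
  x <- cbind(data$values, feature)
  colnames(x) <- c(data$variable_names, name)
  data_matrix(x, variable_annotations = data$variable_annotations,
              sample_labels = data$sample_labels)
}

#' Zero-inflated count matrix with a planted informative gene panel
#'
#' Counts are `Bernoulli(1 - zero_inflation) * round(LogNormal(mu + shift,
#' sdlog))` per cell and gene. A planted panel of genes carries per-subtype
#' shifts of the log-mean (drawn once, SD `shift_sd`), making it informative
#' about subtype; background genes have no shift. An optional per-cell
#' latent factor loads on the panel genes, inducing positive O-information
#' (coexpression) among them after preprocessing.
#'
#' @param n_cells cells.
#' @param n_genes genes.
#' @param n_subtypes ground-truth subtypes (default 3, balanced).
#' @param panel_size planted informative genes (default 150).
#' @param shift_sd SD of the per-subtype log-mean shifts (default 1).
#' @param zero_inflation dropout probability (default 0.3).
#' @param mu,sdlog log-normal location and scale (defaults 1, 0.5).
#' @param latent_factor add a shared per-cell factor on the panel genes
#'   (default FALSE).
#' @param factor_loading loading of that factor (default 0.5).
#' @param seed integer seed.
#' @return a `labeled_dataset` whose `data` is a raw [expression_matrix()]
#'   with `cell_labels`; `truth` holds the panel gene names/indices, the
#'   shift matrix, and the configuration.
#' @export
gen_counts <- function(n_cells = 300L, n_genes = 2000L, n_subtypes = 3L,
                       panel_size = 150L, shift_sd = 1, zero_inflation = 0.3,
                       mu = 1, sdlog = 0.5, latent_factor = FALSE,
                       factor_loading = 0.5, seed = 1L) {
  if (zero_inflation < 0 || zero_inflation > 1)
    stop("'zero_inflation' must be a probability", call. = FALSE)
  if (panel_size > n_genes)
    stop("'panel_size' exceeds 'n_genes'", call. = FALSE)
  with_seed(seed, {
    labels <- sort(rep_len(paste0("type", seq_len(n_subtypes)), n_cells))
    panel <- seq_len(panel_size)
    shifts <- matrix(0, n_genes, n_subtypes)
    shifts[panel, ] <- rnorm(panel_size * n_subtypes, sd = shift_sd)
    type_idx <- match(labels, paste0("type", seq_len(n_subtypes)))
    meanlog <- matrix(mu, n_cells, n_genes) + t(shifts[, type_idx])
    if (latent_factor) {
      z <- rnorm(n_cells)
      meanlog[, panel] <- meanlog[, panel] + factor_loading * z
    }
    counts <- matrix(rbinom(n_cells * n_genes, 1L, 1 - zero_inflation),
                     n_cells, n_genes) *
      round(matrix(rlnorm(n_cells * n_genes, meanlog = meanlog,
                          sdlog = sdlog), n_cells, n_genes))
    gene_names <- paste0("gene", seq_len(n_genes))
    colnames(counts) <- gene_names
    new_labeled_dataset(
      expression_matrix(counts, cell_labels = labels),
      list(kind = "counts", n_cells = n_cells, n_genes = n_genes,
           n_subtypes = n_subtypes, panel = gene_names[panel],
           panel_idx = panel, shifts = shifts, zero_inflation = zero_inflation,
           mu = mu, sdlog = sdlog, latent_factor = latent_factor,
           factor_loading = factor_loading, labels = labels, seed = seed))
  })
}
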