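test_that("generators are bit-reproducible and record their configuration", {
  gens <- list(
    function(s) gen_independent(50, 4, seed = s),
    function(s) gen_redundant(50, 4, seed = s),
    function(s) gen_synergistic(50, 4, seed = s),
    function(s) gen_cluster_mixture(4, K = 10, mode = "unique", seed = s),
    function(s) gen_counts(n_cells = 30, n_genes = 40, panel_size = 10,
                           seed = s))
  for (g in gens) {
    a <- g(11); b <- g(11); c_ <- g(12)
    expect_identical(a$data$values, b$data$values)
    expect_false(identical(a$data$values, c_$data$values))
    expect_true(is.list(a$truth) && !is.null(a$truth$kind))
  }
})

test_that("the independent generator matches its identity covariance", {
  ds <- gen_independent(2e4, 6, seed = 1)
  expect_lt(max(abs(estimate_covariance(ds$data)$sigma - diag(6))), 0.05)
  expect_identical(ds$truth$sigma_pop, diag(6))
  # the shared data container enforces at least two variables
  expect_error(gen_independent(100, 1, seed = 1), "at least 2")
})

test_that("the latent-factor generator carries its closed-form redundancy", {
  ds <- gen_redundant(1e4, 3, n_factors = 1, loadings = 1, noise_sd = 1,
                      seed = 2)
  # population: diag 2, off-diag 1 -> O-info = 0.5 * log(32/27)
  expect_equal(as.double(o_info(covariance_model(ds$truth$sigma_pop))),
               0.5 * log(32 / 27), tolerance = 1e-12)
  expect_equal(as.double(o_info(estimate_covariance(ds$data))),
               0.5 * log(32 / 27), tolerance = 0.02)
  # covariance recovery: L L' + diag within sampling error
  big <- gen_redundant(1e4, 5, loadings = 0.8, seed = 3)
  expect_lt(max(abs(estimate_covariance(big$data)$sigma -
                      big$truth$sigma_pop)), 0.08)
  # vanishing loadings reduce to the independent ensemble
  none <- gen_redundant(500, 4, loadings = 0, seed = 4)
  expect_equal(none$truth$sigma_pop, diag(4))
  # one shared factor: mean O-info nondecreasing with order
  cv <- scan(gen_redundant(5000, 6, seed = 5)$data, scan_config(3:6, seed = 1))
  expect_true(all(diff(curve_statistic(cv, "mean")) > 0))
})

test_that("the constraint generator induces the predicted anti-correlation and synergy", {
  tau <- constraint_tau_for_correlation(3, -0.45)
  ds <- gen_synergistic(5000, 3, tau = tau, seed = 6)
  pop <- covariance_model(ds$truth$sigma_pop)
  rho <- stats::cov2cor(pop$sigma)[1, 2]
  expect_equal(rho, -0.45, tolerance = 1e-12)
  expect_equal(as.double(o_info(pop)), oinfo_equicorr(-0.45),
               tolerance = 1e-12)
  expect_equal(as.double(o_info(estimate_covariance(ds$data))),
               oinfo_equicorr(-0.45), tolerance = 0.05)
  # sample covariance approaches the population covariance
  expect_lt(max(abs(estimate_covariance(ds$data)$sigma - pop$sigma)), 0.06)
  # the variance-matched tau makes the constraint vacuous: independence
  loose <- gen_synergistic(500, 3, tau = sqrt(3), seed = 7)
  expect_equal(loose$truth$sigma_pop, diag(3), tolerance = 1e-12)
  expect_equal(constraint_tau_for_correlation(3, 0), sqrt(3),
               tolerance = 1e-12)
  # zero-weight variables stay untouched background
  w <- c(1, 1, 0, 0)
  pl <- gen_synergistic(200, 4, weights = w, tau = 0.2, seed = 8)
  expect_identical(pl$truth$constrained, c(1L, 2L))
  expect_equal(pl$truth$sigma_pop[3:4, 3:4], diag(2))
})

test_that("cluster mixtures expose the sampling-strategy effect on interaction sign", {
  one <- gen_cluster_mixture(4, K = 1, mode = "pooled", n = 100,
                             within_sd = 1, center_structure = "independent",
                             seed = 9)
  expect_equal(nrow(one$data$values), 100L)
  expect_equal(length(unique(one$truth$assignments)), 1L)
  uq <- gen_cluster_mixture(6, K = 40, mode = "unique", seed = 10)
  expect_equal(nrow(uq$data$values), 40L)
  ov <- gen_cluster_mixture(6, K = 40, mode = "oversampled", n_per = 20,
                            n_clusters_used = 2, seed = 10)
  expect_equal(nrow(ov$data$values), 40L)
  expect_equal(length(unique(ov$truth$assignments)), 2L)
  sc <- scan_config(3:6, seed = 1)
  expect_lt(mean(curve_statistic(scan(uq$data, sc), "mean")), 0)
  expect_gt(mean(curve_statistic(scan(ov$data, sc), "mean")), 0)
  # two nearly coincident structured clusters do not flip a synergy-rich pool
  near <- gen_cluster_mixture(6, K = 2, mode = "oversampled", n_per = 200,
                              n_clusters_used = 2,
                              center_structure = "independent",
                              center_sd = 0.02, within_sd = 1,
                              within_structure = "constraint",
                              within_tau = 0.3, seed = 11)
  expect_lt(mean(curve_statistic(scan(near$data, sc), "mean")), 0)
})

test_that("feature maps expose their generating structure to RSI analysis", {
  ds <- gen_independent(2000, 8, seed = 12)
  rmp <- gen_feature_map(ds$data, "weighted_sum", vars = c("V1", "V2"),
                         weights = c(1, 0.8), noise_sd = 0.1, seed = 13)
  cv <- scan(bind_feature(ds$data, rmp$feature, "RMP"),
             scan_config(1:8, seed = 1, measure = "rsi", target = "RMP"))
  ms <- minimal_synergistic_set(cv)
  expect_equal(ms$order, 2L)
  expect_setequal(ms$tuple, c("V1", "V2"))
  # a broad multiplicative mix keeps gaining synergy beyond order 2
  isi <- gen_feature_map(ds$data, "pairwise_products",
                         vars = paste0("V", 1:6), noise_sd = 0.5, seed = 14)
  cv2 <- scan(bind_feature(ds$data, isi$feature, "ISI"),
              scan_config(1:8, seed = 1, measure = "rsi", target = "ISI"))
  expect_gt(minimal_synergistic_set(cv2)$order, 2L)
  # a noiseless copy of a single variable is a singular pair for the
  # Gaussian formula and errors rather than returning infinity
  copy <- gen_feature_map(ds$data, "weighted_sum", vars = "V1", weights = 1,
                          noise_sd = 0, seed = 15)
  dat <- bind_feature(ds$data, copy$feature, "Y")
  expect_error(rsi(estimate_covariance(dat), "V1", "Y"), "singular")
})

test_that("the count generator plants an informative panel in zero-inflated counts", {
  ds <- gen_counts(n_cells = 120, n_genes = 200, n_subtypes = 2,
                   panel_size = 30, seed = 16)
  expect_true(all(ds$data$values >= 0))
  expect_true(all(ds$data$values == round(ds$data$values)))
  expect_gt(mean(ds$data$values == 0), 0.2)  # zero inflation visible
  expect_identical(ds$truth$panel, paste0("gene", 1:30))
  # full dropout degenerates the whole matrix
  dead <- gen_counts(n_cells = 30, n_genes = 20, zero_inflation = 1,
                     panel_size = 5, seed = 17)
  expect_true(all(dead$data$values == 0))
  expect_error(suppressWarnings(preprocess(dead$data)), "no genes left")
  # a latent factor on the panel induces positive O-info among panel genes
  lf <- gen_counts(n_cells = 400, n_genes = 60, n_subtypes = 1,
                   panel_size = 12, shift_sd = 0, latent_factor = TRUE,
                   factor_loading = 0.6, seed = 18)
  pp <- suppressWarnings(preprocess(lf$data))
  panel_present <- intersect(lf$truth$panel, pp$gene_names)
  cm <- estimate_covariance(data_matrix(pp$values[, panel_present]))
  expect_gt(as.double(o_info(cm, panel_present[1:5])), 0)
})
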