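test_that("covariance estimation is unbiased, ridge-aware, and guards degenerate input", {
  ds <- gen_independent(1e5, 5, seed = 42)
  cm <- estimate_covariance(ds$data)
  expect_lt(max(abs(cm$sigma - diag(5))), 0.02)
  expect_identical(cm$n_samples, 100000L)

  # ridge adds exactly ridge * trace/p to the diagonal, nothing off-diagonal
  small <- gen_redundant(50, 4, seed = 1)$data
  c0 <- estimate_covariance(small, ridge = 0)
  c1 <- estimate_covariance(small, ridge = 1e-9)
  added <- 1e-9 * sum(diag(c0$sigma)) / 4
  expect_equal(c1$sigma, c0$sigma + diag(added, 4), tolerance = 1e-12)

  x <- matrix(rnorm(20), 10, 2, dimnames = list(NULL, c("a", "b")))
  x[, 2] <- 5
  expect_error(estimate_covariance(data_matrix(x)), "zero-variance.*b")
  expect_error(estimate_covariance(data_matrix(matrix(rnorm(4), 2, 2))),
               "at least 3 samples")

  # perfectly duplicated columns: covariance builds, determinant ops error
  y <- matrix(rnorm(30), 30, 1)
  dup <- data_matrix(cbind(a = y[, 1], b = y[, 1], c = rnorm(30)))
  cm2 <- estimate_covariance(dup)
  expect_equal(stats::cov2cor(cm2$sigma)["a", "b"], 1)
  expect_error(total_correlation(cm2), "singular")
})

test_that("Gaussian entropy matches the closed form", {
  cm <- covariance_model(diag(c(1, 1, 4)), c("a", "b", "c"))
  h1 <- 0.5 * log(2 * pi * exp(1))
  expect_equal(gaussian_entropy(cm, "a"), h1, tolerance = 1e-12)
  expect_equal(gaussian_entropy(cm, c("a", "b")), 2 * h1, tolerance = 1e-12)
  expect_equal(gaussian_entropy(cm, "c"), h1 + 0.5 * log(4), tolerance = 1e-12)
})

test_that("Gaussian MI matches the correlation closed form and the entropy identity", {
  for (rho in c(0, 0.3, 0.5, -0.8)) {
    s <- matrix(c(2, rho * sqrt(2 * 3), rho * sqrt(2 * 3), 3), 2, 2)
    cm <- covariance_model(s, c("a", "b"))
    expect_equal(gaussian_mi(cm, "a", "b"), -0.5 * log(1 - rho^2),
                 tolerance = 1e-12)
    expect_equal(gaussian_mi(cm, "a", "b"),
                 gaussian_entropy(cm, "a") + gaussian_entropy(cm, "b") -
                   gaussian_entropy(cm, c("a", "b")),
                 tolerance = 1e-12)
  }
  expect_error(gaussian_mi(covariance_model(matrix(c(1, 1, 1, 1), 2, 2) +
                                              diag(1e-16, 2)), 1, 2),
               "singular")
})

test_that("TC and DTC are nonnegative, vanish under independence, and differ by O-info", {
  ind <- covariance_model(diag(c(1, 2, 3)))
  expect_equal(total_correlation(ind), 0, tolerance = 1e-12)
  expect_equal(dual_total_correlation(ind), 0, tolerance = 1e-12)

  s <- diag(4); s[1, 2] <- s[2, 1] <- 0.99
  cm <- covariance_model(s)
  expect_equal(total_correlation(cm), -0.5 * log(1 - 0.99^2),
               tolerance = 1e-10)

  withr::with_seed(7, {
    for (i in 1:50) {
      p <- sample(3:7, 1)
      cm <- covariance_model(random_pd_sigma(p))
      expect_equal(as.double(o_info(cm)),
                   total_correlation(cm) - dual_total_correlation(cm),
                   tolerance = 1e-9)
      expect_gte(total_correlation(cm), -1e-10)
      expect_gte(dual_total_correlation(cm), -1e-10)
    }
  })
})

test_that("O-info reproduces hand-evaluated cases and sign conventions", {
  # X3 = X1 + X2 + noise: synergy
  sg <- matrix(c(1, 0, 1, 0, 1, 1, 1, 1, 3), 3, 3)
  expect_equal(as.double(o_info(covariance_model(sg))), 0.5 * log(3 / 4),
               tolerance = 1e-12)
  # common latent factor: redundancy
  cf <- matrix(1, 3, 3); diag(cf) <- 2
  expect_equal(as.double(o_info(covariance_model(cf))), 0.5 * log(32 / 27),
               tolerance = 1e-12)
  # exchangeable triples
  for (rho in c(0.45, -0.45)) {
    s <- matrix(rho, 3, 3); diag(s) <- 1
    expect_equal(as.double(o_info(covariance_model(s))), oinfo_equicorr(rho),
                 tolerance = 1e-12)
  }
  expect_equal(oinfo_equicorr(0.45), 0.0625, tolerance = 1e-4)
  expect_equal(oinfo_equicorr(-0.45), -0.4403, tolerance = 1e-4)
  # independence
  expect_equal(as.double(o_info(covariance_model(diag(c(1, 2, 3, 4))))), 0,
               tolerance = 1e-10)
  expect_error(o_info(covariance_model(diag(3)), 1:2), "at least 3")
})

test_that("O-info is invariant to variable order, rescaling, and adds over independent blocks", {
  withr::with_seed(11, {
    s <- random_pd_sigma(5)
    cm <- covariance_model(s, letters[1:5])
    v0 <- as.double(o_info(cm))
    expect_equal(as.double(o_info(cm, c("d", "a", "e", "c", "b"))), v0,
                 tolerance = 1e-9)
    d <- diag(c(2, 0.1, 7, 0.5, 3))
    expect_equal(as.double(o_info(covariance_model(d %*% s %*% d, letters[1:5]))),
                 v0, tolerance = 1e-9)
    # block-diagonal additivity
    s2 <- random_pd_sigma(4)
    blk <- matrix(0, 9, 9)
    blk[1:5, 1:5] <- s; blk[6:9, 6:9] <- s2
    expect_equal(as.double(o_info(covariance_model(blk))),
                 v0 + as.double(o_info(covariance_model(s2))),
                 tolerance = 1e-9)
  })
})

test_that("conditional covariance and variance follow the Schur complement", {
  s <- diag(3); s[1, 3] <- s[3, 1] <- 0.5
  cm <- covariance_model(s, c("x", "z", "y"))
  # z independent of y: conditioning leaves it untouched
  cc <- conditional_covariance(cm, c("x", "z"), "y")
  expect_equal(cc$sigma["z", "z"], 1, tolerance = 1e-12)
  expect_equal(cc$sigma["x", "x"], 0.75, tolerance = 1e-12)
  expect_equal(conditional_variance(cm, "x", "y"), 0.75, tolerance = 1e-12)
  withr::with_seed(3, {
    for (i in 1:20) {
      cmr <- covariance_model(random_pd_sigma(4))
      expect_lte(conditional_variance(cmr, 1, 4), cmr$sigma[1, 1] + 1e-12)
    }
  })
  expect_error(conditional_covariance(cm, c("x", "y"), "y"), "not be part")
})

test_that("RSI reproduces the additive-target closed form and both sign conventions", {
  sg <- diag(3); sg[1, 3] <- sg[3, 1] <- 1; sg[2, 3] <- sg[3, 2] <- 1
  sg[3, 3] <- 3
  cm <- covariance_model(sg, c("x1", "x2", "y"))
  expect_equal(as.double(rsi(cm, c("x1", "x2"), "y", "printed")),
               log(2) - 0.5 * log(3), tolerance = 1e-12)
  expect_equal(as.double(rsi(cm, c("x1", "x2"), "y", "results")),
               -(log(2) - 0.5 * log(3)), tolerance = 1e-12)
  # single predictor: exactly zero under both conventions
  expect_equal(as.double(rsi(cm, "x1", "y", "printed")), 0, tolerance = 1e-12)
  expect_equal(as.double(rsi(cm, "x1", "y", "results")), 0, tolerance = 1e-12)
  # near-duplicate informative predictors: redundancy
  s <- matrix(c(1, 0.95, 0.6, 0.95, 1, 0.6, 0.6, 0.6, 1), 3, 3)
  cmr <- covariance_model(s, c("x1", "x2", "y"))
  expect_lt(as.double(rsi(cmr, c("x1", "x2"), "y", "printed")), 0)
  expect_gt(as.double(rsi(cmr, c("x1", "x2"), "y", "results")), 0)
  # conventions are exact negations on random instances
  withr::with_seed(5, {
    for (i in 1:20) {
      cmx <- covariance_model(random_pd_sigma(5))
      expect_identical(as.double(rsi(cmx, 1:3, 5, "printed")),
                       -as.double(rsi(cmx, 1:3, 5, "results")))
    }
  })
  expect_error(rsi(cm, c("x1", "y"), "y"), "target")
})

test_that("closed-form measures agree with plug-in estimates from large samples", {
  withr::with_seed(21, {
    sigma <- random_pd_sigma(4)
  })
  pop <- as.double(o_info(covariance_model(sigma)))
  expect_equal(oinfo_mc(sigma, n = 1e5, seed = 9), pop, tolerance = 0.02)
})
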