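test_that("scans enumerate exhaustively within budget and sample beyond it", {
  ds <- gen_independent(200, 4, seed = 1)
  cv <- scan(ds$data, scan_config(3, budget = 10, seed = 1))
  expect_equal(cv$summary$n_evaluated, 4L)  # C(4,3)
  expect_true(cv$summary$exhaustive)

  ds8 <- gen_independent(200, 8, seed = 2)
  samp <- scan(ds8$data, scan_config(4, budget = 20, seed = 2))
  expect_equal(samp$summary$n_evaluated, 20L)
  expect_false(samp$summary$exhaustive)
  tup <- samp$per_order[[1]]$tuples
  expect_equal(anyDuplicated(apply(tup, 2, paste, collapse = ",")), 0L)

  # sampled and exhaustive paths agree where the budget covers everything
  ex <- scan(ds8$data, scan_config(4, budget = 100, seed = 9))
  expect_equal(sort(ex$per_order[[1]]$values),
               sort(scan(ds8$data, scan_config(4, budget = 100, seed = 5))$
                      per_order[[1]]$values))

  # seeded reruns are bit-identical even on the sampling path
  samp2 <- scan(ds8$data, scan_config(4, budget = 20, seed = 2))
  expect_identical(samp$per_order, samp2$per_order)
})

test_that("singular tuples are skipped and tallied rather than failing the scan", {
  withr::with_seed(3, {
    y <- rnorm(100)
    x <- cbind(a = y, b = y, c = rnorm(100), d = rnorm(100))
  })
  cm <- covariance_model(cov(x))
  cv <- scan(cm, scan_config(3, seed = 1))
  expect_equal(cv$summary$n_skipped, 2L)    # the two triples containing {a,b}
  expect_equal(cv$summary$n_evaluated, 2L)
})

test_that("RSI scans exclude the target from tuples", {
  ds <- gen_independent(300, 5, seed = 4)
  fm <- gen_feature_map(ds$data, "weighted_sum", vars = c("V1", "V2"), seed = 5)
  dat <- bind_feature(ds$data, fm$feature, "y")
  cv <- scan(dat, scan_config(1:3, seed = 1, measure = "rsi", target = "y"))
  for (po in cv$per_order)
    expect_false(6L %in% po$tuples)  # "y" is column 6
  # order-1 RSI is identically zero
  expect_equal(cv$summary$max[1], 0, tolerance = 1e-12)
  expect_equal(cv$summary$min[1], 0, tolerance = 1e-12)
})

test_that("frequency maps normalize by selected tuples and rank planted variables", {
  ds <- gen_independent(200, 5, seed = 6)
  cv <- scan(ds$data, scan_config(3:4, seed = 1))
  # fraction small enough that exactly one tuple is selected per order
  fm <- top_fraction_frequency(cv, fraction = 1e-6)
  expect_true(all(fm %in% c(0, 1)))
  expect_equal(colSums(fm), c("3" = 3, "4" = 4))
  # full fraction: column sums equal the order
  fm_all <- top_fraction_frequency(cv, fraction = 1)
  expect_equal(colSums(fm_all), c("3" = 3, "4" = 4), tolerance = 1e-12)
  expect_error(top_fraction_frequency(cv, fraction = 0), "fraction")

  # a constrained trio planted among independents dominates the synergy side
  w <- c(1, 1, 1, 0, 0, 0, 0, 0)
  dsp <- gen_synergistic(1500, 8, weights = w, tau = 0.3, seed = 7)
  cvp <- scan(dsp$data, scan_config(3:6, seed = 7))
  fr <- top_fraction_frequency(cvp, fraction = 0.05, side = "min")
  mean_freq <- rowMeans(fr)
  expect_setequal(names(sort(mean_freq, decreasing = TRUE))[1:3],
                  c("V1", "V2", "V3"))

  # redundancy side selects the latent-factor block
  L <- matrix(0, 8, 1); L[1:3, 1] <- 1.5
  dsr <- gen_redundant(1500, 8, loadings = L, seed = 8)
  cvr <- scan(dsr$data, scan_config(3:6, seed = 8))
  fr2 <- top_fraction_frequency(cvr, fraction = 0.05, side = "max")
  expect_setequal(names(sort(rowMeans(fr2), decreasing = TRUE))[1:3],
                  c("V1", "V2", "V3"))
})

test_that("minimal synergistic sets implement the plateau criterion", {
  ds <- gen_independent(2000, 6, seed = 9)
  fm <- gen_feature_map(ds$data, "weighted_sum", vars = c("V1", "V2"),
                        noise_sd = 0.1, seed = 10)
  dat <- bind_feature(ds$data, fm$feature, "y")
  cv <- scan(dat, scan_config(1:6, seed = 1, measure = "rsi", target = "y"))
  ms <- minimal_synergistic_set(cv)
  expect_equal(ms$order, 2L)
  expect_setequal(ms$tuple, c("V1", "V2"))
  # infinite tolerance: the smallest scanned order wins
  expect_equal(minimal_synergistic_set(cv, tolerance = Inf)$order, 1L)
  # strictly decreasing curve with no plateau: the largest order wins
  fake <- cv
  fake$summary$min <- -(1:6)
  expect_equal(minimal_synergistic_set(fake)$order, 6L)
})

test_that("stabilization detection follows the argmin second-difference rule", {
  # worked decay-to-plateau series: second differences 1.5, 1.0, 0.5, 0
  expect_identical(detect_stabilization(c(0, -3, -4.5, -5, -5, -5)), 5L)
  # zero curvature everywhere: tie broken at the first interior position
  expect_identical(detect_stabilization(c(1, 2, 3, 4, 5)), 2L)
  # extending the plateau leaves the minimum value (0) and convention intact
  expect_identical(detect_stabilization(c(0, -3, -4.5, -5, -5, -5, -5, -5)), 5L)
  # the alternative knee detector picks the largest curvature magnitude
  expect_identical(detect_stabilization(c(0, -3, -4.5, -5, -5, -5),
                                        method = "max_abs_d2"), 2L)
  expect_error(detect_stabilization(c(1, 2)), "length >= 3")
})
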