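test_that("expression preprocessing standardizes genes once and only once", {
  ds <- gen_counts(n_cells = 80, n_genes = 60, n_subtypes = 2,
                   panel_size = 20, seed = 1)
  em <- ds$data
  expect_identical(em$processing_state, "raw")
  pp <- suppressWarnings(preprocess(em))
  expect_identical(pp$processing_state, "standardized")
  expect_identical(pp$processing_log, c("log1p", "gene_zscore"))
  expect_lt(max(abs(colMeans(pp$values))), 1e-10)
  expect_equal(unname(apply(pp$values, 2, sd)), rep(1, ncol(pp$values)),
               tolerance = 1e-10)
  expect_error(preprocess(pp), "raw")
  # an all-zero gene is dropped with a warning
  x <- em$values; x[, 1] <- 0
  em0 <- expression_matrix(x, cell_labels = em$cell_labels)
  expect_warning(pp0 <- preprocess(em0), "zero-variance")
  expect_false("gene1" %in% pp0$gene_names)
  expect_error(expression_matrix(matrix(-1, 4, 4)), "nonnegative")
})

test_that("nonzero-median filtering keeps genes expressed in most cells of every group", {
  counts <- cbind(
    both = c(rep(2, 8), rep(3, 8)),          # expressed everywhere
    one_sided = c(rep(5, 8), rep(0, 8)),     # median 0 in group b
    mostly_zero = c(rep(0, 5), rep(1, 3), rep(2, 8)))  # median 0 in group a
  em <- expression_matrix(counts, cell_labels = rep(c("a", "b"), each = 8))
  panel <- filter_nonzero_median(em, c("a", "b"))
  expect_identical(panel$genes, "both")
  expect_identical(panel$source, "filtered")
  expect_error(filter_nonzero_median(em, c("a", "zz")), "unknown group")
})

test_that("DEG identification ranks planted subtype-shifted genes first", {
  ds <- gen_counts(n_cells = 150, n_genes = 300, n_subtypes = 3,
                   panel_size = 25, shift_sd = 1.5, seed = 2)
  tab <- identify_degs(ds$data)
  top <- tab$gene[seq_len(25)]
  expect_gte(length(intersect(top, ds$truth$panel)), 20L)
  # identical expression across classes: nothing significant
  perm_lab <- withr::with_seed(3, sample(rep(c("a", "b"), 75)))
  perm_tab <- identify_degs(expression_matrix(ds$data$values,
                                              cell_labels = perm_lab))
  expect_lt(sum(perm_tab$significant), 0.1 * nrow(perm_tab))
  # undersized classes are skipped with a warning
  lab <- ds$data$cell_labels
  lab[1:2] <- "rare"; lab[lab == "type1"] <- "type1"
  expect_warning(identify_degs(expression_matrix(ds$data$values,
                                                 cell_labels = lab)),
                 "fewer than 3")
})

test_that("panel-based clustering separates planted subtypes and not noise", {
  ds <- gen_counts(n_cells = 200, n_genes = 600, n_subtypes = 2,
                   panel_size = 60, seed = 4)
  em <- suppressWarnings(preprocess(ds$data))
  lab <- cluster_cells(em, ds$truth$panel, seed = 1)
  expect_gte(adjusted_rand_index(lab, ds$truth$labels), 0.9)
  noise_aris <- vapply(1:5, function(s) {
    panel <- withr::with_seed(s, sample(setdiff(em$gene_names,
                                                ds$truth$panel), 60))
    adjusted_rand_index(cluster_cells(em, panel, seed = s), ds$truth$labels)
  }, numeric(1))
  expect_true(all(abs(noise_aris) < 0.1))
  expect_error(cluster_cells(em, "gene1"), "at least 2")
  expect_error(cluster_cells(em, c("nope1", "nope2")), "absent")
})

test_that("adjusted Rand index matches the brute-force pair-counting oracle", {
  expect_equal(adjusted_rand_index(c(1, 1, 2, 2), c("x", "x", "y", "y")), 1)
  expect_equal(adjusted_rand_index(1:6, rep(1, 6)), 0)
  expect_equal(adjusted_rand_index(rep(1, 5), rep("z", 5)), 1)
  a <- c(1, 1, 1, 2, 2, 2); b <- c(1, 1, 2, 2, 3, 3)
  expect_equal(adjusted_rand_index(a, b), ari_pair_oracle(a, b),
               tolerance = 1e-12)
  withr::with_seed(6, {
    for (i in 1:20) {
      x <- sample(1:4, 12, replace = TRUE)
      y <- sample(1:3, 12, replace = TRUE)
      expect_equal(adjusted_rand_index(x, y), ari_pair_oracle(x, y),
                   tolerance = 1e-12)
      expect_equal(adjusted_rand_index(x, y), adjusted_rand_index(y, x))
    }
  })
  expect_error(adjusted_rand_index(1:3, 1:4), "equal length")
})

test_that("the ARI null is seeded, guarded, and pool-aware", {
  ds <- gen_counts(n_cells = 150, n_genes = 300, n_subtypes = 3,
                   panel_size = 40, seed = 7)
  em <- suppressWarnings(preprocess(ds$data))
  an <- ari_null(em, focal_panel = ds$truth$panel, panel_size = 40,
                 n_draws = 15, seed = 9)
  an2 <- ari_null(em, focal_panel = ds$truth$panel, panel_size = 40,
                  n_draws = 15, seed = 9)
  expect_identical(an$null_aris, an2$null_aris)
  expect_gte(an$percentile, 95)
  expect_gt(an$focal_ari, mean(an$null_aris) * 3)
  expect_error(ari_null(em, focal_panel = ds$truth$panel, panel_size = 40,
                        n_draws = 5, pool = em$gene_names[1:10]),
               "pool smaller")
  small <- gen_counts(n_cells = 60, n_genes = 100, panel_size = 20, seed = 8)
  em_small <- suppressWarnings(preprocess(small$data))
  expect_error(ari_null(em_small, focal_panel = small$truth$panel,
                        panel_size = 20, n_draws = 5), "excluded")
})
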