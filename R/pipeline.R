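#' End-to-end pipeline recipes
#'
#' Orchestrates the figure-level workflows (simulate data, scan tuples, map
#' pairwise MI, select subsets, run the ARI null) behind a single
#' declarative configuration, writing deterministic JSON/TSV/CSV artifacts
#' plus the resolved configuration next to every output.
#'
#' @name pipeline
NULL

pkg_version_string <- function() {
  paste0("hoinfo ", as.character(utils::packageVersion("hoinfo")))
}

prepare_outdir <- function(config) {
  out <- config$output_dir
  if (is.null(out)) stop("config$output_dir is required", call. = FALSE)
  marker <- file.path(out, "resolved_config.json")
  if (file.exists(marker) && !isTRUE(config$overwrite))
    stop("output directory already holds a run (", marker,
         "); set overwrite = TRUE to replace it", call. = FALSE)
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  out
}

write_resolved_config <- function(config, subcommand, outdir) {
  cfg <- config
  cfg$subcommand <- subcommand
  cfg$tool_version <- pkg_version_string()
  write_json_file(cfg, file.path(outdir, "resolved_config.json"))
}

read_input_matrix <- function(config) {
  if (is.null(config$input))
    stop("config$input is required", call. = FALSE)
  read_data_matrix(config$input, labels_path = config$labels)
}

curve_to_json <- function(curve) {
  lapply(seq_len(nrow(curve$summary)), function(i) as.list(curve$summary[i, ]))
}

write_top_tuples <- function(curve, path, side = "min", top_n = 20L) {
  rows <- do.call(rbind, lapply(seq_along(curve$orders), function(i) {
    po <- curve$per_order[[i]]
    if (!length(po$values)) return(NULL)
    ord <- order(po$values, decreasing = (side == "max"))
    ord <- ord[seq_len(min(top_n, length(ord)))]
    data.frame(order = curve$orders[i],
               value_nats = po$values[ord],
               tuple = apply(po$tuples[, ord, drop = FALSE], 2L, function(t_)
                 paste(curve$variable_names[t_], collapse = "|")))
  }))
  utils::write.table(rows, path, sep = "\t", row.names = FALSE, quote = FALSE)
}

run_scan_recipe <- function(config, outdir, measure) {
  data <- read_input_matrix(config)
  orders <- config$orders %||% seq(if (measure == "oinfo") 3L else 1L,
                                   min(10L, ncol(data$values) -
                                         (measure == "rsi")))
  sc <- scan_config(orders, budget = config$budget %||% 20000L,
                    seed = config$seed %||% 1L, measure = measure,
                    target = config$target,
                    convention = config$convention %||% "results")
  curve <- scan(data, sc)
  write_json_file(curve_to_json(curve), file.path(outdir, "curve_summary.json"))
  side <- config$side %||% "min"
  write_top_tuples(curve, file.path(outdir, "top_tuples.tsv"), side = side)
  fm <- top_fraction_frequency(curve, fraction = config$fraction %||% 0.05,
                               side = side)
  write.csv(as.data.frame(unclass(fm)), file.path(outdir, "frequency_map.csv"))
  if (isTRUE(config$bands)) {
    bb <- bootstrap_band(data, sc, n_reps = config$n_reps %||% 50L,
                         sample_size = config$sample_size,
                         statistic = side, seed = config$seed %||% 1L,
                         guard = !isFALSE(config$guard))
    sb <- shuffle_surrogates(data, sc,
                             n_surrogates = config$n_surrogates %||% 100L,
                             seed = config$seed %||% 1L)
    write_json_file(list(bootstrap = bb$band, surrogate = sb$band),
                    file.path(outdir, "bands.json"))
  }
  invisible(curve)
}

run_simulate <- function(config, outdir) {
  gen <- config$generator %||% stop("config$generator is required",
                                    call. = FALSE)
  kind <- gen$kind %||% stop("generator$kind is required", call. = FALSE)
  seed <- config$seed %||% 1L
  ds <- switch(kind,
    independent = gen_independent(gen$n %||% 1000L, gen$p %||% 10L, seed),
    latent_factor = gen_redundant(gen$n %||% 1000L, gen$p %||% 10L,
                                  n_factors = gen$n_factors %||% 1L,
                                  loadings = gen$loadings %||% 1,
                                  noise_sd = gen$noise_sd %||% 1, seed = seed),
    constraint = gen_synergistic(gen$n %||% 1000L, gen$p %||% 10L,
                                 weights = gen$weights %||% rep(1, gen$p %||% 10L),
                                 tau = gen$tau %||% 0.5, seed = seed),
    cluster_mixture = gen_cluster_mixture(gen$p %||% 10L, K = gen$K %||% 72L,
                                          mode = gen$mode %||% "unique",
                                          n = gen$n,
                                          n_per = gen$n_per %||% 36L,
                                          seed = seed),
    counts = gen_counts(n_cells = gen$n_cells %||% 300L,
                        n_genes = gen$n_genes %||% 2000L,
                        panel_size = gen$panel_size %||% 150L, seed = seed),
    stop("unknown generator kind: ", kind, call. = FALSE))
  if (inherits(ds$data, "expression_matrix")) {
    write.csv(as.data.frame(ds$data$values), file.path(outdir, "data.csv"),
              row.names = FALSE)
    utils::write.table(data.frame(label = ds$data$cell_labels),
                       file.path(outdir, "labels.tsv"), sep = "\t",
                       row.names = FALSE, quote = FALSE)
  } else {
    write_data_matrix(ds$data, file.path(outdir, "data.csv"))
    if (!is.null(ds$data$sample_labels))
      utils::write.table(data.frame(label = ds$data$sample_labels),
                         file.path(outdir, "labels.tsv"), sep = "\t",
                         row.names = FALSE, quote = FALSE)
  }
  truth <- ds$truth
  truth$centers <- NULL; truth$shifts <- NULL; truth$sigma_pop <- NULL
  write_json_file(truth, file.path(outdir, "truth.json"))
  invisible(ds)
}

run_mi_map <- function(config, outdir) {
  data <- read_input_matrix(config)
  features <- if (!is.null(config$features))
    read_data_matrix(config$features) else NULL
  mm <- significant_pair_map(data, features,
                             alpha = config$alpha %||% 0.05,
                             mi_threshold = config$mi_threshold %||% 0.1,
                             n_bins = config$n_bins %||% 10L,
                             n_perm = config$n_perm %||% 1000L,
                             seed = config$seed %||% 1L)
  utils::write.table(mi_map_table(mm), file.path(outdir, "mi_map.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  write.csv(as.data.frame(mm$mi), file.path(outdir, "mi_matrix.csv"))
  write_json_file(list(n_significant_pairs = sum(mm$significant, na.rm = TRUE),
                       n_significant_variables = mm$n_significant_variables,
                       alpha = mm$alpha, mi_threshold = mm$mi_threshold),
                  file.path(outdir, "mi_summary.json"))
  invisible(mm)
}

run_subset <- function(config, outdir) {
  data <- read_input_matrix(config)
  sel <- select_high_covariance(data,
                                n_components = config$n_components %||% 5L,
                                n_keep = config$n_keep %||% 1000L)
  write_data_matrix(sel$subset, file.path(outdir, "subset.csv"))
  write_json_file(list(
    indices = sel$indices,
    residual_quantiles = as.list(quantile(sel$residuals)),
    explained_variance = sel$model$cumulative_explained),
    file.path(outdir, "subset_summary.json"))
  invisible(sel)
}

run_ari_null <- function(config, outdir) {
  if (is.null(config$input) || !file.exists(config$input))
    stop("input file not found: ", config$input %||% "<missing>",
         call. = FALSE)
  counts <- as.matrix(read.csv(config$input, check.names = FALSE))
  labels <- read.csv(config$labels, sep = "\t")$label
  em <- preprocess(expression_matrix(counts, cell_labels = as.character(labels)))
  panel <- scan_lines_panel(config$panel)
  an <- ari_null(em, focal_panel = panel,
                 panel_size = config$panel_size %||% length(panel),
                 n_draws = config$n_draws %||% 500L,
                 seed = config$seed %||% 1L,
                 guard = !isFALSE(config$guard))
  utils::write.table(data.frame(draw = seq_along(an$null_aris),
                                ari = an$null_aris),
                     file.path(outdir, "null_aris.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  write_json_file(list(focal_ari = an$focal_ari,
                       null_mean = mean(an$null_aris),
                       percentile = an$percentile),
                  file.path(outdir, "ari_summary.json"))
  invisible(an)
}

scan_lines_panel <- function(path) {
  if (is.null(path) || !file.exists(path))
    stop("panel file not found: ", path %||% "<missing>", call. = FALSE)
  readLines(path, warn = FALSE) |> trimws() |> Filter(f = nzchar, x = _)
}

run_fig_recipe <- function(config, outdir) {
  recipe <- config$recipe %||% "parameter-scan"
  seed <- config$seed %||% 1L
  res <- switch(recipe,
    # synergy-rich ensemble: O-info trajectory + bands
    "parameter-scan" = {
      ds <- gen_synergistic(config$n %||% 2000L, config$p %||% 10L,
                            tau = config$tau %||% 0.5, seed = seed)
      sc <- scan_config(3:(config$p %||% 10L), seed = seed)
      curve <- scan(ds$data, sc)
      bb <- bootstrap_band(ds$data, sc, n_reps = config$n_reps %||% 50L,
                           sample_size = min(1000L, nrow(ds$data$values)),
                           seed = seed)
      sb <- shuffle_surrogates(ds$data, sc,
                               n_surrogates = config$n_surrogates %||% 100L,
                               seed = seed)
      write_json_file(list(curve = curve_to_json(curve), bootstrap = bb$band,
                           surrogate = sb$band),
                      file.path(outdir, "parameter_scan.json"))
      curve
    },
    # 2-variable feature module: RSI scan + minimal set
    "feature-rsi" = {
      ds <- gen_independent(config$n %||% 2000L, config$p %||% 8L, seed)
      fm <- gen_feature_map(ds$data, "weighted_sum", seed = child_seed(seed, 2L))
      dat <- bind_feature(ds$data, fm$feature, "feature")
      sc <- scan_config(1:(config$p %||% 8L), seed = seed, measure = "rsi",
                        target = "feature")
      curve <- scan(dat, sc)
      ms <- minimal_synergistic_set(curve)
      write_json_file(list(curve = curve_to_json(curve),
                           minimal_set = unclass(ms)),
                      file.path(outdir, "feature_rsi.json"))
      curve
    },
    # unique vs oversampled cluster mixtures: AUC contrast
    "sampling-contrast" = {
      p <- config$p %||% 10L
      sc <- scan_config(3:p, seed = seed)
      auc_of <- function(mode, s) {
        ds <- gen_cluster_mixture(p, K = config$K %||% 72L, mode = mode,
                                  n_per = config$n_per %||% 36L, seed = s)
        oinfo_auc(scan(ds$data, sc))
      }
      reps <- config$n_reps %||% 20L
      uniq <- lapply(seq_len(reps), function(r) auc_of("unique",
                                                       child_seed(seed, r)))
      over <- lapply(seq_len(reps), function(r) auc_of("oversampled",
                                                       child_seed(seed, 100L + r)))
      summary <- list(
        unique_synergy = sapply(uniq, `[[`, "synergy_auc"),
        unique_redundancy = sapply(uniq, `[[`, "redundancy_auc"),
        oversampled_synergy = sapply(over, `[[`, "synergy_auc"),
        oversampled_redundancy = sapply(over, `[[`, "redundancy_auc"))
      summary$p_rank_sum <- compare_groups(
        summary$unique_synergy - summary$unique_redundancy,
        summary$oversampled_synergy - summary$oversampled_redundancy)
      write_json_file(summary, file.path(outdir, "sampling_contrast.json"))
      summary
    },
    # high-covariance subset flips synergy to redundancy
    "covariance-subset" = {
      p <- config$p %||% 10L
      n <- config$n %||% 5000L
      ds <- gen_synergistic(n, p, tau = config$tau %||% 0.5, seed = seed)
      sel <- select_high_covariance(ds$data, n_keep = config$n_keep %||% 1000L)
      rnd <- with_seed(child_seed(seed, 9L),
                       sample.int(n, config$n_keep %||% 1000L))
      sc <- scan_config(3:p, seed = seed)
      full <- scan(ds$data, sc)
      sub <- scan(sel$subset, sc)
      rand <- scan(data_matrix(ds$data$values[rnd, , drop = FALSE]), sc)
      write_json_file(list(full = curve_to_json(full),
                           high_covariance = curve_to_json(sub),
                           random_subset = curve_to_json(rand)),
                      file.path(outdir, "covariance_subset.json"))
      list(full = full, high_covariance = sub, random = rand)
    },
    stop("unknown recipe: ", recipe, call. = FALSE))
  invisible(res)
}

#' Run a pipeline subcommand
#'
#' @param subcommand one of `"simulate"`, `"scan-oinfo"`, `"scan-rsi"`,
#'   `"mi-map"`, `"subset"`, `"ari-null"`, `"fig-recipe"`.
#' @param config named list: `output_dir` (required), `seed`, `input`,
#'   `labels`, `overwrite`, plus subcommand-specific settings (`orders`,
#'   `budget`, `target`, `convention`, `alpha`, `mi_threshold`, `n_perm`,
#'   `n_bins`, `n_components`, `n_keep`, `panel`, `panel_size`, `n_draws`,
#'   `generator`, `recipe`, ...). Every run writes `resolved_config.json`
#'   beside its outputs; reruns into a used directory require
#'   `overwrite = TRUE`.
#' @return the main result object of the subcommand, invisibly.
#' @export
run_pipeline <- function(subcommand = c("simulate", "scan-oinfo", "scan-rsi",
                                        "mi-map", "subset", "ari-null",
                                        "fig-recipe"),
                         config = list()) {
  subcommand <- match.arg(subcommand)
  outdir <- prepare_outdir(config)
  res <- switch(subcommand,
    "simulate" = run_simulate(config, outdir),
    "scan-oinfo" = run_scan_recipe(config, outdir, "oinfo"),
    "scan-rsi" = run_scan_recipe(config, outdir, "rsi"),
    "mi-map" = run_mi_map(config, outdir),
    "subset" = run_subset(config, outdir),
    "ari-null" = run_ari_null(config, outdir),
    "fig-recipe" = run_fig_recipe(config, outdir))
  write_resolved_config(config, subcommand, outdir)
  invisible(res)
}
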