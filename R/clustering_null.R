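#' Gene-panel clustering and the random-panel ARI null
#'
#' Does a designated gene panel (e.g. ion-channel genes) recover ground-truth
#' cell types better than random panels of matched size? Cells are clustered
#' from a panel's expression (PCA, kNN graph, Leiden-style modularity
#' communities), agreement with the truth is scored by the adjusted Rand
#' index, and the focal panel's ARI is placed within the null distribution
#' of many random panels clustered identically.
#'
#' @name clustering_null
NULL

#' Cells-by-genes expression matrix
#'
#' @param counts numeric matrix, cells in rows, genes in columns;
#'   nonnegative when `state = "raw"`.
#' @param gene_names unique gene names (default `colnames(counts)`).
#' @param cell_labels optional ground-truth cell-type labels.
#' @param state processing state: `"raw"`, `"log"`, or `"standardized"`.
#' @return object of class `expression_matrix`.
#' @export
expression_matrix <- function(counts, gene_names = NULL, cell_labels = NULL,
                              state = c("raw", "log", "standardized")) {
  state <- match.arg(state)
  if (is.data.frame(counts)) counts <- as.matrix(counts)
  if (!is.matrix(counts) || !is.numeric(counts))
    stop("'counts' must be a numeric matrix", call. = FALSE)
  gene_names <- as.character(gene_names %||% colnames(counts) %||%
                               paste0("gene", seq_len(ncol(counts))))
  if (length(gene_names) != ncol(counts) || anyDuplicated(gene_names))
    stop("'gene_names' must be unique and match the number of columns",
         call. = FALSE)
  if (!all(is.finite(counts)))
    stop("non-finite entries in 'counts'", call. = FALSE)
  if (state == "raw" && any(counts < 0))
    stop("raw counts must be nonnegative", call. = FALSE)
  if (!is.null(cell_labels)) {
    cell_labels <- as.character(cell_labels)
    if (length(cell_labels) != nrow(counts))
      stop("'cell_labels' length must equal the number of cells", call. = FALSE)
  }
  colnames(counts) <- gene_names
  structure(list(values = counts, gene_names = gene_names,
                 cell_labels = cell_labels, processing_state = state,
                 processing_log = character(0)),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("<expression_matrix> %d cells x %d genes [%s]\n",
              nrow(x$values), ncol(x$values), x$processing_state))
  invisible(x)
}

#' Standard expression preprocessing
#'
#' log(1 + x) transform followed by gene-wise z-scoring. Genes with zero
#' variance after the log transform carry no information and are dropped
#' with a warning. Only raw matrices are accepted: re-processing an already
#' transformed matrix is an error, not a silent double transform.
#'
#' @param em a raw [expression_matrix()].
#' @return a standardized `expression_matrix` (processing transitions
#'   recorded in `processing_log`).
#' @export
preprocess <- function(em) {
  stopifnot(inherits(em, "expression_matrix"))
  if (em$processing_state != "raw")
    stop("preprocess() expects a raw matrix; state is '",
         em$processing_state, "'", call. = FALSE)
  x <- log1p(em$values)
  sds <- apply(x, 2L, sd)
  if (any(sds == 0)) {
    warning(sum(sds == 0), " zero-variance gene(s) dropped during ",
            "standardization")
    x <- x[, sds > 0, drop = FALSE]
    sds <- sds[sds > 0]
  }
  if (ncol(x) == 0L)
    stop("no genes left after dropping zero-variance genes", call. = FALSE)
  x <- scale(x)
  out <- expression_matrix(x, gene_names = colnames(x),
                           cell_labels = em$cell_labels,
                           state = "standardized")
  out$processing_log <- c(em$processing_log, "log1p", "gene_zscore")
  out
}

#' Gene panel
#'
#' @param genes character vector of unique gene names.
#' @param source provenance tag: `"ion_channel"`, `"deg"`, `"random"`,
#'   `"filtered"`, or `"custom"`.
#' @param draw_seed seed used to draw a random panel, if applicable.
#' @return object of class `gene_panel`.
#' @export
gene_panel <- function(genes, source = c("custom", "ion_channel", "deg",
                                         "random", "filtered"),
                       draw_seed = NULL) {
  source <- match.arg(source)
  genes <- as.character(genes)
  if (anyDuplicated(genes)) stop("panel genes must be unique", call. = FALSE)
  structure(list(genes = genes, source = source, draw_seed = draw_seed),
            class = "gene_panel")
}

#' @export
print.gene_panel <- function(x, ...) {
  cat(sprintf("<gene_panel> %d genes [%s]\n", length(x$genes), x$source))
  invisible(x)
}

#' Filter genes by nonzero within-group median
#'
#' Keeps genes whose median raw expression is strictly positive in every
#' named group (i.e. expressed in more than half the cells of each group).
#'
#' @param em a raw [expression_matrix()] with cell labels.
#' @param groups character vector of group labels (typically a pair).
#' @return a [gene_panel()] (possibly empty; downstream clustering errors on
#'   panels of fewer than 2 genes).
#' @export
filter_nonzero_median <- function(em, groups) {
  stopifnot(inherits(em, "expression_matrix"))
  if (em$processing_state != "raw")
    stop("median filtering is defined on raw expression", call. = FALSE)
  if (is.null(em$cell_labels)) stop("cell labels required", call. = FALSE)
  unknown <- setdiff(groups, unique(em$cell_labels))
  if (length(unknown))
    stop("unknown group label(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  keep <- rep(TRUE, ncol(em$values))
  for (g in groups) {
    med <- apply(em$values[em$cell_labels == g, , drop = FALSE], 2L, median)
    keep <- keep & (med > 0)
  }
  gene_panel(em$gene_names[keep], source = "filtered")
}

#' Identify differentially expressed genes
#'
#' One-vs-rest Wilcoxon rank-sum test per gene per class, BH-corrected
#' across all tests; genes are ranked by their best adjusted p-value and
#' flagged significant at `alpha`. Classes with fewer than 3 cells are
#' skipped with a warning.
#'
#' @param em an [expression_matrix()] (rank-based, so raw or log input give
#'   identical results).
#' @param labels class labels (default the matrix's `cell_labels`).
#' @param alpha BH FDR level (default 0.05).
#' @return data frame (gene, class, p, q, significant) with one row per
#'   gene (its best class), ordered by q.
#' @export
identify_degs <- function(em, labels = NULL, alpha = 0.05) {
  stopifnot(inherits(em, "expression_matrix"))
  labels <- as.character(labels %||% em$cell_labels)
  if (is.null(labels) || !length(labels))
    stop("class labels required", call. = FALSE)
  classes <- names(which(table(labels) >= 3L))
  skipped <- setdiff(unique(labels), classes)
  if (length(skipped))
    warning("class(es) with fewer than 3 cells skipped: ",
            paste(skipped, collapse = ", "))
  if (length(classes) < 2L)
    stop("need at least 2 classes with >= 3 cells", call. = FALSE)
  x <- em$values
  pmat <- vapply(classes, function(cl) {
    inn <- labels == cl
    vapply(seq_len(ncol(x)), function(j) {
      xi <- x[inn, j]; xo <- x[!inn, j]
      if (length(unique(c(xi, xo))) == 1L) return(1)
      suppressWarnings(wilcox.test(xi, xo, exact = FALSE)$p.value)
    }, numeric(1))
  }, numeric(ncol(x)))
  pmat <- matrix(pmat, ncol = length(classes),
                 dimnames = list(em$gene_names, classes))
  qmat <- matrix(p.adjust(pmat, method = "BH"), nrow = nrow(pmat),
                 dimnames = dimnames(pmat))
  best <- apply(qmat, 1L, which.min)
  out <- data.frame(
    gene = em$gene_names,
    class = classes[best],
    p = pmat[cbind(seq_len(nrow(pmat)), best)],
    q = qmat[cbind(seq_len(nrow(qmat)), best)],
    stringsAsFactors = FALSE)
  out$significant <- out$q <= alpha
  out[order(out$q, out$p), , drop = FALSE]
}

#' Cluster cells from a gene panel
#'
#' PCA on the panel's standardized expression, a k-nearest-neighbor graph in
#' PC space (Euclidean), and Leiden community detection under the modularity
#' objective. Deterministic for a fixed seed.
#'
#' @param em a standardized [expression_matrix()] (see [preprocess()]).
#' @param panel a [gene_panel()] or character vector of >= 2 genes present
#'   in the matrix.
#' @param n_pcs principal components (default 50, capped by the data).
#' @param k neighbors per cell (default 15).
#' @param resolution Leiden resolution (default 1.0).
#' @param seed integer seed.
#' @return integer cluster labels, one per cell.
#' @export
cluster_cells <- function(em, panel, n_pcs = 50L, k = 15L, resolution = 1.0,
                          seed = 1L) {
  stopifnot(inherits(em, "expression_matrix"))
  genes <- if (inherits(panel, "gene_panel")) panel$genes else as.character(panel)
  missing_ <- setdiff(genes, em$gene_names)
  if (length(missing_))
    stop("panel gene(s) absent from the matrix: ",
         paste(utils::head(missing_, 5), collapse = ", "), call. = FALSE)
  if (length(genes) < 2L)
    stop("panel must contain at least 2 genes", call. = FALSE)
  x <- em$values[, genes, drop = FALSE]
  n <- nrow(x)
  n_pcs <- min(as.integer(n_pcs), ncol(x), n - 1L)
  pc <- prcomp(x, center = TRUE, scale. = FALSE, rank. = n_pcs)$x
  k <- min(as.integer(k), n - 1L)
  d <- as.matrix(dist(pc))
  edges <- do.call(rbind, lapply(seq_len(n), function(i) {
    nn <- order(d[i, ])[2:(k + 1L)]
    cbind(i, nn)
  }))
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  g <- igraph::simplify(g)
  memb <- with_seed(seed, {
    igraph::membership(igraph::cluster_leiden(
      g, objective_function = "modularity", resolution = resolution,
      n_iterations = 3L))
  })
  as.integer(memb)
}

#' Adjusted Rand index between two partitions
#'
#' Permutation-model-adjusted Rand index: 1 for identical partitions (up to
#' relabeling), expected 0 for independent ones. The degenerate case where
#' both partitions are a single block is defined as 1 (the formula's 0/0).
#'
#' @param a,b label vectors of equal length.
#' @return scalar ARI.
#' @export
adjusted_rand_index <- function(a, b) {
  if (length(a) != length(b))
    stop("partitions must have equal length", call. = FALSE)
  if (length(unique(a)) == 1L && length(unique(b)) == 1L) return(1)
  mclust::adjustedRandIndex(a, b)
}

#' Random-panel ARI null for a focal gene panel
#'
#' Clusters the cells from the focal panel and from `n_draws` random panels
#' of `panel_size` genes (drawn from the full gene pool or from a supplied
#' pool such as DEGs), scoring each against the ground-truth labels with the
#' adjusted Rand index. The focal panel's percentile within the null
#' distribution quantifies whether it is more informative about cell type
#' than matched random panels. The dataset guard is applied first.
#'
#' @param em a standardized [expression_matrix()] (see [preprocess()]).
#' @param truth ground-truth labels (default the matrix's `cell_labels`).
#' @param focal_panel a [gene_panel()] or character vector.
#' @param panel_size genes per random panel (default 150).
#' @param n_draws random panels (default 500).
#' @param pool `"all"` (default) or a character vector of gene names to draw
#'   from (e.g. DEGs).
#' @param seed integer seed.
#' @param guard apply [dataset_guard()] (default TRUE).
#' @param ... clustering settings passed to [cluster_cells()].
#' @return object of class `ari_null`: `focal_ari`, `null_aris`,
#'   `percentile` (0-100, midrank convention for ties), `n_draws`,
#'   `panel_size`.
#' @export
ari_null <- function(em, truth = NULL, focal_panel, panel_size = 150L,
                     n_draws = 500L, pool = "all", seed = 1L, guard = TRUE,
                     ...) {
  stopifnot(inherits(em, "expression_matrix"))
  truth <- truth %||% em$cell_labels
  if (is.null(truth)) stop("ground-truth labels required", call. = FALSE)
  if (n_draws < 1L) stop("'n_draws' must be >= 1", call. = FALSE)
  if (guard) {
    g <- dataset_guard(list(values = em$values, cell_labels = truth))
    if (!g$pass)
      stop("dataset excluded from resampling: ", g$reason, call. = FALSE)
  }
  pool_genes <- if (identical(pool, "all")) em$gene_names else {
    unknown <- setdiff(pool, em$gene_names)
    if (length(unknown))
      stop("pool gene(s) absent from the matrix: ",
           paste(utils::head(unknown, 5), collapse = ", "), call. = FALSE)
    as.character(pool)
  }
  if (length(pool_genes) < panel_size)
    stop("pool smaller than 'panel_size'", call. = FALSE)
  focal_genes <- if (inherits(focal_panel, "gene_panel")) focal_panel$genes
                 else as.character(focal_panel)
  focal_ari <- adjusted_rand_index(
    cluster_cells(em, focal_genes, seed = child_seed(seed, 0L), ...), truth)
  null_aris <- with_seed(seed, {
    vapply(seq_len(n_draws), function(d) {
      genes <- sample(pool_genes, panel_size)
      adjusted_rand_index(
        cluster_cells(em, genes, seed = child_seed(seed, d), ...), truth)
    }, numeric(1))
  })
  percentile <- 100 * (sum(null_aris < focal_ari) +
                         0.5 * sum(null_aris == focal_ari)) / n_draws
  structure(list(focal_ari = focal_ari, null_aris = null_aris,
                 percentile = percentile, n_draws = as.integer(n_draws),
                 panel_size = as.integer(panel_size), seed = as.integer(seed)),
            class = "ari_null")
}

#' @export
print.ari_null <- function(x, ...) {
  cat(sprintf(
    "<ari_null> focal ARI %.3f vs null mean %.3f (%d draws of %d genes): percentile %.1f\n",
    x$focal_ari, mean(x$null_aris), x$n_draws, x$panel_size, x$percentile))
  invisible(x)
}
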