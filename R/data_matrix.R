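#' Sample-by-variable data matrix
#'
#' The universal numeric input of the package: rows are samples (biophysical
#' model instances, cells), columns are named variables (conductance
#' parameters, genes, electrophysiological features). Validation enforces the
#' contracts every downstream operation relies on: finite entries, at least
#' two samples and two variables, and unique column names.
#'
#' @param values numeric matrix (or data frame) with samples in rows.
#' @param variable_names character vector of unique column names; defaults to
#'   `colnames(values)`.
#' @param variable_annotations optional named character vector mapping
#'   variables to a category (compartment, channel family, ...).
#' @param sample_labels optional character vector of per-sample labels
#'   (cell type, source cell), length `nrow(values)`.
#' @return an object of class `data_matrix` with fields `values`,
#'   `variable_names`, `variable_annotations`, `sample_labels`.
#' @examples
#' dm <- data_matrix(matrix(rnorm(40), 10, 4,
#'                          dimnames = list(NULL, paste0("g", 1:4))))
#' dim(dm$values)
#' @export
data_matrix <- function(values, variable_names = NULL,
                        variable_annotations = NULL, sample_labels = NULL) {
  if (is.data.frame(values)) values <- as.matrix(values)
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix", call. = FALSE)
  variable_names <- variable_names %||% colnames(values) %||%
    paste0("V", seq_len(ncol(values)))
  variable_names <- as.character(variable_names)
  if (length(variable_names) != ncol(values))
    stop("'variable_names' length must match the number of columns",
         call. = FALSE)
  if (anyDuplicated(variable_names))
    stop("variable names must be unique", call. = FALSE)
  if (nrow(values) < 2L || ncol(values) < 2L)
    stop("need at least 2 samples and 2 variables", call. = FALSE)
  if (!all(is.finite(values))) {
    bad <- which(colSums(!is.finite(values)) > 0L)
    stop("non-finite entries in column(s): ",
         paste(variable_names[bad], collapse = ", "), call. = FALSE)
  }
  colnames(values) <- variable_names
  if (!is.null(sample_labels)) {
    sample_labels <- as.character(sample_labels)
    if (length(sample_labels) != nrow(values))
      stop("'sample_labels' length must equal the number of samples",
           call. = FALSE)
  }
  if (!is.null(variable_annotations)) {
    variable_annotations <- as.character(variable_annotations) |>
      setNames(names(variable_annotations))
    unknown <- setdiff(names(variable_annotations), variable_names)
    if (length(unknown))
      stop("annotations refer to unknown variable(s): ",
           paste(unknown, collapse = ", "), call. = FALSE)
  }
  structure(list(values = values, variable_names = variable_names,
                 variable_annotations = variable_annotations,
                 sample_labels = sample_labels),
            class = "data_matrix")
}

#' @export
print.data_matrix <- function(x, ...) {
  cat(sprintf("<data_matrix> %d samples x %d variables\n",
              nrow(x$values), ncol(x$values)))
  cat("  variables:", paste(utils::head(x$variable_names, 8), collapse = ", "),
      if (length(x$variable_names) > 8) "..." else "", "\n")
  if (!is.null(x$sample_labels))
    cat("  labels:", paste(utils::head(unique(x$sample_labels), 8),
                           collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.data_matrix <- function(x) dim(x$values)

#' Read a sample-by-variable matrix from CSV/TSV
#'
#' Expects a header row of variable names and one sample per row. The
#' separator is inferred from the file extension (`.tsv`/`.txt` tab,
#' otherwise comma) unless given.
#'
#' @param path path to the delimited file.
#' @param sep field separator; `NULL` to infer from the extension.
#' @param annotations_path optional two-column TSV (variable, category).
#' @param labels_path optional one-column (or two-column: sample, label) TSV
#'   of per-sample labels in row order.
#' @return a [data_matrix()].
#' @export
read_data_matrix <- function(path, sep = NULL, annotations_path = NULL,
                             labels_path = NULL) {
  if (!file.exists(path)) stop("input file not found: ", path, call. = FALSE)
  sep <- sep %||% if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  df <- read.csv(path, sep = sep, check.names = FALSE)
  ann <- NULL
  if (!is.null(annotations_path)) {
    if (!file.exists(annotations_path))
      stop("annotation file not found: ", annotations_path, call. = FALSE)
    a <- read.csv(annotations_path, sep = "\t", header = TRUE,
                  check.names = FALSE)
    ann <- setNames(as.character(a[[2L]]), as.character(a[[1L]]))
  }
  labs <- NULL
  if (!is.null(labels_path)) {
    if (!file.exists(labels_path))
      stop("labels file not found: ", labels_path, call. = FALSE)
    l <- read.csv(labels_path, sep = "\t", header = TRUE, check.names = FALSE)
    labs <- as.character(l[[ncol(l)]])
  }
  data_matrix(as.matrix(df), variable_annotations = ann, sample_labels = labs)
}

#' Write a data matrix to CSV
#'
#' @param data a [data_matrix()].
#' @param path output path.
#' @export
write_data_matrix <- function(data, path) {
  stopifnot(inherits(data, "data_matrix"))
  write.csv(as.data.frame(data$values), path, row.names = FALSE)
  invisible(path)
}

as_data_matrix <- function(x) {
  if (inherits(x, "data_matrix")) return(x)
  if (inherits(x, "labeled_dataset")) return(x$data)
  data_matrix(x)
}
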