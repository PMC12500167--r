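#' Expression matrix container
#'
#' Cells-by-genes expression values with gene and cell identifiers and a
#' layer tag distinguishing raw counts from log-normalized values. Cells are
#' rows everywhere inside the package; Matrix Market files on disk follow the
#' 10x genes-by-cells convention and are transposed on read/write.
#'
#' @param values Numeric matrix, cells in rows, genes in columns.
#' @param genes Character vector of gene identifiers (one per column).
#' @param cells Character vector of cell identifiers (one per row).
#' @param layer `"counts"` (non-negative integers) or `"lognorm"`.
#' @return An object of class `count_matrix`.
#' @export
count_matrix <- function(values, genes = colnames(values),
                         cells = rownames(values),
                         layer = c("counts", "lognorm")) {
  layer <- match.arg(layer)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(genes)) genes <- sprintf("gene_%d", seq_len(ncol(values)))
  if (is.null(cells)) cells <- sprintf("cell_%d", seq_len(nrow(values)))
  if (length(genes) != ncol(values)) stop("`genes` length must match columns", call. = FALSE)
  if (length(cells) != nrow(values)) stop("`cells` length must match rows", call. = FALSE)
  if (layer == "counts") {
    if (any(values < 0) || any(values != floor(values))) {
      stop("counts layer must hold non-negative integers", call. = FALSE)
    }
  }
  dimnames(values) <- list(cells, genes)
  structure(
    list(values = values, genes = as.character(genes),
         cells = as.character(cells), layer = layer),
    class = "count_matrix"
  )
}

#' @export
print.count_matrix <- function(x, ...) {
  cat("<count_matrix> ", length(x$cells), " cells x ", length(x$genes),
      " genes [", x$layer, "]\n", sep = "")
  invisible(x)
}

#' @export
dim.count_matrix <- function(x) dim(x$values)

#' Labeled expression dataset
#'
#' A [count_matrix()] together with a cell-type label per cell and an
#' optional batch label per cell.
#'
#' @param counts A [count_matrix()] (or a plain matrix, coerced with
#'   `layer = "lognorm"` unless integer counts).
#' @param labels Character/factor vector of cell-type labels, one per cell.
#' @param batch Optional character/factor vector of batch labels.
#' @return An object of class `labeled_dataset`.
#' @export
labeled_dataset <- function(counts, labels, batch = NULL) {
  if (!inherits(counts, "count_matrix")) {
    layer <- if (all(counts >= 0) && all(counts == floor(counts))) "counts" else "lognorm"
    counts <- count_matrix(counts, layer = layer)
  }
  labels <- as.character(labels)
  if (length(labels) != length(counts$cells)) {
    stop("`labels` must align with cells", call. = FALSE)
  }
  if (!is.null(batch)) {
    batch <- as.character(batch)
    if (length(batch) != length(counts$cells)) {
      stop("`batch` must align with cells", call. = FALSE)
    }
  }
  structure(
    list(matrix = counts, labels = labels, batch = batch),
    class = "labeled_dataset"
  )
}

#' @export
print.labeled_dataset <- function(x, ...) {
  cat("<labeled_dataset> ", length(x$matrix$cells), " cells x ",
      length(x$matrix$genes), " genes [", x$matrix$layer, "], ",
      length(unique(x$labels)), " cell types",
      if (!is.null(x$batch)) paste0(", ", length(unique(x$batch)), " batches"),
      "\n", sep = "")
  invisible(x)
}

#' @export
dim.labeled_dataset <- function(x) dim(x$matrix$values)

ds_values <- function(data) {
  if (inherits(data, "labeled_dataset")) return(data$matrix$values)
  if (inherits(data, "count_matrix")) return(data$values)
  as_row_matrix(data, arg = "data")
}

ds_labels <- function(data) {
  if (inherits(data, "labeled_dataset")) return(data$labels)
  stop("expected a labeled_dataset", call. = FALSE)
}

# Row subset that remembers which source rows it came from (leakage audits).
subset_cells <- function(data, idx) {
  stopifnot(inherits(data, "labeled_dataset"))
  src <- attr(data, "source_rows")
  if (is.null(src)) src <- seq_along(data$matrix$cells)
  cm <- count_matrix(data$matrix$values[idx, , drop = FALSE],
                     genes = data$matrix$genes,
                     cells = data$matrix$cells[idx],
                     layer = data$matrix$layer)
  out <- labeled_dataset(cm, data$labels[idx],
                         if (!is.null(data$batch)) data$batch[idx])
  attr(out, "source_rows") <- src[idx]
  out
}

#' Read an expression matrix
#'
#' `format = "mtx"`: `path` is a directory holding `matrix.mtx` (Matrix
#' Market, genes x cells on disk), `genes.tsv` and `barcodes.tsv`; the matrix
#' is transposed to cells x genes internally. `format = "csv"`: `path` is a
#' dense CSV, cells x genes, header row of gene identifiers, first column of
#' cell identifiers.
#'
#' @param path Directory (mtx) or file (csv).
#' @param format `"mtx"` or `"csv"`.
#' @param layer Layer tag for the values.
#' @return A [count_matrix()].
#' @export
read_matrix <- function(path, format = c("mtx", "csv"),
                        layer = c("counts", "lognorm")) {
  format <- match.arg(format)
  layer <- match.arg(layer)
  if (format == "mtx") {
    mtx_file <- file.path(path, "matrix.mtx")
    genes_file <- file.path(path, "genes.tsv")
    cells_file <- file.path(path, "barcodes.tsv")
    for (f in c(mtx_file, genes_file, cells_file)) {
      if (!file.exists(f)) stop("missing file: ", f, call. = FALSE)
    }
    body <- readLines(mtx_file, warn = FALSE)
    body <- body[!startsWith(body, "%") & nzchar(trimws(body))]
    hdr <- suppressWarnings(as.numeric(strsplit(trimws(body[1]), "\\s+")[[1]]))
    if (length(hdr) >= 3 && !anyNA(hdr) && (length(body) - 1L) != hdr[3]) {
      stop("parse error in ", mtx_file, ": header declares ", hdr[3],
           " entries but ", length(body) - 1L, " are present", call. = FALSE)
    }
    m <- tryCatch(
      Matrix::readMM(mtx_file),
      error = function(e) stop("parse error in ", mtx_file, ": ",
                               conditionMessage(e), call. = FALSE)
    )
    genes <- utils::read.delim(genes_file, header = FALSE)[[1]]
    cells <- utils::read.delim(cells_file, header = FALSE)[[1]]
    if (nrow(m) != length(genes)) {
      stop("genes.tsv has ", length(genes), " entries but matrix.mtx declares ",
           nrow(m), " rows", call. = FALSE)
    }
    if (ncol(m) != length(cells)) {
      stop("barcodes.tsv has ", length(cells), " entries but matrix.mtx declares ",
           ncol(m), " columns", call. = FALSE)
    }
    count_matrix(t(as.matrix(m)), genes = genes, cells = cells, layer = layer)
  } else {
    df <- utils::read.csv(path, check.names = FALSE)
    cells <- as.character(df[[1]])
    values <- as.matrix(df[, -1, drop = FALSE])
    count_matrix(values, genes = colnames(df)[-1], cells = cells, layer = layer)
  }
}

#' Write an expression matrix
#'
#' Inverse of [read_matrix()]; the round trip is lossless for values and
#' identifiers.
#'
#' @param data A [count_matrix()] or [labeled_dataset()] (labels are written
#'   to `labels.tsv` in mtx format).
#' @param path Directory (mtx) or file (csv).
#' @param format `"mtx"` or `"csv"`.
#' @return `path`, invisibly.
#' @export
write_matrix <- function(data, path, format = c("mtx", "csv")) {
  format <- match.arg(format)
  labels <- NULL
  batch <- NULL
  if (inherits(data, "labeled_dataset")) {
    labels <- data$labels
    batch <- data$batch
    data <- data$matrix
  }
  stopifnot(inherits(data, "count_matrix"))
  if (format == "mtx") {
    dir.create(path, showWarnings = FALSE, recursive = TRUE)
    Matrix::writeMM(Matrix::Matrix(t(data$values), sparse = TRUE),
                    file.path(path, "matrix.mtx"))
    utils::write.table(data$genes, file.path(path, "genes.tsv"),
                       row.names = FALSE, col.names = FALSE, quote = FALSE)
    utils::write.table(data$cells, file.path(path, "barcodes.tsv"),
                       row.names = FALSE, col.names = FALSE, quote = FALSE)
    if (!is.null(labels)) {
      lab <- data.frame(cell = data$cells, label = labels)
      if (!is.null(batch)) lab$batch <- batch
      utils::write.table(lab, file.path(path, "labels.tsv"), sep = "\t",
                         row.names = FALSE, quote = FALSE)
    }
  } else {
    df <- data.frame(cell = data$cells, data$values, check.names = FALSE)
    colnames(df) <- c("cell", data$genes)
    utils::write.csv(df, path, row.names = FALSE)
  }
  invisible(path)
}

#' Read a labeled dataset from an mtx directory
#'
#' Reads `matrix.mtx` + sidecars plus `labels.tsv` (columns `cell`, `label`,
#' optional `batch`) and checks alignment.
#'
#' @param path Directory.
#' @param layer Layer tag for the values.
#' @return A [labeled_dataset()].
#' @export
read_dataset <- function(path, layer = c("counts", "lognorm")) {
  cm <- read_matrix(path, "mtx", layer = match.arg(layer))
  lf <- file.path(path, "labels.tsv")
  if (!file.exists(lf)) stop("missing file: ", lf, call. = FALSE)
  lab <- utils::read.delim(lf)
  if (!all(c("cell", "label") %in% names(lab))) {
    stop("labels.tsv must have columns `cell` and `label`", call. = FALSE)
  }
  if (nrow(lab) != length(cm$cells) || !all(lab$cell == cm$cells)) {
    stop("labels.tsv is not aligned with barcodes.tsv", call. = FALSE)
  }
  labeled_dataset(cm, lab$label, if ("batch" %in% names(lab)) lab$batch)
}
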