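#' Quality-control filter on counts
#'
#' Single pass in the stated order: genes expressed (nonzero) in fewer than
#' `min_cells` cells are dropped, then cells expressing fewer than
#' `min_genes` of the remaining genes are dropped. No iteration to a fixed
#' point. The numbers removed are attached as attribute `"removed"`.
#'
#' @param data A [count_matrix()] or [labeled_dataset()] with a counts layer.
#' @param min_cells Minimum cells a gene must be expressed in.
#' @param min_genes Minimum genes a cell must express.
#' @return Filtered object of the same class.
#' @export
qc_filter <- function(data, min_cells = 100L, min_genes = 100L) {
  UseMethod("qc_filter")
}

#' @export
qc_filter.count_matrix <- function(data, min_cells = 100L, min_genes = 100L) {
  if (data$layer != "counts") stop("qc_filter expects a counts layer", call. = FALSE)
  expressed <- data$values > 0
  keep_genes <- colSums(expressed) >= min_cells
  if (!any(keep_genes)) stop("qc_filter removed every gene", call. = FALSE)
  expressed <- expressed[, keep_genes, drop = FALSE]
  keep_cells <- rowSums(expressed) >= min_genes
  if (!any(keep_cells)) stop("qc_filter removed every cell", call. = FALSE)
  out <- count_matrix(
    data$values[keep_cells, keep_genes, drop = FALSE],
    genes = data$genes[keep_genes],
    cells = data$cells[keep_cells],
    layer = "counts"
  )
  attr(out, "removed") <- c(genes = sum(!keep_genes), cells = sum(!keep_cells))
  attr(out, "kept_cells") <- which(keep_cells)
  out
}

#' @export
qc_filter.labeled_dataset <- function(data, min_cells = 100L, min_genes = 100L) {
  cm <- qc_filter(data$matrix, min_cells, min_genes)
  idx <- attr(cm, "kept_cells")
  out <- labeled_dataset(cm, data$labels[idx],
                         if (!is.null(data$batch)) data$batch[idx])
  attr(out, "removed") <- attr(cm, "removed")
  attr(out, "source_rows") <- idx
  out
}

#' Drop under-represented cell types
#'
#' Removes every class with fewer than `min_count` cells, along with its
#' cells. Per-class removal counts are attached as attribute `"removed"`.
#'
#' @param data A [labeled_dataset()].
#' @param min_count Minimum class size to keep.
#' @return A filtered [labeled_dataset()].
#' @export
drop_rare_classes <- function(data, min_count = 10L) {
  stopifnot(inherits(data, "labeled_dataset"))
  counts <- table(data$labels)
  drop <- names(counts)[counts < min_count]
  keep <- !(data$labels %in% drop)
  if (!any(keep)) stop("every class was removed", call. = FALSE)
  out <- subset_cells(data, which(keep))
  attr(out, "removed") <- counts[drop]
  out
}

#' Library-size normalization and log transform
#'
#' Size factor of a cell = its library size divided by the median library
#' size; values become `log1p(count / factor)` and the layer tag switches to
#' `"lognorm"`. Cells with zero library size are removed with a warning.
#' Externally computed size factors (for example scran-style deconvolution
#' factors) can be supplied instead.
#'
#' @param data A [count_matrix()] or [labeled_dataset()] with a counts layer.
#' @param size_factors Optional positive numeric vector, one per cell.
#' @return The normalized object with layer `"lognorm"`; size factors are
#'   attached as attribute `"size_factors"`.
#' @export
normalize_log <- function(data, size_factors = NULL) {
  UseMethod("normalize_log")
}

#' @export
normalize_log.count_matrix <- function(data, size_factors = NULL) {
  if (data$layer != "counts") stop("normalize_log expects a counts layer", call. = FALSE)
  lib <- rowSums(data$values)
  keep <- lib > 0
  if (!all(keep)) {
    warning(sum(!keep), " cell(s) with zero library size removed")
    data <- count_matrix(data$values[keep, , drop = FALSE],
                         genes = data$genes, cells = data$cells[keep],
                         layer = "counts")
    lib <- lib[keep]
    if (!is.null(size_factors)) size_factors <- size_factors[keep]
  }
  if (is.null(size_factors)) {
    size_factors <- lib / stats::median(lib)
  }
  if (any(size_factors <= 0)) stop("size factors must be positive", call. = FALSE)
  vals <- log1p(sweep(data$values, 1L, size_factors, "/"))
  out <- count_matrix(vals, genes = data$genes, cells = data$cells,
                      layer = "lognorm")
  attr(out, "size_factors") <- size_factors
  attr(out, "kept_cells") <- which(keep)
  out
}

#' @export
normalize_log.labeled_dataset <- function(data, size_factors = NULL) {
  cm <- normalize_log(data$matrix, size_factors)
  idx <- attr(cm, "kept_cells")
  out <- labeled_dataset(cm, data$labels[idx],
                         if (!is.null(data$batch)) data$batch[idx])
  attr(out, "size_factors") <- attr(cm, "size_factors")
  attr(out, "source_rows") <- idx
  out
}

#' Select highly variable genes
#'
#' Ranks genes by per-gene variance of the log-normalized values (computed on
#' training cells only) and returns the indices of the top `n`, with ties
#' broken deterministically by gene identifier. Apply the same index set to
#' test or synthetic matrices to keep feature spaces aligned.
#'
#' @param train A [count_matrix()] or [labeled_dataset()] with lognorm layer.
#' @param n Number of genes to keep.
#' @return Integer vector of gene column indices (decreasing variance).
#' @export
select_hvg <- function(train, n = 3000L) {
  vals <- if (inherits(train, "labeled_dataset")) train$matrix else train
  if (inherits(vals, "count_matrix")) {
    if (vals$layer != "lognorm") stop("select_hvg expects a lognorm layer", call. = FALSE)
    genes <- vals$genes
    vals <- vals$values
  } else {
    vals <- as_row_matrix(vals, arg = "train")
    genes <- colnames(vals) %||% as.character(seq_len(ncol(vals)))
  }
  if (n >= ncol(vals)) {
    if (n > ncol(vals)) warning("`n` exceeds gene count; returning all genes")
    n <- ncol(vals)
  }
  v <- apply(vals, 2L, stats::var)
  ord <- order(-v, genes)
  ord[seq_len(n)]
}

#' Subset genes of a dataset
#'
#' @param data A [count_matrix()] or [labeled_dataset()].
#' @param genes Integer column indices (for example from [select_hvg()]).
#' @return The object restricted to those genes, order preserved.
#' @export
subset_genes <- function(data, genes) {
  if (inherits(data, "labeled_dataset")) {
    cm <- subset_genes(data$matrix, genes)
    out <- labeled_dataset(cm, data$labels, data$batch)
    attr(out, "source_rows") <- attr(data, "source_rows")
    return(out)
  }
  stopifnot(inherits(data, "count_matrix"))
  count_matrix(data$values[, genes, drop = FALSE],
               genes = data$genes[genes], cells = data$cells,
               layer = data$layer)
}

#' Full preprocessing pipeline
#'
#' Applies, in order: [drop_rare_classes()], [qc_filter()], [normalize_log()]
#' and [select_hvg()] + gene subsetting. Every step is logged with
#' before/after shapes in the attached `"log"` tibble. Deterministic given
#' input and parameters.
#'
#' @param data A [labeled_dataset()] with a counts layer.
#' @param min_class Minimum class size.
#' @param min_cells,min_genes QC thresholds.
#' @param n_hvg Number of highly variable genes to retain.
#' @return A log-normalized, HVG-restricted [labeled_dataset()].
#' @export
preprocess_pipeline <- function(data, min_class = 10L, min_cells = 100L,
                                min_genes = 100L, n_hvg = 3000L) {
  stopifnot(inherits(data, "labeled_dataset"))
  steps <- list()
  note <- function(step, d) {
    steps[[length(steps) + 1L]] <<- tibble::tibble(
      step = step, cells = dim(d)[1], genes = dim(d)[2]
    )
  }
  note("input", data)
  data <- drop_rare_classes(data, min_class); note("drop_rare_classes", data)
  data <- qc_filter(data, min_cells, min_genes); note("qc_filter", data)
  data <- normalize_log(data); note("normalize_log", data)
  hvg <- select_hvg(data, n_hvg)
  data <- subset_genes(data, hvg); note("select_hvg", data)
  attr(data, "log") <- dplyr::bind_rows(steps)
  data
}

`%||%` <- function(a, b) if (is.null(a)) b else a
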