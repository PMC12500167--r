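#' Q3 class-balancing generation plan
#'
#' Computes the third quartile (Q3) of the per-class cell-count distribution
#' (linear-interpolation 0.75-quantile, rounded half-up to an integer) and
#' plans `max(0, Q3 - observed)` synthetic cells per class, so that pooling
#' train and synthetic cells raises every class to at least Q3 without
#' overshooting `max(observed, Q3)`.
#'
#' @param labels Character/factor vector of cell-type labels.
#' @return A tibble of class `generation_plan` with columns `cell_type`,
#'   `observed`, `target`, and the Q3 value as attribute `"q3"`.
#' @examples
#' q3_plan(rep(c("A", "B", "C", "D"), times = c(100, 30, 10, 4)))
#' @export
q3_plan <- function(labels) {
  labels <- as.character(labels)
  if (length(labels) == 0L) stop("`labels` must be non-empty", call. = FALSE)
  counts <- table(labels)
  q3 <- floor(stats::quantile(as.numeric(counts), 0.75, names = FALSE) + 0.5)
  plan <- tibble::tibble(
    cell_type = names(counts),
    observed = as.integer(counts),
    target = pmax(0L, as.integer(q3) - as.integer(counts))
  )
  attr(plan, "q3") <- as.integer(q3)
  class(plan) <- c("generation_plan", class(plan))
  plan
}

#' Fit one flow per cell type needing synthesis
#'
#' Partitions the training data by cell-type label and fits a separate,
#' seeded flow model on each class whose plan target is positive. Classes
#' with a zero target are skipped; classes with fewer than 2 cells are
#' skipped with a warning. Each fit records the source rows it was trained
#' on for leakage audits.
#'
#' @param data A [labeled_dataset()] (lognorm layer expected).
#' @param config A [train_config()]; each class trains with a seed derived
#'   deterministically from `config$seed` and the class's position.
#' @param plan Optional [q3_plan()]; computed from `data` by default.
#' @return Named list of `flow_fit` objects (one per planned class).
#' @export
fit_per_type <- function(data, config = train_config(), plan = NULL) {
  stopifnot(inherits(data, "labeled_dataset"))
  if (is.null(plan)) plan <- q3_plan(data$labels)
  need <- plan$cell_type[plan$target > 0L]
  src <- attr(data, "source_rows") %||% seq_along(data$matrix$cells)
  models <- list()
  for (i in seq_along(need)) {
    lab <- need[i]
    rows <- which(data$labels == lab)
    if (length(rows) < 2L) {
      warning("class `", lab, "` has fewer than 2 cells; skipped")
      next
    }
    cfg <- config
    cfg$seed <- config$seed + i
    fit <- train_flow(data$matrix$values[rows, , drop = FALSE], cfg)
    fit$train_rows <- src[rows]
    fit$cell_type <- lab
    fit$genes <- data$matrix$genes
    models[[lab]] <- fit
  }
  models
}

#' Generate the planned synthetic cells
#'
#' Draws exactly `target` synthetic cells per class from that class's fitted
#' flow, labeled accordingly. Deterministic given `seed`.
#'
#' @param models Named list from [fit_per_type()].
#' @param plan A [q3_plan()].
#' @param seed Integer seed.
#' @param genes Optional gene identifiers for the output matrix.
#' @return A [labeled_dataset()] (lognorm layer) with `sum(plan$target)`
#'   rows; zero-target plans yield an empty dataset.
#' @export
generate_balanced <- function(models, plan, seed = 1L, genes = NULL) {
  stopifnot(inherits(plan, "generation_plan"))
  need <- plan[plan$target > 0L, ]
  missing <- setdiff(need$cell_type, names(models))
  if (length(missing) > 0L) {
    stop("no model for class(es): ", paste(missing, collapse = ", "), call. = FALSE)
  }
  mats <- list()
  labs <- character()
  for (i in seq_len(nrow(need))) {
    lab <- need$cell_type[i]
    m <- sample_flow(models[[lab]], need$target[i], seed = seed + i)
    mats[[length(mats) + 1L]] <- m
    labs <- c(labs, rep(lab, need$target[i]))
  }
  d <- if (length(mats) > 0L) ncol(mats[[1]]) else {
    if (length(models) > 0L) models[[1]]$d else 0L
  }
  vals <- if (length(mats) > 0L) do.call(rbind, mats) else matrix(0, 0L, d)
  if (is.null(genes) && length(models) > 0L) {
    genes <- models[[1]]$genes
  }
  cm <- count_matrix(
    vals,
    genes = genes %||% sprintf("gene_%d", seq_len(ncol(vals))),
    cells = if (nrow(vals) > 0L) sprintf("synth_%05d", seq_len(nrow(vals))) else character(),
    layer = "lognorm"
  )
  labeled_dataset(cm, labs)
}

#' Label-free matched-size generation
#'
#' Draws `n_test` unlabeled synthetic cells from one flow fitted on the full
#' training matrix — the protocol used when benchmarking against a test set
#' of known size without using cell-type labels.
#'
#' @param model A `flow_fit` or [flow_model()].
#' @param n_test Number of synthetic cells (`>= 1`).
#' @param seed Integer seed.
#' @return An `n_test x d` matrix.
#' @export
generate_matched <- function(model, n_test, seed = 1L) {
  n_test <- check_positive_int(n_test, "n_test")
  sample_flow(model, n_test, seed = seed)
}

#' Proportional subsampling of a labeled dataset
#'
#' Subsamples `n` cells preserving the cell-type distribution: each type gets
#' `floor(n * p_type)` cells and the remaining cells are assigned one each to
#' the types with the largest fractional remainders (ties broken by larger
#' class, then label order). Cells are drawn uniformly without replacement
#' within type; no type is oversampled beyond its size.
#'
#' @param data A [labeled_dataset()].
#' @param n Number of cells to keep (`n <=` total cells).
#' @param seed Integer seed.
#' @return A subsampled [labeled_dataset()].
#' @export
proportional_subsample <- function(data, n, seed = 1L) {
  stopifnot(inherits(data, "labeled_dataset"))
  n <- check_positive_int(n, "n")
  total <- length(data$labels)
  if (n > total) stop("`n` exceeds the number of cells", call. = FALSE)
  counts <- table(data$labels)
  p <- as.numeric(counts) / total
  base <- floor(n * p)
  frac <- n * p - base
  r <- n - sum(base)
  if (r > 0L) {
    ord <- order(-frac, -as.numeric(counts), names(counts))
    base[ord[seq_len(r)]] <- base[ord[seq_len(r)]] + 1L
  }
  take <- stats::setNames(as.integer(base), names(counts))
  idx <- withr::with_seed(seed, {
    unlist(lapply(names(counts), function(lab) {
      rows <- which(data$labels == lab)
      sample(rows, take[[lab]])
    }), use.names = FALSE)
  })
  subset_cells(data, sort(idx))
}
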