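#' Project datasets onto the reference's leading principal components
#'
#' Fits PCA (centering, no scaling) on the reference matrix only — keeping
#' the representation independent of any generator under evaluation — and
#' transforms the reference plus every query matrix with that single fit.
#' The number of components is `min(n_components, numerical rank)`; a
#' deficient rank triggers a warning.
#'
#' @param reference Numeric matrix the projection is fitted on (real cells).
#' @param queries List of numeric matrices in the same feature space.
#' @param n_components Target dimensionality (default 50, the PC-50
#'   representation used for discrepancy metrics).
#' @return A list with `reference` (projected scores), `queries` (list of
#'   projected matrices) and `projection` (rotation, centering vector,
#'   explained variance, components kept).
#' @export
pc50_project <- function(reference, queries = list(), n_components = 50L) {
  reference <- as_row_matrix(reference, arg = "reference")
  queries <- lapply(queries, as_row_matrix, arg = "queries")
  for (q in queries) {
    if (ncol(q) != ncol(reference)) {
      stop("query feature space does not match the reference", call. = FALSE)
    }
  }
  pc <- stats::prcomp(reference, center = TRUE, scale. = FALSE)
  tol <- max(dim(reference)) * .Machine$double.eps * pc$sdev[1]
  rank <- sum(pc$sdev > max(tol, 1e-12))
  k <- min(n_components, rank)
  if (k < n_components) {
    warning("reference rank ", rank, " < ", n_components,
            " components; using ", k)
  }
  rot <- pc$rotation[, seq_len(k), drop = FALSE]
  project <- function(m) {
    sweep(m, 2L, pc$center, "-") %*% rot
  }
  list(
    reference = pc$x[, seq_len(k), drop = FALSE],
    queries = lapply(queries, project),
    projection = list(
      rotation = rot, center = pc$center,
      explained_variance = pc$sdev[seq_len(k)]^2, n_components = k
    )
  )
}

#' Stratified k-fold split
#'
#' Seeded label-stratified partition: within every class the shuffled cells
#' are dealt round-robin across folds, so each fold's test set holds about
#' `1/k` of every class, the test sets are disjoint, and their union covers
#' all rows. Classes with fewer than `k` members are flagged with a warning
#' (they cannot appear in every fold).
#'
#' @param labels Label vector.
#' @param k Number of folds (`>= 2`).
#' @param seed Integer seed.
#' @param stratified Set `FALSE` for a plain unstratified split.
#' @return List of `k` fold objects, each with `fold`, `train`, `test` row
#'   indices.
#' @export
stratified_kfold <- function(labels, k = 5L, seed = 1L, stratified = TRUE) {
  labels <- as.character(labels)
  n <- length(labels)
  k <- check_positive_int(k, "k")
  if (k < 2L) stop("`k` must be >= 2", call. = FALSE)
  if (k > n) stop("`k` exceeds the number of rows", call. = FALSE)
  counts <- table(labels)
  if (stratified && any(counts < k)) {
    warning("class(es) smaller than k: ",
            paste(names(counts)[counts < k], collapse = ", "))
  }
  assign_fold <- integer(n)
  withr::with_seed(seed, {
    if (stratified) {
      for (lab in names(counts)) {
        rows <- sample(which(labels == lab))
        assign_fold[rows] <- rep(seq_len(k), length.out = length(rows))
      }
    } else {
      assign_fold <- sample(rep(seq_len(k), length.out = n))
    }
  })
  lapply(seq_len(k), function(i) {
    list(fold = i, train = which(assign_fold != i), test = which(assign_fold == i))
  })
}

#' Random-forest cell-type classification
#'
#' Fits a 100-tree random forest with unlimited depth on the training cells
#' and predicts the test cells' types. Seeded and deterministic.
#'
#' @param train A [labeled_dataset()] covering `>= 2` classes.
#' @param test A [labeled_dataset()] or plain matrix in the same feature
#'   space.
#' @param seed Integer seed.
#' @param num_trees Number of trees.
#' @return Character vector of predicted labels, one per test row.
#' @export
rf_classify <- function(train, test, seed = 1L, num_trees = 100L) {
  x <- ds_values(train)
  y <- factor(ds_labels(train))
  if (nlevels(y) < 2L) stop("training data must cover >= 2 classes", call. = FALSE)
  xt <- ds_values(test)
  if (ncol(xt) != ncol(x)) stop("feature space mismatch", call. = FALSE)
  df <- as.data.frame(x)
  colnames(df) <- paste0("f", seq_len(ncol(df)))
  df$.label <- y
  fit <- ranger::ranger(
    dependent.variable.name = ".label", data = df,
    num.trees = num_trees, seed = seed, num.threads = 1L,
    respect.unordered.factors = TRUE
  )
  dft <- as.data.frame(xt)
  colnames(dft) <- paste0("f", seq_len(ncol(dft)))
  as.character(stats::predict(fit, dft, num.threads = 1L)$predictions)
}

#' Cross-validated generative balancing benchmark
#'
#' Runs the full evaluation protocol on a labeled (log-normalized) dataset:
#' for every stratified fold, flows are fitted per cell type on the training
#' cells only, synthetic cells raise each class to the Q3 target, fidelity
#' metrics (WD/CD/MMD) are computed in the PC space fitted on the fold's real
#' training matrix between both train-vs-test (baseline) and
#' balanced-train-vs-test, and a random forest is trained once on the
#' original cells and once on the pooled (original + synthetic) cells and
#' scored on the untouched test fold. A structural leakage audit asserts that
#' no generator ever saw a test row.
#'
#' @param data A [labeled_dataset()] with lognorm layer.
#' @param config A [train_config()] used for every per-type flow.
#' @param k Number of folds.
#' @param seed Integer seed for the fold split and generation.
#' @param n_components PC dimensionality for the fidelity metrics.
#' @param average Averaging mode for classification scores.
#' @return An object of class `flow_benchmark`: `per_fold` (long tibble of
#'   fold/arm/metric/value), `averages` (mean across folds) and `plans`.
#' @export
run_benchmark <- function(data, config = train_config(), k = 5L, seed = 1L,
                          n_components = 50L, average = "macro") {
  stopifnot(inherits(data, "labeled_dataset"))
  folds <- stratified_kfold(data$labels, k = k, seed = seed)
  rows_list <- list()
  plans <- list()
  for (f in folds) {
    train_ds <- subset_cells(data, f$train)
    test_ds <- subset_cells(data, f$test)
    plan <- q3_plan(train_ds$labels)
    plans[[f$fold]] <- plan
    cfg <- config
    cfg$seed <- config$seed + 997L * f$fold
    models <- fit_per_type(train_ds, cfg, plan)
    # leakage audit: every generator must have trained inside the fold's
    # training rows
    for (m in models) {
      if (!all(m$train_rows %in% f$train)) {
        stop("leakage audit failed: generator saw non-training rows", call. = FALSE)
      }
    }
    synth <- generate_balanced(models, plan, seed = seed + f$fold,
                               genes = train_ds$matrix$genes)
    train_x <- train_ds$matrix$values
    test_x <- test_ds$matrix$values
    pooled_x <- rbind(train_x, synth$matrix$values)
    pooled_labels <- c(train_ds$labels, synth$labels)
    pc <- pc50_project(train_x, list(test_x, pooled_x), n_components)
    test_pc <- pc$queries[[1]]
    pooled_pc <- pc$queries[[2]]
    fid <- function(a, b, arm) {
      rep_ <- evaluate_fidelity(a, b, representation = paste0("pc", ncol(a)))
      tibble::tibble(fold = f$fold, arm = arm, metric = rep_$metric,
                     value = rep_$value)
    }
    cls <- function(y_pred, arm) {
      sc <- classification_scores(test_ds$labels, y_pred, average = average)
      pcr <- per_class_recall(test_ds$labels, y_pred)
      dplyr::bind_rows(
        tibble::tibble(fold = f$fold, arm = arm,
                       metric = c("precision", "recall", "f1", "accuracy"),
                       value = c(sc$precision, sc$recall, sc$f1, sc$accuracy)),
        tibble::tibble(fold = f$fold, arm = arm,
                       metric = paste0("recall_", pcr$cell_type),
                       value = pcr$recall)
      )
    }
    pred_orig <- rf_classify(train_ds, test_ds, seed = seed + f$fold)
    pooled_ds <- labeled_dataset(
      count_matrix(pooled_x, genes = train_ds$matrix$genes, layer = "lognorm"),
      pooled_labels
    )
    pred_pool <- rf_classify(pooled_ds, test_ds, seed = seed + f$fold)
    rows_list[[f$fold]] <- dplyr::bind_rows(
      fid(pc$reference, test_pc, "baseline"),
      fid(pooled_pc, test_pc, "balanced"),
      cls(pred_orig, "original"),
      cls(pred_pool, "pooled")
    )
  }
  per_fold <- dplyr::bind_rows(rows_list)
  averages <- per_fold |>
    dplyr::group_by(.data$arm, .data$metric) |>
    dplyr::summarise(value = mean(.data$value), .groups = "drop")
  structure(
    list(per_fold = per_fold, averages = averages, plans = plans,
         k = length(folds)),
    class = "flow_benchmark"
  )
}

#' @export
print.flow_benchmark <- function(x, ...) {
  cat("<flow_benchmark> ", x$k, "-fold\n", sep = "")
  print(tidyr::pivot_wider(
    dplyr::filter(x$averages,
                  .data$metric %in% c("wd", "cd", "mmd", "precision",
                                      "recall", "f1", "accuracy")),
    names_from = "arm", values_from = "value"
  ))
  invisible(x)
}

#' Tidy a benchmark result
#'
#' @param x A `flow_benchmark`.
#' @param ... Unused.
#' @return The long per-fold tibble.
#' @export
tidy.flow_benchmark <- function(x, ...) x$per_fold

#' Plot fold-averaged benchmark metrics
#'
#' @param object A `flow_benchmark`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.flow_benchmark <- function(object, ...) {
  keep <- c("wd", "cd", "mmd", "precision", "recall", "f1")
  dat <- dplyr::filter(object$averages, .data$metric %in% keep)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$metric, y = .data$value,
                                    fill = .data$arm)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = "fold-averaged value", fill = NULL) +
    ggplot2::theme_minimal()
}

#' Mutually exclusive top differentially expressed genes
#'
#' Filters a precomputed DEG table to adjusted p-value below `p_cutoff` and
#' log2 fold change above `lfc_cutoff`, ranks by decreasing log2FC (ties by
#' smaller adjusted p, then gene identifier), takes the top `top_n` per cell
#' type and finally removes every gene appearing in the top list of two or
#' more types, leaving mutually exclusive candidate markers.
#'
#' @param records Data frame with columns `gene`, `cell_type`, `p_adj`,
#'   `log2fc`.
#' @param top_n Genes per type before the exclusivity filter.
#' @param p_cutoff,lfc_cutoff Significance thresholds.
#' @return Named list mapping cell type to its ordered gene character
#'   vector (possibly empty).
#' @export
unique_top_degs <- function(records, top_n = 20L, p_cutoff = 0.05,
                            lfc_cutoff = 1) {
  stopifnot(is.data.frame(records))
  need <- c("gene", "cell_type", "p_adj", "log2fc")
  if (!all(need %in% names(records))) {
    stop("`records` needs columns: ", paste(need, collapse = ", "), call. = FALSE)
  }
  types <- sort(unique(as.character(records$cell_type)))
  top <- records |>
    dplyr::filter(.data$p_adj < p_cutoff, .data$log2fc > lfc_cutoff) |>
    dplyr::arrange(dplyr::desc(.data$log2fc), .data$p_adj, .data$gene) |>
    dplyr::group_by(.data$cell_type) |>
    dplyr::slice_head(n = top_n) |>
    dplyr::ungroup()
  shared <- top |>
    dplyr::distinct(.data$gene, .data$cell_type) |>
    dplyr::count(.data$gene) |>
    dplyr::filter(.data$n >= 2L) |>
    dplyr::pull(.data$gene)
  out <- stats::setNames(vector("list", length(types)), types)
  for (tp in types) {
    g <- top$gene[top$cell_type == tp]
    out[[tp]] <- g[!(g %in% shared)]
  }
  out
}
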