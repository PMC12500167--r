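#' Correlation discrepancy between two datasets
#'
#' Mean absolute entrywise difference of the Pearson correlation matrices of
#' `A` and `B` (same feature space), diagonal included. Correlations
#' involving zero-variance columns are defined as 0, with a warning.
#'
#' @param A,B Numeric matrices with the same number of columns, `>= 2` rows.
#' @return A single non-negative number; 0 when `A` and `B` have identical
#'   correlation structure.
#' @export
correlation_discrepancy <- function(A, B) {
  A <- as_row_matrix(A, arg = "A"); B <- as_row_matrix(B, arg = "B")
  if (ncol(A) != ncol(B)) stop("`A` and `B` must share columns", call. = FALSE)
  if (nrow(A) < 2L || nrow(B) < 2L) stop("need >= 2 rows in each matrix", call. = FALSE)
  corr0 <- function(m) {
    r <- suppressWarnings(stats::cor(m))
    if (anyNA(r)) {
      warning("zero-variance column(s); their correlations set to 0")
      r[is.na(r)] <- 0
    }
    r
  }
  mean(abs(corr0(A) - corr0(B)))
}

#' Mean per-feature 1-D Wasserstein distance
#'
#' For each feature the Wasserstein-1 distance between the two empirical
#' distributions is computed as the discrete CDF sum
#' `sum_k |F(z_k) - G(z_k)| * (z_{k+1} - z_k)` over the sorted unique pooled
#' values `z_k`; the result is the mean across features.
#'
#' @param A,B Numeric matrices with the same number of columns.
#' @return A single non-negative number.
#' @export
wasserstein_mean <- function(A, B) {
  A <- as_row_matrix(A, arg = "A"); B <- as_row_matrix(B, arg = "B")
  if (ncol(A) != ncol(B)) stop("`A` and `B` must share columns", call. = FALSE)
  if (nrow(A) == 0L || nrow(B) == 0L) stop("empty input", call. = FALSE)
  w1 <- function(a, b) {
    z <- sort(unique(c(a, b)))
    if (length(z) < 2L) return(0)
    zk <- z[-length(z)]
    f <- stats::ecdf(a)(zk)
    g <- stats::ecdf(b)(zk)
    sum(abs(f - g) * diff(z))
  }
  mean(vapply(seq_len(ncol(A)), function(j) w1(A[, j], B[, j]), numeric(1)))
}

#' RBF kernel configuration for MMD
#'
#' @param length_scales Positive length scales `l` of the RBF kernel
#'   `exp(-||x - y||^2 / (2 l^2))`; the MMD is averaged over them.
#' @return An `rbf_config` list.
#' @export
rbf_config <- function(length_scales = c(0.005, 0.01, 0.1, 0.5, 1, 2)) {
  if (any(length_scales <= 0)) stop("length scales must be positive", call. = FALSE)
  structure(list(length_scales = as.numeric(length_scales)),
            class = "rbf_config")
}

#' Maximum mean discrepancy between two samples
#'
#' Biased V-statistic `mean(K_AA) + mean(K_BB) - 2 mean(K_AB)` (diagonal
#' terms included, so identical multisets give exactly 0), averaged over the
#' configured RBF length scales. A linear kernel (`x . y`) is available as an
#' option.
#'
#' @param A,B Numeric matrices with the same number of columns, `>= 1` row.
#' @param config An [rbf_config()].
#' @param kernel `"rbf"` or `"linear"`.
#' @return A single non-negative number.
#' @export
mmd_rbf <- function(A, B, config = rbf_config(), kernel = c("rbf", "linear")) {
  kernel <- match.arg(kernel)
  A <- as_row_matrix(A, arg = "A"); B <- as_row_matrix(B, arg = "B")
  if (ncol(A) != ncol(B)) stop("`A` and `B` must share columns", call. = FALSE)
  if (nrow(A) < 1L || nrow(B) < 1L) stop("need >= 1 row in each matrix", call. = FALSE)
  if (kernel == "linear") {
    gaa <- tcrossprod(A); gbb <- tcrossprod(B); gab <- tcrossprod(A, B)
    return(mean(gaa) + mean(gbb) - 2 * mean(gab))
  }
  stopifnot(inherits(config, "rbf_config"))
  sq_dists <- function(X, Y) {
    xn <- rowSums(X^2); yn <- rowSums(Y^2)
    pmax(outer(xn, yn, "+") - 2 * tcrossprod(X, Y), 0)
  }
  daa <- sq_dists(A, A); dbb <- sq_dists(B, B); dab <- sq_dists(A, B)
  vals <- vapply(config$length_scales, function(l) {
    g <- 1 / (2 * l^2)
    mean(exp(-g * daa)) + mean(exp(-g * dbb)) - 2 * mean(exp(-g * dab))
  }, numeric(1))
  mean(vals)
}

#' Multi-class classification scores
#'
#' Per-class one-vs-rest confusion counts aggregated by macro averaging
#' (micro and weighted selectable): precision `TP/(TP+FP)`, recall
#' `TP/(TP+FN)`, F1 the harmonic mean of the two, and accuracy the overall
#' fraction correct. A class never predicted has precision defined as 0
#' (logged via a message).
#'
#' @param y_true,y_pred Label vectors of equal length.
#' @param average `"macro"`, `"micro"` or `"weighted"`.
#' @return A one-row tibble with `precision`, `recall`, `f1`, `accuracy` and
#'   the averaging mode used.
#' @export
classification_scores <- function(y_true, y_pred,
                                  average = c("macro", "micro", "weighted")) {
  average <- match.arg(average)
  y_true <- as.character(y_true); y_pred <- as.character(y_pred)
  if (length(y_true) != length(y_pred)) {
    stop("`y_true` and `y_pred` must have equal length", call. = FALSE)
  }
  classes <- sort(union(y_true, y_pred))
  per <- lapply(classes, function(cl) {
    tp <- sum(y_true == cl & y_pred == cl)
    fp <- sum(y_true != cl & y_pred == cl)
    fn <- sum(y_true == cl & y_pred != cl)
    if (tp + fp == 0L) message("class `", cl, "` never predicted; precision set to 0")
    prec <- if (tp + fp > 0L) tp / (tp + fp) else 0
    rec <- if (tp + fn > 0L) tp / (tp + fn) else 0
    f1 <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
    c(tp = tp, fp = fp, fn = fn, precision = prec, recall = rec, f1 = f1,
      support = sum(y_true == cl))
  })
  per <- do.call(rbind, per)
  acc <- mean(y_true == y_pred)
  if (average == "macro") {
    out <- colMeans(per[, c("precision", "recall", "f1"), drop = FALSE])
  } else if (average == "weighted") {
    w <- per[, "support"] / sum(per[, "support"])
    out <- colSums(per[, c("precision", "recall", "f1"), drop = FALSE] * w)
  } else {
    tp <- sum(per[, "tp"]); fp <- sum(per[, "fp"]); fn <- sum(per[, "fn"])
    prec <- if (tp + fp > 0) tp / (tp + fp) else 0
    rec <- if (tp + fn > 0) tp / (tp + fn) else 0
    f1 <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
    out <- c(precision = prec, recall = rec, f1 = f1)
  }
  tibble::tibble(
    precision = unname(out["precision"]),
    recall = unname(out["recall"]),
    f1 = unname(out["f1"]),
    accuracy = acc,
    average = average
  )
}

#' Per-class recall
#'
#' @param y_true,y_pred Label vectors of equal length.
#' @return Tibble with `cell_type`, `recall`, `support`.
#' @export
per_class_recall <- function(y_true, y_pred) {
  y_true <- as.character(y_true); y_pred <- as.character(y_pred)
  classes <- sort(unique(y_true))
  tibble::tibble(
    cell_type = classes,
    recall = vapply(classes, function(cl) {
      mean(y_pred[y_true == cl] == cl)
    }, numeric(1)),
    support = vapply(classes, function(cl) sum(y_true == cl), numeric(1))
  )
}

#' Batch-mixing silhouette score
#'
#' Computes silhouette widths of the samples with batches as clusters
#' (Euclidean distance in the supplied representation), averages them and
#' returns `1 - |mean silhouette|`, so values near 1 indicate well-mixed
#' batches (reduced batch effect) and values near 0 indicate separated
#' batches.
#'
#' @param X Numeric matrix of samples (for example a PC-50 representation).
#' @param batches Batch label vector, `>= 2` batches with `>= 2` members
#'   each.
#' @return A number in `[0, 1]`.
#' @export
batch_silhouette <- function(X, batches) {
  X <- as_row_matrix(X, arg = "X")
  batches <- as.character(batches)
  if (length(batches) != nrow(X)) stop("`batches` must align with rows", call. = FALSE)
  counts <- table(batches)
  if (length(counts) < 2L) stop("need >= 2 batches", call. = FALSE)
  if (any(counts < 2L)) stop("every batch needs >= 2 members", call. = FALSE)
  sil <- cluster::silhouette(as.integer(factor(batches)), stats::dist(X))
  s <- mean(sil[, "sil_width"])
  1 - abs(s)
}

#' Root mean square error
#'
#' @param A,B Numeric vectors or matrices of identical shape.
#' @return `sqrt(mean((A - B)^2))`.
#' @export
rmse <- function(A, B) {
  if (length(A) != length(B)) stop("`A` and `B` must have identical shape", call. = FALSE)
  if (length(A) == 0L) stop("empty input", call. = FALSE)
  sqrt(mean((as.numeric(A) - as.numeric(B))^2))
}

#' RMSE between keyed mean tables
#'
#' Pairs two tables (for example interaction-pair by ligand-receptor mean
#' expression tables) on the intersection of their keys and computes the
#' RMSE over the shared entries, reporting the overlap size.
#'
#' @param a,b Data frames.
#' @param by Character vector of key column names.
#' @param value Name of the value column.
#' @return A one-row tibble with `rmse` and `n_overlap`.
#' @export
rmse_paired <- function(a, b, by, value = "mean_expression") {
  stopifnot(is.data.frame(a), is.data.frame(b))
  merged <- dplyr::inner_join(
    dplyr::select(a, dplyr::all_of(c(by, value))),
    dplyr::select(b, dplyr::all_of(c(by, value))),
    by = by, suffix = c("_a", "_b")
  )
  if (nrow(merged) == 0L) stop("no overlapping keys", call. = FALSE)
  tibble::tibble(
    rmse = rmse(merged[[paste0(value, "_a")]], merged[[paste0(value, "_b")]]),
    n_overlap = nrow(merged)
  )
}

#' Fidelity metrics between a real and a synthetic sample
#'
#' Computes the requested two-sample discrepancies in the supplied
#' representation and returns them as a tidy report.
#'
#' @param real,synthetic Numeric matrices in the same feature space.
#' @param metrics Subset of `c("wd", "cd", "mmd")`.
#' @param config An [rbf_config()] for the MMD.
#' @param representation Free-text tag recorded in the report (for example
#'   `"pc50"` or `"raw"`).
#' @return A tibble of class `metric_report` with columns `metric`, `value`,
#'   `n_real`, `n_synth`, `representation`, `scales`.
#' @export
evaluate_fidelity <- function(real, synthetic, metrics = c("wd", "cd", "mmd"),
                              config = rbf_config(),
                              representation = "raw") {
  metrics <- match.arg(metrics, several.ok = TRUE)
  real <- as_row_matrix(real, arg = "real")
  synthetic <- as_row_matrix(synthetic, arg = "synthetic")
  vals <- vapply(metrics, function(m) {
    switch(m,
      wd = wasserstein_mean(real, synthetic),
      cd = correlation_discrepancy(real, synthetic),
      mmd = mmd_rbf(real, synthetic, config)
    )
  }, numeric(1))
  out <- tibble::tibble(
    metric = metrics,
    value = unname(vals),
    n_real = nrow(real),
    n_synth = nrow(synthetic),
    representation = representation,
    scales = paste(config$length_scales, collapse = ",")
  )
  class(out) <- c("metric_report", class(out))
  out
}

#' Plot a fidelity metric report
#'
#' @param object A `metric_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.metric_report <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$metric, y = .data$value)) +
    ggplot2::geom_col(fill = "steelblue", width = 0.6) +
    ggplot2::labs(x = NULL, y = "discrepancy",
                  subtitle = paste0("representation: ",
                                    object$representation[1])) +
    ggplot2::theme_minimal()
}
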