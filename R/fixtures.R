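#' Configuration for the negative-binomial scRNA-seq simulator
#'
#' Describes an imbalanced multi-cell-type count matrix with the statistical
#' structure the generative models consume: per-gene log-normal mean
#' expression, negative-binomial counts with a global dispersion, per-type
#' marker-gene fold shifts, Bernoulli dropout zeroing, geometrically decaying
#' class sizes and optional multiplicative batch effects.
#'
#' @param n_cells,n_genes,n_types Matrix dimensions and number of cell types.
#' @param decay Geometric decay factor of the class proportions
#'   (`p_k` proportional to `decay^(k-1)`); `decay = 20^(-1/3)` gives a 20:1
#'   largest-to-smallest ratio over four types.
#' @param markers_per_type Marker genes per type (disjoint blocks).
#' @param marker_fold Multiplicative mean up-shift of a type's markers within
#'   that type.
#' @param mean_log_mean,mean_log_sd Log-normal parameters of the per-gene
#'   base means.
#' @param dispersion Negative-binomial `size` parameter (smaller = noisier).
#' @param dropout Probability that an observed count is zeroed.
#' @param n_batches Number of batches; `1` disables batch structure.
#' @param batch_sd Standard deviation of the per-batch per-gene log-normal
#'   multiplicative shift.
#' @param seed Integer seed; simulation is fully deterministic given it.
#' @return A `fixture_config` list.
#' @export
fixture_config <- function(n_cells = 2000L, n_genes = 200L, n_types = 4L,
                           decay = 20^(-1 / 3), markers_per_type = 10L,
                           marker_fold = 4, mean_log_mean = 0.5,
                           mean_log_sd = 0.7, dispersion = 2,
                           dropout = 0.3, n_batches = 1L, batch_sd = 0.2,
                           seed = 1L) {
  stopifnot(decay > 0, marker_fold > 0, dispersion > 0,
            dropout >= 0, dropout < 1, batch_sd >= 0)
  n_types <- check_positive_int(n_types, "n_types")
  markers_per_type <- check_positive_int(markers_per_type, "markers_per_type")
  if (n_types * markers_per_type > n_genes) {
    stop("marker blocks exceed the gene count", call. = FALSE)
  }
  structure(
    list(
      n_cells = check_positive_int(n_cells, "n_cells"),
      n_genes = check_positive_int(n_genes, "n_genes"),
      n_types = n_types, decay = decay,
      markers_per_type = markers_per_type, marker_fold = marker_fold,
      mean_log_mean = mean_log_mean, mean_log_sd = mean_log_sd,
      dispersion = dispersion, dropout = dropout,
      n_batches = check_positive_int(n_batches, "n_batches"),
      batch_sd = batch_sd, seed = as.integer(seed)
    ),
    class = "fixture_config"
  )
}

#' Simulate an imbalanced labeled scRNA-seq count matrix
#'
#' @param config A [fixture_config()].
#' @return A [labeled_dataset()] with a counts layer, cell-type labels and
#'   (when `n_batches > 1`) batch labels. Class sizes are a multinomial draw
#'   from the geometric proportions.
#' @export
simulate_fixture <- function(config = fixture_config()) {
  stopifnot(inherits(config, "fixture_config"))
  withr::with_seed(config$seed, {
    k <- config$n_types
    p <- config$decay^(seq_len(k) - 1)
    p <- p / sum(p)
    sizes <- drop(stats::rmultinom(1L, config$n_cells, p))
    base_mu <- stats::rlnorm(config$n_genes, config$mean_log_mean,
                             config$mean_log_sd)
    marker_sets <- lapply(seq_len(k), function(t) {
      ((t - 1L) * config$markers_per_type + 1L):(t * config$markers_per_type)
    })
    type_mu <- lapply(seq_len(k), function(t) {
      mu <- base_mu
      mu[marker_sets[[t]]] <- mu[marker_sets[[t]]] * config$marker_fold
      mu
    })
    labels <- rep(paste0("type_", seq_len(k)), times = sizes)
    n <- length(labels)
    batch <- if (config$n_batches > 1L) {
      sample(paste0("batch_", seq_len(config$n_batches)), n, replace = TRUE)
    }
    batch_shift <- if (config$n_batches > 1L) {
      matrix(stats::rlnorm(config$n_batches * config$n_genes,
                           meanlog = 0, sdlog = config$batch_sd),
             config$n_batches, config$n_genes)
    }
    vals <- matrix(0, n, config$n_genes)
    row <- 0L
    for (t in seq_len(k)) {
      for (i in seq_len(sizes[t])) {
        row <- row + 1L
        mu <- type_mu[[t]]
        if (!is.null(batch_shift)) {
          b <- as.integer(sub("batch_", "", batch[row]))
          mu <- mu * batch_shift[b, ]
        }
        cnt <- stats::rnbinom(config$n_genes, mu = mu, size = config$dispersion)
        if (config$dropout > 0) {
          cnt <- cnt * stats::rbinom(config$n_genes, 1L, 1 - config$dropout)
        }
        vals[row, ] <- cnt
      }
    }
    cm <- count_matrix(
      vals,
      genes = sprintf("gene_%03d", seq_len(config$n_genes)),
      cells = sprintf("cell_%04d", seq_len(n)),
      layer = "counts"
    )
    out <- labeled_dataset(cm, labels, batch)
    attr(out, "marker_sets") <- marker_sets
    attr(out, "proportions") <- p
    out
  })
}
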