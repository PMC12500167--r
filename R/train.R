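#' Training configuration for flow models
#'
#' Defaults reproduce the selected MAF-FB setting: a single flow layer,
#' 1024 hidden features, learning rate `1e-6`, and 100 iterations
#' (interpreted as epochs over the training set). The grid these values came
#' from fixed only the rate, so the optimizer defaults to Adam with plain SGD
#' selectable.
#'
#' @param model `"maf"` or `"moe"`.
#' @param n_layers MAF layers (MAF-FB) — ignored for `"moe"`.
#' @param hidden_features Hidden width of the masked conditioners.
#' @param learning_rate Optimizer step size.
#' @param n_iterations Training epochs.
#' @param batch_size Minibatch size; the full batch is used when the data is
#'   smaller.
#' @param seed Integer seed governing initialization, shuffling and jitter.
#' @param optimizer `"adam"` or `"sgd"`.
#' @param n_blocks,n_experts,n_heads,embed_dim,gate_hidden,actnorm,context_mask,mask_hidden
#'   MOE-FB architecture settings, see [build_moefb()].
#' @param jitter_sd Standard deviation of the seeded Gaussian jitter added to
#'   zero-variance features before fitting.
#' @return A `train_config` list.
#' @export
train_config <- function(model = c("maf", "moe"),
                         n_layers = 1L,
                         hidden_features = 1024L,
                         learning_rate = 1e-6,
                         n_iterations = 100L,
                         batch_size = 256L,
                         seed = 1L,
                         optimizer = c("adam", "sgd"),
                         n_blocks = 1L,
                         n_experts = 4L,
                         n_heads = 10L,
                         embed_dim = 20L,
                         gate_hidden = 64L,
                         actnorm = TRUE,
                         context_mask = TRUE,
                         mask_hidden = 64L,
                         jitter_sd = 1e-6) {
  model <- match.arg(model)
  optimizer <- match.arg(optimizer)
  stopifnot(learning_rate > 0)
  structure(
    list(
      model = model,
      n_layers = check_positive_int(n_layers, "n_layers"),
      hidden_features = check_positive_int(hidden_features, "hidden_features"),
      learning_rate = learning_rate,
      n_iterations = check_positive_int(n_iterations, "n_iterations"),
      batch_size = check_positive_int(batch_size, "batch_size"),
      seed = as.integer(seed),
      optimizer = optimizer,
      n_blocks = check_positive_int(n_blocks, "n_blocks"),
      n_experts = check_positive_int(n_experts, "n_experts"),
      n_heads = check_positive_int(n_heads, "n_heads"),
      embed_dim = check_positive_int(embed_dim, "embed_dim"),
      gate_hidden = check_positive_int(gate_hidden, "gate_hidden"),
      actnorm = isTRUE(actnorm),
      context_mask = isTRUE(context_mask),
      mask_hidden = check_positive_int(mask_hidden, "mask_hidden"),
      jitter_sd = jitter_sd
    ),
    class = "train_config"
  )
}

build_from_config <- function(d, config) {
  if (config$model == "maf") {
    build_maffb(d, config$n_layers, config$hidden_features,
                permute_seed = config$seed)
  } else {
    build_moefb(d, config$n_blocks, config$hidden_features,
                config$n_experts, config$n_heads, config$embed_dim,
                config$gate_hidden, config$actnorm, config$context_mask,
                config$mask_hidden)
  }
}

# Data-dependent ActNorm initialization: each ActNorm standardizes the
# activations reaching it from the init batch.
initialize_actnorms <- function(model, batch) {
  x <- batch
  if (!is.null(model$context_mask)) {
    x <- context_mask_forward(model$context_mask, x)$y
  }
  for (i in seq_along(model$layers)) {
    l <- model$layers[[i]]
    if (inherits(l, "actnorm_layer") && l$enabled && !l$initialized) {
      l <- actnorm_initialize(l, x)
      model$layers[[i]] <- l
    }
    x <- layer_forward(model$layers[[i]], x)$y
  }
  model
}

#' Fit a flow model by maximum likelihood
#'
#' Minimizes the mean negative log-likelihood with minibatch gradient descent
#' (Adam by default). All gradients are computed analytically through every
#' layer, including the attention experts and the contextual feature mask.
#' Training is deterministic given `config$seed`. Zero-variance features are
#' perturbed with tiny seeded Gaussian jitter (with a warning) to avoid scale
#' collapse; a non-finite loss aborts with a `flowsynth_divergence` condition
#' carrying the loss history.
#'
#' @param data Numeric matrix, samples in rows (`>= 2` rows).
#' @param config A [train_config()].
#' @param model Optional pre-built [flow_model()]; by default the
#'   architecture is built from `config`.
#' @return An object of class `flow_fit` with elements `model`, `config`,
#'   `history` (tibble of per-epoch mean NLL), `n` and `d`.
#' @export
train_flow <- function(data, config = train_config(), model = NULL) {
  data <- as_row_matrix(data, arg = "data")
  n <- nrow(data)
  d <- ncol(data)
  if (n < 2L) stop("`data` must have at least 2 rows", call. = FALSE)
  sds <- apply(data, 2L, stats::sd)
  if (any(sds == 0)) {
    warning(sum(sds == 0), " zero-variance feature(s); adding seeded jitter (sd = ",
            format(config$jitter_sd), ")")
    zcols <- which(sds == 0)
    data[, zcols] <- data[, zcols, drop = FALSE] +
      matrix(seeded_normal(n * length(zcols), config$jitter_sd,
                           config$seed + 1000003L),
             n, length(zcols))
  }
  history <- numeric(config$n_iterations)
  withr::with_seed(config$seed, {
    if (is.null(model)) model <- build_from_config(d, config)
    model <- initialize_actnorms(
      model, data[seq_len(min(n, config$batch_size)), , drop = FALSE]
    )
    params <- flow_params(model)
    theta <- unlist(params)
    opt_m <- numeric(length(theta))
    opt_v <- numeric(length(theta))
    tstep <- 0L
    bs <- min(config$batch_size, n)
    for (epoch in seq_len(config$n_iterations)) {
      perm <- sample.int(n)
      epoch_loss <- 0
      starts <- seq(1L, n, by = bs)
      for (s0 in starts) {
        idx <- perm[s0:min(s0 + bs - 1L, n)]
        xb <- data[idx, , drop = FALSE]
        nb <- nrow(xb)
        fw <- flow_forward(model, xb, keep_cache = TRUE)
        loss <- mean(0.5 * (rowSums(fw$z^2) + d * log(2 * pi)) - fw$logdet)
        if (!is.finite(loss)) {
          cond <- structure(
            class = c("flowsynth_divergence", "error", "condition"),
            list(message = paste0("training diverged (non-finite loss) at epoch ",
                                  epoch),
                 call = sys.call(-1),
                 history = tibble::tibble(
                   epoch = seq_len(epoch - 1L),
                   nll = history[seq_len(epoch - 1L)]
                 ))
          )
          stop(cond)
        }
        epoch_loss <- epoch_loss + loss * nb
        grads <- flow_backward(model, fw, fw$z / nb, rep(-1 / nb, nb))
        g <- unlist(grads)
        if (config$optimizer == "adam") {
          tstep <- tstep + 1L
          opt_m <- 0.9 * opt_m + 0.1 * g
          opt_v <- 0.999 * opt_v + 0.001 * g^2
          mhat <- opt_m / (1 - 0.9^tstep)
          vhat <- opt_v / (1 - 0.999^tstep)
          theta <- theta - config$learning_rate * mhat / (sqrt(vhat) + 1e-8)
        } else {
          theta <- theta - config$learning_rate * g
        }
        model <- flow_set_params(model, utils::relist(theta, params))
      }
      history[epoch] <- epoch_loss / n
    }
  })
  structure(
    list(
      model = model,
      config = config,
      history = tibble::tibble(epoch = seq_len(config$n_iterations), nll = history),
      n = n, d = d
    ),
    class = "flow_fit"
  )
}

#' @export
print.flow_fit <- function(x, ...) {
  cat("<flow_fit> ", x$config$model, "-flow, d = ", x$d, ", n = ", x$n,
      ", final NLL = ", format(utils::tail(x$history$nll, 1), digits = 6),
      "\n", sep = "")
  invisible(x)
}

#' Tidy a fitted flow's training history
#'
#' @param x A `flow_fit`.
#' @param ... Unused.
#' @return A tibble with columns `epoch` and `nll`.
#' @export
tidy.flow_fit <- function(x, ...) x$history

#' One-row summary of a fitted flow
#'
#' @param x A `flow_fit`.
#' @param ... Unused.
#' @return A one-row tibble with model kind, sizes and final NLL.
#' @export
glance.flow_fit <- function(x, ...) {
  tibble::tibble(
    model = x$config$model,
    n = x$n,
    d = x$d,
    iterations = x$config$n_iterations,
    learning_rate = x$config$learning_rate,
    final_nll = utils::tail(x$history$nll, 1)
  )
}

#' Plot the training loss curve of a fitted flow
#'
#' @param object A `flow_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.flow_fit <- function(object, ...) {
  ggplot2::ggplot(object$history, ggplot2::aes(x = .data$epoch, y = .data$nll)) +
    ggplot2::geom_line(color = "steelblue") +
    ggplot2::labs(x = "epoch", y = "mean NLL",
                  title = paste0(object$config$model, " flow training")) +
    ggplot2::theme_minimal()
}

#' Save / load a flow checkpoint
#'
#' The checkpoint is a single-file archive holding a schema version, the
#' configuration echo, all layer parameters and the training history.
#'
#' @param fit A `flow_fit`.
#' @param path File path.
#' @return `save_flow` returns `path` invisibly; `load_flow` returns the
#'   restored `flow_fit`.
#' @export
save_flow <- function(fit, path) {
  stopifnot(inherits(fit, "flow_fit"))
  saveRDS(list(schema = "flowsynth-checkpoint-1", fit = fit), path)
  invisible(path)
}

#' @rdname save_flow
#' @export
load_flow <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$schema, "flowsynth-checkpoint-1")) {
    stop("not a flowsynth checkpoint (schema mismatch)", call. = FALSE)
  }
  obj$fit
}
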