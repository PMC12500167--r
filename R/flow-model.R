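#' Construct a flow model from a list of invertible layers
#'
#' A flow model maps data `x` through an ordered sequence of invertible
#' layers to a latent point `z` that is modeled as standard multivariate
#' normal. The exact log-density follows from the change of variables:
#' the base log-density of the fully transformed point plus the sum of all
#' layer log-determinants. An optional (non-invertible) contextual feature
#' mask is applied to inputs before the invertible stack on the
#' density/training path and skipped during sampling.
#'
#' @param layers List of flow layers (`maf_layer`, `actnorm_layer`,
#'   `moe_coupling_layer`), applied to data in order.
#' @param d Feature dimension.
#' @param context_mask Optional [new_context_mask()] module.
#' @return An object of class `flow_model`.
#' @export
flow_model <- function(layers, d, context_mask = NULL) {
  d <- check_positive_int(d, "d")
  stopifnot(is.list(layers))
  for (l in layers) {
    if (!inherits(l, "flow_layer")) stop("all layers must be flow layers", call. = FALSE)
    if (l$d != d) stop("layer dimension mismatch", call. = FALSE)
  }
  if (!is.null(context_mask)) stopifnot(inherits(context_mask, "context_mask"))
  structure(
    list(layers = layers, d = d, context_mask = context_mask),
    class = "flow_model"
  )
}

#' Standard-normal base log-density
#'
#' Log-density of the `d`-dimensional standard multivariate Gaussian,
#' `-0.5 * (||z||^2 + d * log(2 pi))`, evaluated per row.
#'
#' @param z Numeric vector (one point) or matrix (rows are points).
#' @return Numeric vector of log-densities.
#' @export
base_log_density <- function(z) {
  z <- as_row_matrix(z, arg = "z")
  if (any(!is.finite(z))) stop("`z` must be finite", call. = FALSE)
  -0.5 * (rowSums(z^2) + ncol(z) * log(2 * pi))
}

# Full forward pass with caches (training path: context mask included).
flow_forward <- function(model, x, keep_cache = FALSE) {
  x <- as_row_matrix(x, model$d)
  mask_cache <- NULL
  if (!is.null(model$context_mask)) {
    mf <- context_mask_forward(model$context_mask, x)
    x <- mf$y
    mask_cache <- mf$cache
  }
  logdet <- rep(0, nrow(x))
  caches <- if (keep_cache) vector("list", length(model$layers)) else NULL
  for (i in seq_along(model$layers)) {
    fw <- layer_forward(model$layers[[i]], x)
    x <- fw$y
    logdet <- logdet + fw$logdet
    if (keep_cache) caches[[i]] <- fw$cache
  }
  list(z = x, logdet = logdet, caches = caches, mask_cache = mask_cache)
}

# Inverse of the invertible stack only (sampling path).
flow_inverse <- function(model, z) {
  z <- as_row_matrix(z, model$d, arg = "z")
  for (i in rev(seq_along(model$layers))) {
    z <- layer_inverse(model$layers[[i]], z)
  }
  z
}

#' Exact log-density under a flow model
#'
#' @param x Numeric vector or matrix of data points (rows are samples).
#' @param model A [flow_model()] (or a fitted model from [train_flow()]).
#' @return Numeric vector of per-sample log-densities. Non-finite inputs or
#'   intermediates propagate to non-finite results.
#' @export
flow_log_density <- function(x, model) {
  model <- as_flow_model(model)
  fw <- flow_forward(model, x)
  ok <- apply(fw$z, 1L, function(r) all(is.finite(r)))
  out <- rep(NA_real_, nrow(fw$z))
  if (any(ok)) {
    out[ok] <- base_log_density(fw$z[ok, , drop = FALSE]) + fw$logdet[ok]
  }
  out
}

#' Mean negative log-likelihood of a batch
#'
#' The training objective: `-(1/N) * sum_n log p(x_n)`.
#'
#' @param batch Numeric matrix of samples (rows).
#' @param model A [flow_model()] or fitted flow.
#' @return A single numeric value.
#' @export
nll_loss <- function(batch, model) {
  batch <- as_row_matrix(batch, arg = "batch")
  if (nrow(batch) == 0L) stop("`batch` must be non-empty", call. = FALSE)
  -mean(flow_log_density(batch, model))
}

#' Sample from a flow model
#'
#' Draws latent points `z ~ N(0, I_d)` and passes them through the inverses
#' of the invertible layers in reverse order. The contextual feature mask, if
#' present, is a density-path preprocessor and is never applied when
#' sampling.
#'
#' @param model A [flow_model()] or fitted flow.
#' @param n Number of samples.
#' @param seed Integer seed; sampling is deterministic given `seed`.
#' @return An `n x d` matrix of samples.
#' @export
sample_flow <- function(model, n, seed = 1L) {
  model <- as_flow_model(model)
  n <- check_positive_int(n, "n")
  z <- withr::with_seed(seed, matrix(stats::rnorm(n * model$d), n, model$d))
  flow_inverse(model, z)
}

as_flow_model <- function(model) {
  if (inherits(model, "flow_fit")) return(model$model)
  stopifnot(inherits(model, "flow_model"))
  model
}

# ---- parameter (un)flattening -------------------------------------------

flow_params <- function(model) {
  p <- list()
  if (!is.null(model$context_mask)) p$mask <- model$context_mask$params
  p$layers <- lapply(model$layers, layer_params)
  p
}

flow_set_params <- function(model, params) {
  if (!is.null(model$context_mask)) model$context_mask$params <- params$mask
  for (i in seq_along(model$layers)) {
    model$layers[[i]] <- layer_set_params(model$layers[[i]], params$layers[[i]])
  }
  model
}

# Backward pass through the whole model; returns gradients in the structure
# of flow_params(). d_z is the loss gradient at the latent output; d_logdet
# is the per-sample loss gradient of the accumulated log-determinant.
flow_backward <- function(model, fw, d_z, d_logdet) {
  layer_grads <- vector("list", length(model$layers))
  for (i in rev(seq_along(model$layers))) {
    bw <- layer_backward(model$layers[[i]], fw$caches[[i]], d_z, d_logdet)
    d_z <- bw$d_x
    layer_grads[[i]] <- bw$grads
  }
  g <- list()
  if (!is.null(model$context_mask)) {
    g$mask <- context_mask_backward(model$context_mask, fw$mask_cache, d_z)$grads
  }
  g$layers <- layer_grads
  g
}
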