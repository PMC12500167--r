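#' Create a masked affine autoregressive (MAF) layer
#'
#' One flow layer in which each feature is transformed as
#' `z_i = (x_i - mu_i(x_<i)) / sigma_i(x_<i)`, with the location `mu_i` and
#' scale `sigma_i` emitted by a masked one-hidden-layer ReLU network whose
#' MADE masks guarantee that both depend only on features preceding `i` in the
#' autoregressive ordering. Positivity of the scale is enforced through
#' `sigma_i = exp(alpha_i)`, making the forward log-determinant exactly
#' `-sum_i alpha_i`.
#'
#' @param d Feature dimension.
#' @param hidden_features Hidden width of the masked conditioner.
#' @param ordering Autoregressive ordering (permutation of `1:d`).
#' @param init `"identity"` starts the layer at `mu = 0`, `sigma = 1` (output
#'   weights zero); `"random"` draws all weights from a small Gaussian, which
#'   is useful for invertibility and Jacobian checks.
#' @param init_sd Standard deviation for random initialization.
#' @return An object of class `maf_layer`.
#' @export
new_maf_layer <- function(d, hidden_features = 64L,
                          ordering = seq_len(d),
                          init = c("identity", "random"),
                          init_sd = 0.1) {
  d <- check_positive_int(d, "d")
  hidden_features <- check_positive_int(hidden_features, "hidden_features")
  init <- match.arg(init)
  masks <- build_autoregressive_masks(d, hidden_features, ordering)
  h <- hidden_features
  params <- list(
    W1 = matrix(stats::rnorm(h * d, sd = 1 / sqrt(max(d, 1))), h, d),
    b1 = rep(0, h),
    W_mu = matrix(0, d, h),
    b_mu = rep(0, d),
    W_alpha = matrix(0, d, h),
    b_alpha = rep(0, d)
  )
  if (init == "random") {
    params$W_mu <- matrix(stats::rnorm(d * h, sd = init_sd), d, h)
    params$W_alpha <- matrix(stats::rnorm(d * h, sd = init_sd), d, h)
    params$b_mu <- stats::rnorm(d, sd = init_sd)
    params$b_alpha <- stats::rnorm(d, sd = init_sd)
  }
  structure(
    list(
      d = d, hidden_features = h,
      ordering = masks$input_degrees,
      input_mask = masks$input_mask,
      output_mask = masks$output_mask,
      params = params
    ),
    class = c("maf_layer", "flow_layer")
  )
}

# Conditioner pass: returns mu, alpha (= log sigma) and the caches needed for
# backprop. Single parallel pass; masking keeps it autoregressive.
maf_conditioner <- function(layer, x) {
  p <- layer$params
  a1 <- sweep(tcrossprod(x, p$W1 * layer$input_mask), 2L, p$b1, "+")
  h <- relu(a1)
  mu <- sweep(tcrossprod(h, p$W_mu * layer$output_mask), 2L, p$b_mu, "+")
  alpha <- sweep(tcrossprod(h, p$W_alpha * layer$output_mask), 2L, p$b_alpha, "+")
  list(a1 = a1, h = h, mu = mu, alpha = alpha)
}

#' @export
layer_forward.maf_layer <- function(layer, x) {
  x <- as_row_matrix(x, layer$d)
  cond <- maf_conditioner(layer, x)
  z <- (x - cond$mu) * exp(-cond$alpha)
  list(
    y = z,
    logdet = -rowSums(cond$alpha),
    cache = c(cond, list(x = x))
  )
}

#' @export
layer_backward.maf_layer <- function(layer, cache, d_y, d_logdet) {
  p <- layer$params
  w1m <- p$W1 * layer$input_mask
  wmum <- p$W_mu * layer$output_mask
  wam <- p$W_alpha * layer$output_mask
  ea <- exp(-cache$alpha)
  n <- nrow(d_y)
  # z = (x - mu) * exp(-alpha); logdet = -sum(alpha)
  d_alpha <- -d_y * (cache$x - cache$mu) * ea -
    matrix(d_logdet, n, layer$d)
  d_mu <- -d_y * ea
  d_x <- d_y * ea
  d_h <- d_mu %*% wmum + d_alpha %*% wam
  d_a1 <- d_h * (cache$a1 > 0)
  d_x <- d_x + d_a1 %*% w1m
  grads <- list(
    W1 = crossprod(d_a1, cache$x) * layer$input_mask,
    b1 = colSums(d_a1),
    W_mu = crossprod(d_mu, cache$h) * layer$output_mask,
    b_mu = colSums(d_mu),
    W_alpha = crossprod(d_alpha, cache$h) * layer$output_mask,
    b_alpha = colSums(d_alpha)
  )
  list(d_x = d_x, grads = grads)
}

#' @export
layer_inverse.maf_layer <- function(layer, z) {
  z <- as_row_matrix(z, layer$d, arg = "z")
  x <- z
  # Sequential inversion: feature at autoregressive rank r only needs the
  # already-reconstructed features of lower rank, so one conditioner pass per
  # rank suffices.
  for (r in seq_len(layer$d)) {
    i <- which(layer$ordering == r)
    cond <- maf_conditioner(layer, x)
    x[, i] <- z[, i] * exp(cond$alpha[, i]) + cond$mu[, i]
  }
  x
}

#' Evaluate a MAF layer on a batch
#'
#' Applies the forward (data-to-latent) direction of a MAF layer and returns
#' the transformed batch together with the per-sample log-determinant.
#'
#' @param x Numeric vector or matrix (rows are samples).
#' @param layer A [new_maf_layer()] object.
#' @return A list with `z` (matrix) and `logdet` (numeric vector).
#' @export
maf_forward <- function(x, layer) {
  stopifnot(inherits(layer, "maf_layer"))
  x <- as_row_matrix(x, layer$d)
  if (any(!is.finite(x))) stop("`x` must be finite", call. = FALSE)
  fw <- layer_forward(layer, x)
  list(z = fw$y, logdet = fw$logdet)
}

#' Invert a MAF layer
#'
#' Sequentially reconstructs `x` such that `maf_forward(x, layer)$z == z`.
#'
#' @param z Numeric vector or matrix of latent points.
#' @param layer A [new_maf_layer()] object.
#' @return Matrix of reconstructed inputs.
#' @export
maf_inverse <- function(z, layer) {
  stopifnot(inherits(layer, "maf_layer"))
  z <- as_row_matrix(z, layer$d, arg = "z")
  if (any(!is.finite(z))) stop("`z` must be finite", call. = FALSE)
  layer_inverse(layer, z)
}
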