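#' Create a contextual feature masking module
#'
#' A learnable, sample-adaptive soft mask that attenuates uninformative
#' (typically sparse) features by interpolating them toward the sample mean.
#' A shallow ReLU MLP maps the feature vector to `c = sigmoid(...)`, the mask
#' is `m = 0.5 * c` (so `m` lies in `(0, 0.5)`), and the masked input is
#' `x' = x * (1 - m) + xbar * m`, where `xbar` is the scalar mean of the
#' sample's feature values. Each masked value is therefore a convex
#' combination of the original value and the sample mean, never moving more
#' than halfway.
#'
#' The module is not invertible; in a flow it acts as a learnable input
#' preprocessor on the density/training path, contributes nothing to the
#' log-determinant, and is skipped during sampling.
#'
#' @param d Feature dimension.
#' @param hidden Hidden width of the masking MLP.
#' @param bias_init Initial value of the output bias `b_m`. The default `-3`
#'   starts the mask near zero so the module is close to the identity.
#' @return An object of class `context_mask`.
#' @export
new_context_mask <- function(d, hidden = 64L, bias_init = -3) {
  d <- check_positive_int(d, "d")
  hidden <- check_positive_int(hidden, "hidden")
  structure(
    list(
      d = d, hidden = hidden,
      params = list(
        W_c = matrix(stats::rnorm(hidden * d, sd = 1 / sqrt(d)), hidden, d),
        b_c = rep(0, hidden),
        W_m = matrix(stats::rnorm(d * hidden, sd = 0.01), d, hidden),
        b_m = rep(bias_init, d)
      )
    ),
    class = "context_mask"
  )
}

context_mask_forward <- function(module, x) {
  p <- module$params
  a <- sweep(tcrossprod(x, p$W_c), 2L, p$b_c, "+")
  h <- relu(a)
  cpre <- sweep(tcrossprod(h, p$W_m), 2L, p$b_m, "+")
  cval <- sigmoid(cpre)
  m <- 0.5 * cval
  xbar <- rowMeans(x)
  xp <- x * (1 - m) + xbar * m
  list(y = xp, cache = list(x = x, a = a, h = h, cval = cval, m = m, xbar = xbar))
}

# Gradients for the mask parameters only; the input is data, and downstream
# layers receive x' directly.
context_mask_backward <- function(module, cache, d_y) {
  p <- module$params
  d_m <- d_y * (cache$xbar - cache$x)
  d_cpre <- 0.5 * d_m * cache$cval * (1 - cache$cval)
  d_h <- d_cpre %*% p$W_m
  d_a <- d_h * (cache$a > 0)
  list(grads = list(
    W_c = crossprod(d_a, cache$x),
    b_c = colSums(d_a),
    W_m = crossprod(d_cpre, cache$h),
    b_m = colSums(d_cpre)
  ))
}

#' Apply contextual feature masking
#'
#' @param x Numeric vector or matrix (rows are samples).
#' @param module A [new_context_mask()] object.
#' @return Matrix of masked inputs, the same shape as `x`.
#' @export
context_mask_apply <- function(x, module) {
  stopifnot(inherits(module, "context_mask"))
  x <- as_row_matrix(x, module$d)
  if (any(!is.finite(x))) stop("`x` must be finite", call. = FALSE)
  context_mask_forward(module, x)$y
}
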