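#' Create an ActNorm layer
#'
#' Trainable per-feature affine normalization `y = s * x + b` with exact
#' log-determinant `sum_j log |s_j|`. The layer can be disabled, in which case
#' it is the identity with zero log-determinant. Scale and bias are usually
#' initialized data-dependently from the first training batch (see
#' [actnorm_initialize()]) so that the batch is standardized feature-wise.
#'
#' @param d Feature dimension.
#' @param enabled If `FALSE` the layer passes inputs through unchanged.
#' @return An object of class `actnorm_layer`.
#' @export
new_actnorm_layer <- function(d, enabled = TRUE) {
  d <- check_positive_int(d, "d")
  structure(
    list(
      d = d,
      enabled = isTRUE(enabled),
      initialized = FALSE,
      params = list(s = rep(1, d), b = rep(0, d))
    ),
    class = c("actnorm_layer", "flow_layer")
  )
}

#' Data-dependent ActNorm initialization
#'
#' Sets `s = 1/sd(x_j)` and `b = -mean(x_j)/sd(x_j)` per feature so that the
#' initializing batch maps to zero mean and unit variance. Zero-variance
#' features keep `s = 1` with a warning.
#'
#' @param layer An [new_actnorm_layer()] object.
#' @param x Batch matrix used for initialization.
#' @return The initialized layer.
#' @export
actnorm_initialize <- function(layer, x) {
  stopifnot(inherits(layer, "actnorm_layer"))
  x <- as_row_matrix(x, layer$d)
  if (nrow(x) < 2L) stop("ActNorm initialization needs >= 2 rows", call. = FALSE)
  m <- colMeans(x)
  sdv <- apply(x, 2L, stats::sd)
  if (any(sdv == 0)) {
    warning("zero-variance feature(s) during ActNorm initialization; scale kept at 1")
    m[sdv == 0] <- 0
    sdv[sdv == 0] <- 1
  }
  layer$params$s <- 1 / sdv
  layer$params$b <- -m / sdv
  layer$initialized <- TRUE
  layer
}

#' @export
layer_forward.actnorm_layer <- function(layer, x) {
  x <- as_row_matrix(x, layer$d)
  if (!layer$enabled) {
    return(list(y = x, logdet = rep(0, nrow(x)), cache = list(x = x)))
  }
  s <- layer$params$s
  if (any(s == 0)) stop("ActNorm scale contains zero", call. = FALSE)
  y <- sweep(sweep(x, 2L, s, "*"), 2L, layer$params$b, "+")
  list(
    y = y,
    logdet = rep(sum(log(abs(s))), nrow(x)),
    cache = list(x = x)
  )
}

#' @export
layer_backward.actnorm_layer <- function(layer, cache, d_y, d_logdet) {
  if (!layer$enabled) {
    return(list(d_x = d_y, grads = list(s = rep(0, layer$d), b = rep(0, layer$d))))
  }
  s <- layer$params$s
  grads <- list(
    s = colSums(d_y * cache$x) + sum(d_logdet) / s,
    b = colSums(d_y)
  )
  list(d_x = sweep(d_y, 2L, s, "*"), grads = grads)
}

#' @export
layer_inverse.actnorm_layer <- function(layer, z) {
  z <- as_row_matrix(z, layer$d, arg = "z")
  if (!layer$enabled) return(z)
  s <- layer$params$s
  if (any(s == 0)) stop("ActNorm scale contains zero", call. = FALSE)
  sweep(sweep(z, 2L, layer$params$b, "-"), 2L, s, "/")
}

#' Apply an ActNorm layer
#'
#' @param x Numeric vector or matrix.
#' @param layer An [new_actnorm_layer()] object.
#' @return A list with `y` and per-sample `logdet`.
#' @export
actnorm_forward <- function(x, layer) {
  stopifnot(inherits(layer, "actnorm_layer"))
  fw <- layer_forward(layer, x)
  list(y = fw$y, logdet = fw$logdet)
}

#' Invert an ActNorm layer
#'
#' @param y Numeric vector or matrix of transformed points.
#' @param layer An [new_actnorm_layer()] object.
#' @return Matrix of reconstructed inputs.
#' @export
actnorm_inverse <- function(y, layer) {
  stopifnot(inherits(layer, "actnorm_layer"))
  layer_inverse(layer, y)
}
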