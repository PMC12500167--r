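# Internal layer interface.
#
# Every invertible layer implements:
#   layer_forward(layer, x)  -> list(y, logdet, cache)   (batch matrix in/out)
#   layer_backward(layer, cache, d_y, d_logdet) -> list(d_x, grads)
#   layer_inverse(layer, z)  -> x
# `d_logdet` is the per-sample gradient of the loss with respect to the
# layer's log-determinant contribution. `grads` mirrors layer$params.

layer_forward <- function(layer, x) UseMethod("layer_forward")
layer_backward <- function(layer, cache, d_y, d_logdet) UseMethod("layer_backward")
layer_inverse <- function(layer, z) UseMethod("layer_inverse")

# Parameters live in layer$params as a named list of numeric arrays; training
# flattens and restores them in structure order.
layer_params <- function(layer) layer$params
layer_set_params <- function(layer, params) {
  layer$params <- params
  layer
}
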