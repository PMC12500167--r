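#' Build a MAF flow (MAF-FB architecture)
#'
#' Stacks `n_layers` masked affine autoregressive layers over a standard
#' normal base. With a single layer (the selected setting) features keep
#' their natural column order; deeper stacks draw a fresh seeded permutation
#' of the autoregressive ordering for every layer after the first so that no
#' feature is unconditionally first throughout.
#'
#' @param d Feature dimension.
#' @param n_layers Number of MAF layers.
#' @param hidden_features Hidden width of each masked conditioner.
#' @param init Layer initialization, see [new_maf_layer()].
#' @param permute_seed Seed for the orderings of layers beyond the first.
#' @return A [flow_model()].
#' @export
build_maffb <- function(d, n_layers = 1L, hidden_features = 1024L,
                        init = "identity", permute_seed = 1L) {
  n_layers <- check_positive_int(n_layers, "n_layers")
  orderings <- c(
    list(seq_len(d)),
    if (n_layers > 1L) {
      withr::with_seed(permute_seed, lapply(seq_len(n_layers - 1L), function(i) {
        sample(seq_len(d))
      }))
    }
  )
  layers <- lapply(orderings, function(ord) {
    new_maf_layer(d, hidden_features, ordering = ord, init = init)
  })
  flow_model(layers, d)
}

#' Build a mixture-of-experts attention flow (MOE-FB architecture)
#'
#' Composes a contextual feature mask front end with `n_blocks` blocks of
#' `[ActNorm, MoE coupling, ActNorm, MAF]`. The mask is applied to inputs on
#' the density/training path only and contributes nothing to the Jacobian;
#' sampling inverts the invertible blocks alone.
#'
#' @param d Feature dimension (`>= 2`).
#' @param n_blocks Number of blocks.
#' @param hidden_features Hidden width of the MAF conditioners.
#' @param n_experts,n_heads,embed_dim,gate_hidden Mixture-of-experts coupling
#'   sizes, see [new_moe_coupling_layer()].
#' @param actnorm Enable the ActNorm layers (disabled layers are identities).
#' @param context_mask Include the contextual feature mask front end.
#' @param mask_hidden Hidden width of the feature-masking MLP.
#' @param init Layer initialization (`"identity"` or `"random"`).
#' @return A [flow_model()].
#' @export
build_moefb <- function(d, n_blocks = 1L, hidden_features = 1024L,
                        n_experts = 4L, n_heads = 10L, embed_dim = 20L,
                        gate_hidden = 64L, actnorm = TRUE,
                        context_mask = TRUE, mask_hidden = 64L,
                        init = "identity") {
  d <- check_positive_int(d, "d")
  if (d < 2L) stop("MOE-FB needs d >= 2 (coupling requires both partitions)", call. = FALSE)
  n_blocks <- check_positive_int(n_blocks, "n_blocks")
  layers <- list()
  for (b in seq_len(n_blocks)) {
    layers <- c(layers, list(
      new_actnorm_layer(d, enabled = actnorm),
      new_moe_coupling_layer(d, n_experts, n_heads, embed_dim, gate_hidden,
                             init = init),
      new_actnorm_layer(d, enabled = actnorm),
      new_maf_layer(d, hidden_features, init = init)
    ))
  }
  cm <- if (isTRUE(context_mask)) new_context_mask(d, mask_hidden) else NULL
  flow_model(layers, d, context_mask = cm)
}
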