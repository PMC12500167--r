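#' Create a mixture-of-experts attention coupling layer
#'
#' An affine coupling transform in which the features are split by an
#' alternating binary mask into a parameter-generating subset `x_a` (passed
#' through unchanged) and a transformed subset `x_b`. `x_a` is processed by
#' `n_experts` parallel multi-head attention experts; a softmax gating network
#' mixes the expert outputs, and learned linear heads map the aggregate to a
#' tanh-bounded scale `s` and a shift `t` so that
#' `z_b = x_b * exp(s) + t`, with exact log-determinant `sum(s)` over the
#' transformed coordinates.
#'
#' Tokenization is feature-wise: every a-set feature is one token, linearly
#' embedded into `embed_dim` dimensions (`embed_dim` must be divisible by
#' `n_heads`), attended over the a-set positions, and projected back to one
#' scalar per token.
#'
#' @param d Feature dimension (`d >= 2`, so both partitions are non-empty).
#' @param n_experts Number of attention experts.
#' @param n_heads Attention heads per expert.
#' @param embed_dim Token embedding size.
#' @param gate_hidden Hidden width of the gating network.
#' @param mask Optional binary partition mask of length `d`; defaults to the
#'   alternating mask `1,0,1,0,...`.
#' @param init `"identity"` zero-initializes the scale/shift heads so the
#'   layer starts as the identity; `"random"` perturbs them for testing.
#' @return An object of class `moe_coupling_layer`.
#' @export
new_moe_coupling_layer <- function(d, n_experts = 4L, n_heads = 10L,
                                   embed_dim = 20L, gate_hidden = 64L,
                                   mask = NULL,
                                   init = c("identity", "random")) {
  d <- check_positive_int(d, "d")
  if (d < 2L) stop("coupling needs d >= 2 so both partitions are non-empty", call. = FALSE)
  n_experts <- check_positive_int(n_experts, "n_experts")
  n_heads <- check_positive_int(n_heads, "n_heads")
  embed_dim <- check_positive_int(embed_dim, "embed_dim")
  gate_hidden <- check_positive_int(gate_hidden, "gate_hidden")
  if (embed_dim %% n_heads != 0L) {
    stop("`embed_dim` must be divisible by `n_heads`", call. = FALSE)
  }
  init <- match.arg(init)
  if (is.null(mask)) mask <- rep(c(1L, 0L), length.out = d)
  if (length(mask) != d || !all(mask %in% c(0L, 1L))) {
    stop("`mask` must be a binary vector of length d", call. = FALSE)
  }
  a_idx <- which(mask == 1L)
  b_idx <- which(mask == 0L)
  if (length(a_idx) == 0L || length(b_idx) == 0L) {
    stop("`mask` must select a non-empty subset on both sides", call. = FALSE)
  }
  ta <- length(a_idx)
  tb <- length(b_idx)
  de <- embed_dim

  new_expert <- function() {
    list(
      w_emb = stats::rnorm(de, sd = 0.5),
      b_emb = stats::rnorm(de, sd = 0.1),
      W_q = matrix(stats::rnorm(de * de, sd = 1 / sqrt(de)), de, de),
      W_k = matrix(stats::rnorm(de * de, sd = 1 / sqrt(de)), de, de),
      W_v = matrix(stats::rnorm(de * de, sd = 1 / sqrt(de)), de, de),
      W_o = matrix(stats::rnorm(de * de, sd = 1 / sqrt(de)), de, de),
      w_proj = stats::rnorm(de, sd = 1 / sqrt(de)),
      b_proj = 0
    )
  }
  params <- list(
    experts = lapply(seq_len(n_experts), function(e) new_expert()),
    U_g = matrix(stats::rnorm(gate_hidden * ta, sd = 0.3), gate_hidden, ta),
    W_g = matrix(stats::rnorm(n_experts * gate_hidden, sd = 0.3), n_experts, gate_hidden),
    b_g = rep(0, n_experts),
    W_s = matrix(0, tb, ta),
    b_s = rep(0, tb),
    W_t = matrix(0, tb, ta),
    b_t = rep(0, tb)
  )
  if (init == "random") {
    params$W_s <- matrix(stats::rnorm(tb * ta, sd = 0.3 / sqrt(ta)), tb, ta)
    params$b_s <- stats::rnorm(tb, sd = 0.1)
    params$W_t <- matrix(stats::rnorm(tb * ta, sd = 0.3 / sqrt(ta)), tb, ta)
    params$b_t <- stats::rnorm(tb, sd = 0.1)
  }
  structure(
    list(
      d = d, mask = as.integer(mask), a_idx = a_idx, b_idx = b_idx,
      n_experts = n_experts, n_heads = n_heads, embed_dim = de,
      gate_hidden = gate_hidden, params = params
    ),
    class = c("moe_coupling_layer", "flow_layer")
  )
}

# Because every token is a scalar feature under a shared linear embedding,
# the query/key/value of token j are affine in x_j. Each head therefore
# reduces to four scalars (A, B, C, D) in the attention scores
#   S[j, k] = (A x_j x_k + B x_j + C x_k + D) / sqrt(dk)
# and the head output at token j collapses to kappa * sum_k P[j, k] x_k plus
# a constant. This keeps the pass fully vectorized over the batch.
expert_head_constants <- function(ex, n_heads) {
  de <- length(ex$w_emb)
  dk <- de %/% n_heads
  uq <- drop(ex$w_emb %*% ex$W_q); cq <- drop(ex$b_emb %*% ex$W_q)
  uk <- drop(ex$w_emb %*% ex$W_k); ck <- drop(ex$b_emb %*% ex$W_k)
  uv <- drop(ex$w_emb %*% ex$W_v); cv <- drop(ex$b_emb %*% ex$W_v)
  vo <- drop(ex$W_o %*% ex$w_proj)
  list(uq = uq, cq = cq, uk = uk, ck = ck, uv = uv, cv = cv, vo = vo,
       dk = dk, sdk = sqrt(dk))
}

expert_forward <- function(ex, xa, n_heads) {
  n <- nrow(xa); ta <- ncol(xa)
  hc <- expert_head_constants(ex, n_heads)
  y <- matrix(0, n, ta)
  c0 <- ex$b_proj
  wtil <- vector("list", n_heads)
  for (h in seq_len(n_heads)) {
    idx <- ((h - 1L) * hc$dk + 1L):(h * hc$dk)
    a_ <- sum(hc$uq[idx] * hc$uk[idx]); b_ <- sum(hc$uq[idx] * hc$ck[idx])
    c_ <- sum(hc$cq[idx] * hc$uk[idx]); d_ <- sum(hc$cq[idx] * hc$ck[idx])
    kap <- sum(hc$uv[idx] * hc$vo[idx])
    c0 <- c0 + sum(hc$cv[idx] * hc$vo[idx])
    w <- matrix(0, n, ta)
    for (j in seq_len(ta)) {
      s_ <- (a_ * xa * xa[, j] + c_ * xa + (b_ * xa[, j] + d_)) / hc$sdk
      p <- row_softmax(s_)
      w[, j] <- rowSums(p * xa)
    }
    wtil[[h]] <- w
    y <- y + kap * w
  }
  list(y = y + c0, wtil = wtil)
}

expert_backward <- function(ex, xa, wtil, g_y, n_heads) {
  n <- nrow(xa); ta <- ncol(xa)
  hc <- expert_head_constants(ex, n_heads)
  de <- length(hc$uq)
  duq <- dcq <- duk <- dck <- duv <- dcv <- dvo <- numeric(de)
  dc0 <- sum(g_y)
  d_xa <- matrix(0, n, ta)
  for (h in seq_len(n_heads)) {
    idx <- ((h - 1L) * hc$dk + 1L):(h * hc$dk)
    a_ <- sum(hc$uq[idx] * hc$uk[idx]); b_ <- sum(hc$uq[idx] * hc$ck[idx])
    c_ <- sum(hc$cq[idx] * hc$uk[idx]); d_ <- sum(hc$cq[idx] * hc$ck[idx])
    kap <- sum(hc$uv[idx] * hc$vo[idx])
    dkap <- sum(g_y * wtil[[h]])
    dw <- g_y * kap
    da <- db <- dc <- dd <- 0
    for (j in seq_len(ta)) {
      s_ <- (a_ * xa * xa[, j] + c_ * xa + (b_ * xa[, j] + d_)) / hc$sdk
      p <- row_softmax(s_)
      dp <- dw[, j] * xa
      d_xa <- d_xa + dw[, j] * p
      r <- rowSums(dp * p)
      ds <- p * (dp - r)
      da <- da + sum(ds * xa * xa[, j]) / hc$sdk
      db <- db + sum(ds * xa[, j]) / hc$sdk
      dc <- dc + sum(ds * xa) / hc$sdk
      dd <- dd + sum(ds) / hc$sdk
      d_xa[, j] <- d_xa[, j] + rowSums(ds * (a_ * xa + b_)) / hc$sdk
      d_xa <- d_xa + ds * (a_ * xa[, j] + c_) / hc$sdk
    }
    duq[idx] <- da * hc$uk[idx] + db * hc$ck[idx]
    duk[idx] <- da * hc$uq[idx] + dc * hc$cq[idx]
    dcq[idx] <- dc * hc$uk[idx] + dd * hc$ck[idx]
    dck[idx] <- db * hc$uq[idx] + dd * hc$cq[idx]
    duv[idx] <- dkap * hc$vo[idx]
    dcv[idx] <- dc0 * hc$vo[idx]
    dvo[idx] <- dkap * hc$uv[idx] + dc0 * hc$cv[idx]
  }
  grads <- list(
    w_emb = drop(ex$W_q %*% duq + ex$W_k %*% duk + ex$W_v %*% duv),
    b_emb = drop(ex$W_q %*% dcq + ex$W_k %*% dck + ex$W_v %*% dcv),
    W_q = outer(ex$w_emb, duq) + outer(ex$b_emb, dcq),
    W_k = outer(ex$w_emb, duk) + outer(ex$b_emb, dck),
    W_v = outer(ex$w_emb, duv) + outer(ex$b_emb, dcv),
    W_o = outer(dvo, ex$w_proj),
    w_proj = drop(crossprod(ex$W_o, dvo)),
    b_proj = dc0
  )
  list(grads = grads, d_xa = d_xa)
}

# Gate + expert aggregation on the compact a-set matrix (n x |a|).
moe_aggregate <- function(layer, xa) {
  p <- layer$params
  ag <- tcrossprod(xa, p$U_g)
  hg <- relu(ag)
  logits <- sweep(tcrossprod(hg, p$W_g), 2L, p$b_g, "+")
  gate <- row_softmax(logits)
  ye <- vector("list", layer$n_experts)
  wtil <- vector("list", layer$n_experts)
  hagg <- matrix(0, nrow(xa), ncol(xa))
  for (e in seq_len(layer$n_experts)) {
    ef <- expert_forward(p$experts[[e]], xa, layer$n_heads)
    ye[[e]] <- ef$y
    wtil[[e]] <- ef$wtil
    hagg <- hagg + gate[, e] * ef$y
  }
  list(hagg = hagg, gate = gate, ye = ye, wtil = wtil, ag = ag, hg = hg)
}

#' @export
layer_forward.moe_coupling_layer <- function(layer, x) {
  x <- as_row_matrix(x, layer$d)
  p <- layer$params
  xa <- x[, layer$a_idx, drop = FALSE]
  xb <- x[, layer$b_idx, drop = FALSE]
  agg <- moe_aggregate(layer, xa)
  pre_s <- sweep(tcrossprod(agg$hagg, p$W_s), 2L, p$b_s, "+")
  s <- tanh(pre_s)
  tt <- sweep(tcrossprod(agg$hagg, p$W_t), 2L, p$b_t, "+")
  zb <- xb * exp(s) + tt
  z <- x
  z[, layer$b_idx] <- zb
  list(
    y = z,
    logdet = rowSums(s),
    cache = list(xa = xa, xb = xb, agg = agg, s = s)
  )
}

#' @export
layer_backward.moe_coupling_layer <- function(layer, cache, d_y, d_logdet) {
  p <- layer$params
  agg <- cache$agg
  s <- cache$s
  dzb <- d_y[, layer$b_idx, drop = FALSE]
  d_xa <- d_y[, layer$a_idx, drop = FALSE]
  es <- exp(s)
  ds <- dzb * cache$xb * es + d_logdet
  d_xb <- dzb * es
  dpre_s <- ds * (1 - s^2)
  g_W_s <- crossprod(dpre_s, agg$hagg)
  g_b_s <- colSums(dpre_s)
  g_W_t <- crossprod(dzb, agg$hagg)
  g_b_t <- colSums(dzb)
  d_hagg <- dpre_s %*% p$W_s + dzb %*% p$W_t
  d_gate <- vapply(agg$ye, function(y) rowSums(d_hagg * y),
                   numeric(nrow(d_hagg)))
  if (is.null(dim(d_gate))) d_gate <- matrix(d_gate, nrow = 1L)
  expert_grads <- vector("list", layer$n_experts)
  for (e in seq_len(layer$n_experts)) {
    eb <- expert_backward(p$experts[[e]], cache$xa, agg$wtil[[e]],
                          d_hagg * agg$gate[, e], layer$n_heads)
    expert_grads[[e]] <- eb$grads
    d_xa <- d_xa + eb$d_xa
  }
  # softmax gate backward
  dlogits <- agg$gate * (d_gate - rowSums(d_gate * agg$gate))
  g_W_g <- crossprod(dlogits, agg$hg)
  g_b_g <- colSums(dlogits)
  d_ag <- (dlogits %*% p$W_g) * (agg$ag > 0)
  g_U_g <- crossprod(d_ag, cache$xa)
  d_xa <- d_xa + d_ag %*% p$U_g
  d_x <- d_y
  d_x[, layer$a_idx] <- d_xa
  d_x[, layer$b_idx] <- d_xb
  list(
    d_x = d_x,
    grads = list(
      experts = expert_grads,
      U_g = g_U_g, W_g = g_W_g, b_g = g_b_g,
      W_s = g_W_s, b_s = g_b_s, W_t = g_W_t, b_t = g_b_t
    )
  )
}

#' @export
layer_inverse.moe_coupling_layer <- function(layer, z) {
  z <- as_row_matrix(z, layer$d, arg = "z")
  p <- layer$params
  za <- z[, layer$a_idx, drop = FALSE]
  zb <- z[, layer$b_idx, drop = FALSE]
  # the a-set is untouched, so s and t are recomputable from z_a alone
  agg <- moe_aggregate(layer, za)
  s <- tanh(sweep(tcrossprod(agg$hagg, p$W_s), 2L, p$b_s, "+"))
  tt <- sweep(tcrossprod(agg$hagg, p$W_t), 2L, p$b_t, "+")
  x <- z
  x[, layer$b_idx] <- (zb - tt) * exp(-s)
  x
}

#' Split features by a binary coupling mask
#'
#' Returns the zero-padded complementary parts `x_a = x * M` and
#' `x_b = x * (1 - M)`, so that `x_a + x_b = x`.
#'
#' @param x Numeric vector or matrix.
#' @param M Binary mask of length `ncol(x)`.
#' @return A list with full-length matrices `x_a` and `x_b`.
#' @export
coupling_split <- function(x, M) {
  x <- as_row_matrix(x)
  if (length(M) != ncol(x)) {
    stop("`M` must have one entry per feature", call. = FALSE)
  }
  if (!all(M %in% c(0, 1))) stop("`M` must be binary", call. = FALSE)
  xa <- sweep(x, 2L, M, "*")
  xb <- sweep(x, 2L, 1 - M, "*")
  list(x_a = xa, x_b = xb)
}

#' Mixture-of-experts attention over the parameter-generating subset
#'
#' Computes the gated aggregate of the attention experts for the a-set
#' features of `x`. The result is returned at full length `d`, with zeros at
#' the b-set positions (the layer's zero-padding convention).
#'
#' @param x_a Numeric vector or matrix, full length `d` (b-set entries are
#'   ignored).
#' @param layer A [new_moe_coupling_layer()] object.
#' @return Matrix (`n x d`) of aggregated expert outputs, along with the gate
#'   weights as attribute `"gate"`.
#' @export
moe_attention <- function(x_a, layer) {
  stopifnot(inherits(layer, "moe_coupling_layer"))
  x_a <- as_row_matrix(x_a, layer$d)
  agg <- moe_aggregate(layer, x_a[, layer$a_idx, drop = FALSE])
  out <- matrix(0, nrow(x_a), layer$d)
  out[, layer$a_idx] <- agg$hagg
  attr(out, "gate") <- agg$gate
  out
}

#' Apply a mixture-of-experts coupling layer
#'
#' @param x Numeric vector or matrix.
#' @param layer A [new_moe_coupling_layer()] object.
#' @return A list with `z` and per-sample `logdet`.
#' @export
coupling_forward <- function(x, layer) {
  stopifnot(inherits(layer, "moe_coupling_layer"))
  fw <- layer_forward(layer, x)
  list(z = fw$y, logdet = fw$logdet)
}

#' Invert a mixture-of-experts coupling layer
#'
#' @param z Numeric vector or matrix.
#' @param layer A [new_moe_coupling_layer()] object.
#' @return Matrix of reconstructed inputs.
#' @export
coupling_inverse <- function(z, layer) {
  stopifnot(inherits(layer, "moe_coupling_layer"))
  if (any(!is.finite(z))) stop("`z` must be finite", call. = FALSE)
  layer_inverse(layer, z)
}
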