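test_that("coupling_split matches the elementwise products and reconstructs", {
  out <- coupling_split(c(1, 2, 3, 4), c(1, 0, 1, 0))
  expect_equal(drop(out$x_a), c(1, 0, 3, 0))
  expect_equal(drop(out$x_b), c(0, 2, 0, 4))
  all_ones <- coupling_split(c(1, 2), c(1, 1))
  expect_equal(drop(all_ones$x_a), c(1, 2))
  expect_equal(drop(all_ones$x_b), c(0, 0))
  set.seed(10)
  x <- matrix(rnorm(12), 3, 4)
  sp <- coupling_split(x, c(0, 1, 1, 0))
  expect_equal(sp$x_a + sp$x_b, x)
  expect_error(coupling_split(c(1, 2), c(1, 0, 1)), "entry per feature")
})

test_that("a single expert makes the gate irrelevant", {
  set.seed(11)
  lay <- new_moe_coupling_layer(4, n_experts = 1, n_heads = 2, embed_dim = 4,
                                gate_hidden = 6, init = "random")
  x <- matrix(rnorm(8), 2, 4)
  h1 <- moe_attention(x, lay)
  lay$params$W_g[] <- rnorm(length(lay$params$W_g))
  lay$params$b_g[] <- rnorm(length(lay$params$b_g))
  h2 <- moe_attention(x, lay)
  expect_equal(unclass(h1)[, ], unclass(h2)[, ])
})

test_that("zero gate pre-activations give uniform expert weights", {
  set.seed(12)
  lay <- new_moe_coupling_layer(4, n_experts = 3, n_heads = 2, embed_dim = 4,
                                gate_hidden = 6)
  lay$params$W_g[] <- 0
  lay$params$b_g[] <- 0
  g <- attr(moe_attention(matrix(rnorm(4), 1, 4), lay), "gate")
  expect_equal(drop(g), rep(1 / 3, 3))
})

test_that("gate weights are a probability vector for random inputs", {
  set.seed(13)
  lay <- new_moe_coupling_layer(6, n_experts = 4, n_heads = 2, embed_dim = 6,
                                gate_hidden = 8, init = "random")
  g <- attr(moe_attention(matrix(rnorm(30), 5, 6), lay), "gate")
  expect_true(all(g >= 0))
  expect_equal(rowSums(g), rep(1, 5))
})

test_that("zero scale/shift heads give the identity coupling", {
  set.seed(14)
  lay <- new_moe_coupling_layer(4, n_experts = 2, n_heads = 2, embed_dim = 4,
                                gate_hidden = 6, init = "identity")
  x <- matrix(rnorm(12), 3, 4)
  fw <- coupling_forward(x, lay)
  expect_equal(fw$z, x)
  expect_equal(fw$logdet, rep(0, 3))
})

test_that("a forced scale of 0.5 on two coordinates gives logdet 1", {
  set.seed(15)
  lay <- new_moe_coupling_layer(4, n_experts = 2, n_heads = 2, embed_dim = 4,
                                gate_hidden = 6)
  lay$params$W_s[] <- 0
  lay$params$b_s <- rep(atanh(0.5), 2)  # two transformed coordinates
  fw <- coupling_forward(matrix(rnorm(4), 1, 4), lay)
  expect_equal(fw$logdet, 1.0)
})

test_that("coupling logdet matches the finite-difference Jacobian", {
  set.seed(16)
  for (d in c(3, 5, 8)) {
    lay <- new_moe_coupling_layer(d, n_experts = 2, n_heads = 2, embed_dim = 4,
                                  gate_hidden = 6, init = "random")
    x <- rnorm(d)
    fw <- coupling_forward(x, lay)
    ld_fd <- fd_logdet(function(v) drop(coupling_forward(v, lay)$z), x)
    expect_lt(abs(fw$logdet - ld_fd), 1e-4)
  }
})

test_that("a-set passes through, tanh bounds the logdet, inverse round-trips", {
  set.seed(17)
  lay <- new_moe_coupling_layer(7, n_experts = 3, n_heads = 2, embed_dim = 6,
                                gate_hidden = 8, init = "random")
  x <- matrix(rnorm(100 * 7, sd = 2), 100, 7)
  fw <- coupling_forward(x, lay)
  expect_equal(fw$z[, lay$a_idx], x[, lay$a_idx])
  expect_true(all(abs(fw$logdet) <= length(lay$b_idx)))
  xr <- coupling_inverse(fw$z, lay)
  expect_lt(max(abs(xr - x)), 1e-5)
  # identity example inverted
  id <- new_moe_coupling_layer(4, n_experts = 2, n_heads = 2, embed_dim = 4,
                               gate_hidden = 6, init = "identity")
  z <- matrix(rnorm(4), 1, 4)
  expect_equal(coupling_inverse(z, id), z)
})

test_that("MOE-FB assembly validates its dimension and starts at identity", {
  expect_error(build_moefb(1), "d >= 2")
  set.seed(18)
  model <- build_moefb(4, hidden_features = 8, n_experts = 2, n_heads = 2,
                       embed_dim = 4, gate_hidden = 6, actnorm = FALSE)
  x <- matrix(rnorm(20), 5, 4)
  # identity blocks: log-density equals base log-density of the masked input
  xm <- context_mask_apply(x, model$context_mask)
  expect_equal(flow_log_density(x, model), base_log_density(xm))
})

test_that("the invertible MOE-FB stack round-trips (mask excluded)", {
  set.seed(19)
  model <- build_moefb(6, hidden_features = 8, n_experts = 2, n_heads = 2,
                       embed_dim = 4, gate_hidden = 6, context_mask = TRUE,
                       init = "random")
  for (i in seq_along(model$layers)) {
    if (inherits(model$layers[[i]], "actnorm_layer")) {
      model$layers[[i]]$params$s <- runif(6, 0.5, 2)
      model$layers[[i]]$params$b <- rnorm(6)
      model$layers[[i]]$initialized <- TRUE
    }
  }
  x <- matrix(rnorm(60), 10, 6)
  z <- flowsynth:::flow_forward(model, x)  # includes the mask
  # invert the stack only: recover the masked input, not x
  xm <- context_mask_apply(x, model$context_mask)
  xr <- flowsynth:::flow_inverse(model, z$z)
  expect_lt(max(abs(xr - xm)), 1e-5)
})
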