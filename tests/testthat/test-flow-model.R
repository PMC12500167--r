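test_that("base log-density matches the closed form", {
  expect_equal(base_log_density(0), -0.5 * log(2 * pi))
  expect_equal(round(base_log_density(0), 4), -0.9189)
  expect_equal(round(base_log_density(c(0, 0)), 4), -1.8379)
  expect_equal(round(base_log_density(1), 4), -1.4189)
})

test_that("identity flows reproduce the base density; constant scale shifts it", {
  model <- flow_model(list(constant_maf_layer(2)), 2)
  x <- matrix(rnorm(10), 5, 2)
  expect_equal(flow_log_density(x, model), base_log_density(x))

  scale2 <- flow_model(list(constant_maf_layer(1, alpha = log(2))), 1)
  expect_equal(flow_log_density(0, scale2), -0.5 * log(2 * pi) - log(2))
})

test_that("NLL is the negated mean log-density and is duplication-invariant", {
  model <- flow_model(list(constant_maf_layer(1)), 1)
  expect_equal(nll_loss(matrix(0), model), 0.5 * log(2 * pi))
  set.seed(20)
  b <- matrix(rnorm(8), 8, 1)
  expect_equal(nll_loss(rbind(b, b, b), model), nll_loss(b, model))
  expect_equal(nll_loss(b, model), mean(-flow_log_density(b, model)))
  expect_error(nll_loss(matrix(numeric(0), 0, 1), model), "non-empty")
})

test_that("sampling an identity flow returns base draws, deterministically", {
  model <- flow_model(list(constant_maf_layer(3)), 3)
  s1 <- sample_flow(model, 4000, seed = 21)
  s2 <- sample_flow(model, 4000, seed = 21)
  expect_identical(s1, s2)
  expect_true(all(abs(colMeans(s1)) < 4 / sqrt(4000)))
  expect_true(all(is.finite(flow_log_density(s1, model))))
})

test_that("analytic gradients agree with finite differences through all layers", {
  set.seed(22)
  d <- 4
  n <- 5
  x <- matrix(rnorm(n * d), n, d)
  model <- build_moefb(d, hidden_features = 6, n_experts = 2, n_heads = 2,
                       embed_dim = 4, gate_hidden = 5, mask_hidden = 5,
                       init = "random")
  for (i in seq_along(model$layers)) {
    if (inherits(model$layers[[i]], "actnorm_layer")) {
      model$layers[[i]]$params$s <- runif(d, 0.5, 2)
      model$layers[[i]]$params$b <- rnorm(d)
      model$layers[[i]]$initialized <- TRUE
    }
  }
  params <- flowsynth:::flow_params(model)
  theta <- unlist(params)
  nll_at <- function(th) {
    m <- flowsynth:::flow_set_params(model, utils::relist(th, params))
    nll_loss(x, m)
  }
  fw <- flowsynth:::flow_forward(model, x, keep_cache = TRUE)
  g <- unlist(flowsynth:::flow_backward(model, fw, fw$z / n, rep(-1 / n, n)))
  expect_length(g, length(theta))
  sel <- sample(length(theta), 120)
  h <- 1e-5
  for (i in sel) {
    tp <- theta; tp[i] <- tp[i] + h
    tm <- theta; tm[i] <- tm[i] - h
    gfd <- (nll_at(tp) - nll_at(tm)) / (2 * h)
    expect_lt(abs(g[i] - gfd) / max(1, abs(gfd)), 1e-5)
  }
})

test_that("checkpoints round-trip through disk", {
  set.seed(23)
  x <- matrix(rnorm(200), 100, 2)
  cfg <- train_config(model = "maf", hidden_features = 8, learning_rate = 0.01,
                      n_iterations = 3, seed = 1)
  fit <- train_flow(x, cfg)
  path <- tempfile(fileext = ".rds")
  save_flow(fit, path)
  fit2 <- load_flow(path)
  expect_equal(flow_log_density(x[1:5, ], fit2), flow_log_density(x[1:5, ], fit))
  saveRDS(list(schema = "other"), path)
  expect_error(load_flow(path), "schema")
})
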