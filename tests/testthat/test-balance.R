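test_that("Q3 plan reproduces the worked example exactly", {
  labels <- rep(c("A", "B", "C", "D"), times = c(100, 30, 10, 4))
  plan <- q3_plan(labels)
  expect_equal(attr(plan, "q3"), 48L)
  expect_equal(
    setNames(plan$target, plan$cell_type),
    c(A = 0L, B = 18L, C = 38L, D = 44L)
  )
})

test_that("equal class sizes need no synthesis", {
  plan <- q3_plan(rep(c("x", "y", "z"), each = 25))
  expect_equal(attr(plan, "q3"), 25L)
  expect_true(all(plan$target == 0L))
  expect_error(q3_plan(character(0)), "non-empty")
})

test_that("pooled counts hit max(observed, Q3) without overshoot", {
  set.seed(30)
  for (rep_ in 1:10) {
    counts <- sample(3:200, sample(3:8, 1))
    labels <- rep(paste0("c", seq_along(counts)), times = counts)
    plan <- q3_plan(labels)
    q3 <- attr(plan, "q3")
    pooled <- plan$observed + plan$target
    expect_equal(pooled, pmax(plan$observed, q3))
  }
})

test_that("per-type fitting honors the plan and isolates training rows", {
  set.seed(31)
  cfg_fix <- fixture_config(n_cells = 260, n_genes = 30, n_types = 3,
                            decay = 0.4, markers_per_type = 5, dropout = 0.2,
                            seed = 41)
  ds <- normalize_log(simulate_fixture(cfg_fix))
  plan <- q3_plan(ds$labels)
  expect_equal(sum(plan$target > 0), 2L)
  cfg <- train_config(model = "maf", hidden_features = 8,
                      learning_rate = 0.02, n_iterations = 10, seed = 5)
  models <- fit_per_type(ds, cfg, plan)
  expect_length(models, 2L)
  expect_setequal(names(models), plan$cell_type[plan$target > 0])
  for (lab in names(models)) {
    expect_setequal(models[[lab]]$train_rows, which(ds$labels == lab))
  }
})

test_that("per-type generated means track the type's training means", {
  set.seed(32)
  cfg_fix <- fixture_config(n_cells = 600, n_genes = 200, n_types = 3,
                            decay = 0.45, markers_per_type = 20,
                            marker_fold = 4, dropout = 0.3, seed = 42)
  ds <- normalize_log(simulate_fixture(cfg_fix))
  cfg <- train_config(model = "maf", hidden_features = 32,
                      learning_rate = 0.02, n_iterations = 40,
                      batch_size = 128, seed = 6)
  plan <- q3_plan(ds$labels)
  models <- fit_per_type(ds, cfg, plan)
  for (lab in names(models)) {
    train_mean <- colMeans(ds$matrix$values[ds$labels == lab, , drop = FALSE])
    gen <- sample_flow(models[[lab]], 300, seed = 8)
    expect_gt(cor(colMeans(gen), train_mean), 0.8)
  }
})

test_that("balanced generation delivers the exact per-label counts", {
  set.seed(33)
  labels <- rep(c("A", "B", "C", "D"), times = c(100, 30, 10, 4))
  plan <- q3_plan(labels)
  # simple stand-in flows: identity models at the right dimension
  mk <- function() flow_model(list(constant_maf_layer(5)), 5)
  models <- list(B = mk(), C = mk(), D = mk())
  out <- generate_balanced(models, plan, seed = 2)
  expect_equal(nrow(out$matrix$values), 100L)
  expect_equal(
    as.vector(table(out$labels)[c("B", "C", "D")]),
    c(18L, 38L, 44L)
  )
  out2 <- generate_balanced(models, plan, seed = 2)
  expect_identical(out$matrix$values, out2$matrix$values)
  expect_error(generate_balanced(models["B"], plan, seed = 2), "no model")
  # all-zero plan yields an empty dataset
  plan0 <- q3_plan(rep(c("A", "B"), each = 10))
  empty <- generate_balanced(list(), plan0, seed = 1)
  expect_equal(nrow(empty$matrix$values), 0L)
})

test_that("matched-size generation validates n and is seeded", {
  model <- flow_model(list(constant_maf_layer(3)), 3)
  expect_error(generate_matched(model, 0), "positive integer")
  g <- generate_matched(model, 500, seed = 4)
  expect_equal(dim(g), c(500L, 3L))
  expect_identical(g, generate_matched(model, 500, seed = 4))
})

test_that("proportional subsampling follows the largest-remainder rule", {
  ds1 <- labeled_dataset(
    count_matrix(matrix(0L, 10, 2)), rep(c("A", "B"), times = c(6, 4))
  )
  s1 <- proportional_subsample(ds1, 5, seed = 1)
  expect_equal(as.vector(table(s1$labels)[c("A", "B")]), c(3L, 2L))

  ds2 <- labeled_dataset(
    count_matrix(matrix(0L, 10, 2)), rep(c("A", "B", "C"), times = c(5, 3, 2))
  )
  s2 <- proportional_subsample(ds2, 6, seed = 1)
  expect_equal(as.vector(table(s2$labels)[c("A", "B", "C")]), c(3L, 2L, 1L))

  # n = total keeps the label multiset
  s3 <- proportional_subsample(ds2, 10, seed = 1)
  expect_equal(sort(s3$labels), sort(ds2$labels))
  expect_error(proportional_subsample(ds2, 11, seed = 1), "exceeds")
})

test_that("subsampling preserves proportions within 1/n", {
  set.seed(34)
  labels <- sample(paste0("t", 1:5), 800, replace = TRUE,
                   prob = c(0.4, 0.3, 0.15, 0.1, 0.05))
  ds <- labeled_dataset(count_matrix(matrix(0L, 800, 2)), labels)
  n <- 333
  s <- proportional_subsample(ds, n, seed = 3)
  p_full <- table(ds$labels) / 800
  p_sub <- table(factor(s$labels, names(p_full))) / n
  expect_lte(max(abs(p_sub - p_full)), 1 / n + 1e-12)
})
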