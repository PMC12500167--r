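test_that("correlation discrepancy: identity, antithetic pair, invariances", {
  set.seed(40)
  A <- matrix(rnorm(60), 20, 3)
  expect_equal(correlation_discrepancy(A, A), 0)
  # perfectly correlated vs perfectly anticorrelated 2-feature sets
  up <- cbind(1:10, 1:10)
  down <- cbind(1:10, 10:1)
  expect_equal(correlation_discrepancy(up, down), 1)
  B <- matrix(rnorm(60), 20, 3)
  expect_equal(correlation_discrepancy(A[sample(20), ], B),
               correlation_discrepancy(A, B))
  expect_equal(correlation_discrepancy(A, B), correlation_discrepancy(B, A))
  expect_error(correlation_discrepancy(A, B[, 1:2]), "share columns")
  w <- capture_warnings(correlation_discrepancy(cbind(A[, 1], 1), cbind(B[, 1], 1)))
  expect_true(length(w) > 0 && all(grepl("zero-variance", w)))
})

test_that("Wasserstein mean reproduces point-mass and shifted examples", {
  expect_equal(wasserstein_mean(matrix(0), matrix(1)), 1)
  expect_equal(wasserstein_mean(matrix(c(0, 1)), matrix(c(1, 2))), 1)
  A <- matrix(rnorm(30), 10, 3)
  expect_equal(wasserstein_mean(A, A), 0)
})

test_that("Wasserstein CDF sum agrees with the sorted-quantile oracle", {
  set.seed(41)
  for (rep_ in 1:10) {
    n <- sample(5:40, 1)
    A <- matrix(rnorm(n * 4, sd = runif(1, 0.5, 3)), n, 4)
    B <- matrix(rnorm(n * 4, mean = runif(1, -1, 1)), n, 4)
    oracle <- mean(vapply(1:4, function(j) {
      mean(abs(sort(A[, j]) - sort(B[, j])))
    }, numeric(1)))
    expect_lt(abs(wasserstein_mean(A, B) - oracle), 1e-10)
  }
})

test_that("MMD: exact zero on identical multisets and singleton closed form", {
  set.seed(42)
  A <- matrix(rnorm(40), 10, 4)
  expect_equal(mmd_rbf(A, A[sample(10), , drop = FALSE]), 0)
  delta <- 0.7
  l <- 0.5
  got <- mmd_rbf(matrix(0), matrix(delta), rbf_config(l))
  expect_equal(got, 2 - 2 * exp(-delta^2 / (2 * l^2)))
  # multi-scale value is the mean of the single-scale values
  scales <- c(0.005, 0.01, 0.1, 0.5, 1, 2)
  B <- matrix(rnorm(40, 1), 10, 4)
  singles <- vapply(scales, function(s) mmd_rbf(A, B, rbf_config(s)), numeric(1))
  expect_equal(mmd_rbf(A, B, rbf_config(scales)), mean(singles))
  expect_error(rbf_config(c(1, -1)), "positive")
  # symmetry
  expect_equal(mmd_rbf(A, B), mmd_rbf(B, A))
})

test_that("classification scores match the hand-computed binary case", {
  perfect <- classification_scores(c("a", "b", "a"), c("a", "b", "a"))
  expect_equal(unlist(perfect[, 1:4]),
               c(precision = 1, recall = 1, f1 = 1, accuracy = 1))
  # TP=8 FP=2 FN=2 TN=8 on the positive class, symmetric for the negative
  y_true <- rep(c("pos", "neg"), each = 10)
  y_pred <- c(rep("pos", 8), rep("neg", 2), rep("neg", 8), rep("pos", 2))
  sc <- classification_scores(y_true, y_pred)
  expect_equal(unlist(sc[, 1:4]),
               c(precision = 0.8, recall = 0.8, f1 = 0.8, accuracy = 0.8))
  expect_error(classification_scores(c("a"), c("a", "b")), "equal length")
})

test_that("a never-predicted class gets precision 0 and macro-F1 matches brute force", {
  y_true <- c("a", "a", "b", "c")
  y_pred <- c("a", "a", "b", "b")  # class c never predicted
  expect_message(sc <- classification_scores(y_true, y_pred), "never predicted")
  set.seed(43)
  for (rep_ in 1:10) {
    yt <- sample(letters[1:4], 60, replace = TRUE)
    yp <- sample(letters[1:4], 60, replace = TRUE)
    got <- suppressMessages(classification_scores(yt, yp))
    # brute-force one-vs-rest confusion-matrix oracle
    cls <- sort(union(yt, yp))
    f1s <- vapply(cls, function(cl) {
      tp <- sum(yt == cl & yp == cl)
      fp <- sum(yt != cl & yp == cl)
      fn <- sum(yt == cl & yp != cl)
      p <- if (tp + fp > 0) tp / (tp + fp) else 0
      r <- if (tp + fn > 0) tp / (tp + fn) else 0
      if (p + r > 0) 2 * p * r / (p + r) else 0
    }, numeric(1))
    expect_equal(got$f1, mean(f1s))
    expect_equal(got$accuracy, mean(yt == yp))
  }
})

test_that("batch silhouette separates mixed from split batches", {
  set.seed(44)
  mixed <- matrix(rnorm(200 * 5), 200, 5)
  b <- rep(c("b1", "b2"), 100)
  s_mixed <- batch_silhouette(mixed, b)
  expect_gt(s_mixed, 0.9)
  split <- rbind(matrix(rnorm(100 * 5, -100, 0.5), 100, 5),
                 matrix(rnorm(100 * 5, 100, 0.5), 100, 5))
  s_split <- batch_silhouette(split, rep(c("x", "y"), each = 100))
  expect_lt(s_split, 0.1)
  # invariant to renaming the batches
  expect_equal(batch_silhouette(mixed, ifelse(b == "b1", "zz", "aa")), s_mixed)
  expect_error(batch_silhouette(mixed, rep("one", 200)), ">= 2 batches")
  expect_error(batch_silhouette(mixed[1:3, ], c("a", "a", "b")), ">= 2 members")
})

test_that("RMSE closed forms, symmetry and keyed pairing", {
  expect_equal(rmse(c(1, 2), c(1, 2)), 0)
  expect_equal(rmse(c(0, 0), c(3, 4)), sqrt(12.5))
  set.seed(45)
  a <- rnorm(10); b <- rnorm(10)
  expect_equal(rmse(a, b), rmse(b, a))
  expect_error(rmse(1:3, 1:2), "identical shape")
  ta <- data.frame(pair = c("p1", "p2", "p3"), mean_expression = c(1, 2, 3))
  tb <- data.frame(pair = c("p2", "p3", "p4"), mean_expression = c(2, 5, 9))
  out <- rmse_paired(ta, tb, by = "pair")
  expect_equal(out$n_overlap, 2L)
  expect_equal(out$rmse, sqrt(mean(c(0, 4))))
  expect_error(rmse_paired(ta, data.frame(pair = "zz", mean_expression = 1),
                           by = "pair"), "overlap")
})

test_that("fidelity report carries values and metadata", {
  set.seed(46)
  A <- matrix(rnorm(100), 25, 4)
  B <- matrix(rnorm(100, 0.5), 25, 4)
  rep_ <- evaluate_fidelity(A, B, representation = "pc4")
  expect_setequal(rep_$metric, c("wd", "cd", "mmd"))
  expect_true(all(rep_$value >= 0))
  expect_equal(rep_$n_real[1], 25L)
  expect_equal(rep_$representation[1], "pc4")
  expect_s3_class(autoplot(rep_), "ggplot")
})
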