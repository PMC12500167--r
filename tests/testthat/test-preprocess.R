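test_that("qc_filter drops genes first, then cells, in a single pass", {
  vals <- rbind(
    c(5, 0, 2, 1),
    c(3, 0, 1, 1),
    c(0, 4, 0, 1),
    c(2, 0, 3, 0)
  )
  cm <- count_matrix(vals, genes = paste0("g", 1:4), cells = paste0("c", 1:4))
  # g2 expressed in 1 cell only -> dropped at min_cells = 2
  out <- qc_filter(cm, min_cells = 2, min_genes = 1)
  expect_false("g2" %in% out$genes)
  expect_equal(attr(out, "removed")[["genes"]], 1)
  # c3 expressed g2 (dropped) and g4: with min_genes = 2 it survives only if
  # counted AFTER the gene pass -> it has 1 remaining nonzero gene -> dropped
  out2 <- qc_filter(cm, min_cells = 2, min_genes = 2)
  expect_false("c3" %in% out2$cells)
  # zero thresholds are the identity
  out0 <- qc_filter(cm, min_cells = 0, min_genes = 0)
  expect_equal(out0$values, cm$values)
  expect_error(qc_filter(cm, min_cells = 5, min_genes = 1), "every gene")
})

test_that("rare classes are removed with their cells and reported", {
  ds <- labeled_dataset(count_matrix(matrix(0L, 21, 2)),
                        rep(c("A", "B"), times = c(12, 9)))
  out <- drop_rare_classes(ds, min_count = 10)
  expect_equal(unique(out$labels), "A")
  expect_equal(nrow(out$matrix$values), 12)
  expect_equal(as.vector(attr(out, "removed")), 9)
  expect_equal(drop_rare_classes(ds, min_count = 0)$labels, ds$labels)
  expect_error(drop_rare_classes(ds, min_count = 100), "every class")
})

test_that("normalization matches the closed form and factor properties", {
  cm <- count_matrix(rbind(c(1, 1), c(1, 1)), layer = "counts")
  out <- normalize_log(cm)
  expect_equal(out$layer, "lognorm")
  expect_equal(as.vector(out$values), rep(log1p(1), 4))
  expect_equal(as.vector(attr(out, "size_factors")), c(1, 1))
  # doubling every count doubles every size factor exactly
  cm2 <- count_matrix(rbind(c(4, 2), c(1, 1)))
  f1 <- attr(normalize_log(cm2), "size_factors")
  cm3 <- count_matrix(2 * cm2$values)
  f2 <- attr(normalize_log(cm3), "size_factors")
  expect_equal(f2, f1 * 1)  # factors are scale-invariant ratios of libraries
  expect_equal(as.vector(f1), c(6, 2) / median(c(6, 2)))
  # zero-library cell removed with warning
  cm4 <- count_matrix(rbind(c(0, 0), c(1, 2), c(2, 1)))
  expect_warning(out4 <- normalize_log(cm4), "zero library")
  expect_equal(nrow(out4$values), 2)
})

test_that("HVG selection ranks by variance with deterministic ties", {
  vals <- cbind(c(0, 2, 4), c(1, 1.5, 2), c(0, 1.4, 2.8))
  cm <- count_matrix(vals, genes = c("g1", "g2", "g3"), layer = "lognorm")
  expect_equal(sort(select_hvg(cm, 2)), c(1, 3))
  # constant gene ranks last
  vals2 <- cbind(c(1, 1, 1), c(0, 1, 2))
  cm2 <- count_matrix(vals2, genes = c("flat", "varying"), layer = "lognorm")
  expect_equal(select_hvg(cm2, 1), 2)
  expect_warning(idx <- select_hvg(cm2, 5), "exceeds")
  expect_length(idx, 2)
})

test_that("the pipeline runs the steps in order and logs shapes", {
  set.seed(53)
  ds <- simulate_fixture(fixture_config(n_cells = 300, n_genes = 60,
                                        n_types = 3, decay = 0.5,
                                        markers_per_type = 5, dropout = 0.2,
                                        seed = 60))
  out <- preprocess_pipeline(ds, min_class = 10, min_cells = 5,
                             min_genes = 5, n_hvg = 40)
  expect_equal(out$matrix$layer, "lognorm")
  expect_equal(ncol(out$matrix$values), 40)
  log <- attr(out, "log")
  expect_equal(log$step,
               c("input", "drop_rare_classes", "qc_filter", "normalize_log",
                 "select_hvg"))
  expect_true(all(diff(log$genes) <= 0))
})

test_that("the simulator is seeded, imbalanced and marker-shifted", {
  cfg <- fixture_config(n_cells = 2000, n_genes = 100, n_types = 4,
                        markers_per_type = 10, marker_fold = 4,
                        dropout = 0.3, seed = 77)
  d1 <- simulate_fixture(cfg)
  d2 <- simulate_fixture(cfg)
  expect_identical(d1$matrix$values, d2$matrix$values)
  expect_identical(d1$labels, d2$labels)
  # empirical class proportions near the geometric scheme
  p_hat <- as.vector(table(factor(d1$labels, paste0("type_", 1:4)))) / 2000
  expect_lt(max(abs(p_hat - attr(d1, "proportions"))), 1 / sqrt(2000) * 3)
  # markers of each type are up-shifted within that type
  markers <- attr(d1, "marker_sets")
  for (t in 1:4) {
    own <- colMeans(d1$matrix$values[d1$labels == paste0("type_", t),
                                     markers[[t]], drop = FALSE])
    other <- colMeans(d1$matrix$values[d1$labels != paste0("type_", t),
                                       markers[[t]], drop = FALSE])
    expect_gt(mean(own > other), 0.95)
  }
})

test_that("batch structure reaches the labels and the silhouette metric", {
  cfg <- fixture_config(n_cells = 200, n_genes = 40, n_types = 2,
                        markers_per_type = 5, n_batches = 2, batch_sd = 0.1,
                        seed = 78)
  ds <- simulate_fixture(cfg)
  expect_false(is.null(ds$batch))
  expect_setequal(unique(ds$batch), c("batch_1", "batch_2"))
  ln <- normalize_log(ds)
  s <- batch_silhouette(ln$matrix$values, ln$batch)
  expect_true(s >= 0 && s <= 1)
})
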