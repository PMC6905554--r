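test_that("differential expression matches a direct Welch t-test", {
  expr <- expression_matrix(
    rbind(g1 = c(8, 9, 10, 2, 3, 4)),
    condition = c("disease", "disease", "disease",
                  "healthy", "healthy", "healthy"))
  de <- differential_expression(expr)
  expect_equal(de$log_fc, 6)
  ref <- t.test(c(8, 9, 10), c(2, 3, 4))
  expect_equal(de$p_raw, ref$p.value)
})

test_that("null genes get zero logFC and p = 1 when exactly constant", {
  expr <- expression_matrix(
    rbind(flat = rep(5, 8), shifted = rep(c(1, 3), each = 4)),
    condition = rep(c("disease", "healthy"), each = 4))
  de <- differential_expression(expr)
  expect_equal(de$log_fc[de$gene_id == "flat"], 0)
  expect_equal(de$p_raw[de$gene_id == "flat"], 1)
  # constant groups with different means: the difference is exact
  expect_equal(de$p_raw[de$gene_id == "shifted"], 0)
})

test_that("BH adjustment reproduces the hand step-up and its invariants", {
  p <- c(0.01, 0.02, 0.03, 0.04)
  expr <- tiny_expression()
  de <- differential_expression(expr)
  # p_adj computed via stats::p.adjust: monotone and >= raw
  expect_true(all(de$p_adj >= de$p_raw - 1e-15))
  ord <- order(de$p_raw)
  expect_true(all(diff(de$p_adj[ord]) >= -1e-15))
  expect_equal(p.adjust(p, "BH"), rep(0.04, 4))
})

test_that("positive labeling uses strict two-sided thresholds", {
  de <- data.frame(
    gene_id = c("up", "down", "boundary_lfc", "boundary_p", "null"),
    log_fc = c(1.5, -1.2, 1.0, 2.0, 0.1),
    p_raw = c(0.001, 0.003, 0.001, 0.01, 0.5),
    p_adj = c(0.01, 0.03, 0.01, 0.05, 0.9))
  feats <- matrix(0, 5, 4, dimnames = list(de$gene_id, NULL))
  expr <- list(gene_ids = de$gene_id, values = feats)
  bench <- select_positive_unlabeled(de, expr)
  expect_setequal(bench$positives, c("up", "down"))
  expect_setequal(bench$unlabeled, c("boundary_lfc", "boundary_p", "null"))
  # partition property: union is everything, intersection empty
  expect_setequal(c(bench$positives, bench$unlabeled), de$gene_id)
  expect_length(intersect(bench$positives, bench$unlabeled), 0)
})

test_that("the unlabeled cap keeps the least differential genes", {
  de <- data.frame(gene_id = paste0("g", 1:6),
                   log_fc = c(3, -0.1, 0.5, 0.2, -0.9, 0.05),
                   p_raw = rep(0.001, 6), p_adj = rep(0.01, 6))
  feats <- matrix(0, 6, 2, dimnames = list(de$gene_id, NULL))
  bench <- select_positive_unlabeled(de, list(gene_ids = de$gene_id,
                                              values = feats),
                                     max_unlabeled = 3)
  expect_equal(bench$positives, "g1")
  expect_setequal(bench$unlabeled, c("g2", "g4", "g6"))
})

test_that("empty positive sets warn and downstream training refuses", {
  de <- data.frame(gene_id = c("a", "b"), log_fc = c(0, 0.2),
                   p_raw = c(0.9, 0.8), p_adj = c(0.9, 0.9))
  feats <- matrix(0, 2, 3, dimnames = list(de$gene_id, NULL))
  expect_warning(
    bench <- select_positive_unlabeled(de, list(gene_ids = de$gene_id,
                                                values = feats)),
    "empty positive")
  expect_error(run_ocsvm_experiment(bench), "no positive")
})

test_that("outlier screening removes planted rows, keeps clean data", {
  set.seed(9)
  feats <- matrix(rnorm(50 * 4), 50, 4,
                  dimnames = list(paste0("g", 1:50), NULL))
  feats["g7", 2] <- feats["g7", 2] + 100   # ~100 MADs out
  screened <- remove_outliers(feats, z_threshold = 4)
  expect_true("g7" %in% screened$removed)
  expect_false("g7" %in% rownames(screened$features))
  # homogeneous gaussian rows: at most a few percent removed
  clean <- matrix(rnorm(200 * 4), 200, 4,
                  dimnames = list(paste0("c", 1:200), NULL))
  expect_gte(nrow(remove_outliers(clean, 4)$features) / 200, 0.97)
  # zero-spread features must not divide by zero or remove anything
  const <- matrix(1, 5, 3, dimnames = list(paste0("k", 1:5), NULL))
  expect_length(remove_outliers(const, 4)$removed, 0)
})

test_that("min-max scaling follows the formula and avoids leakage", {
  sc <- minmax_scale(matrix(c(2, 4, 6), 3))
  expect_equal(drop(sc$train), c(0, 0.5, 1))
  # constant feature maps to 0
  expect_equal(drop(minmax_scale(matrix(c(5, 5), 2))$train), c(0, 0))
  # identity on already-scaled input
  expect_equal(drop(minmax_scale(matrix(c(0, 1), 2))$train), c(0, 1))
  # test matrices use training parameters and clip to [0, 1]
  sc2 <- minmax_scale(matrix(c(2, 4, 6), 3), matrix(c(0, 8), 2))
  expect_equal(drop(sc2[[2]]), c(0, 1))
  # idempotence: rescaling the scaled training matrix is the identity
  tr <- matrix(rnorm(20), 10, 2)
  once <- minmax_scale(tr)$train
  twice <- minmax_scale(once)$train
  expect_equal(twice, once, tolerance = 1e-12)
})

test_that("train/test splits are seed-reproducible and exhaustive", {
  bench <- separable_benchmark(n_pos = 100, n_unl = 50)
  s1 <- split_train_test(bench, 0.7, seed = 11)
  s2 <- split_train_test(bench, 0.7, seed = 11)
  expect_identical(s1, s2)
  expect_length(s1$train_positives, 70)
  expect_length(s1$test_positives, 30)
  expect_setequal(c(s1$train_positives, s1$test_positives),
                  bench$positives)
  # unlabeled genes never reach training
  expect_length(intersect(s1$train_positives, bench$unlabeled), 0)
  expect_setequal(s1$test_unlabeled, bench$unlabeled)
  # different seeds give different partitions (overwhelmingly)
  diffs <- vapply(1:10, function(s) {
    !setequal(split_train_test(bench, 0.7, seed = 100 + s)$train_positives,
              s1$train_positives)
  }, logical(1))
  expect_true(all(diffs))
})

test_that("cross-validation partitions every gene exactly once", {
  feats <- separable_benchmark(n_pos = 45, n_unl = 10)$features[1:45, ]
  cv <- cross_validate(feats, kernel = "linear", nu = 0.1, folds = 5,
                       seed = 3)
  expect_length(cv$fold_recall, 5)
  expect_equal(sort(unique(cv$assignments)), 1:5)
  expect_equal(tabulate(cv$assignments), rep(9, 5))
  # clean, well-separated data: mean CV recall >= 1 - nu - eps
  expect_gte(cv$mean, 1 - 0.1 - 0.1)
  expect_error(cross_validate(feats, folds = 46), "folds")
})
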