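# End-to-end experiment drivers tying the stages together: the one-class
# 70/30 protocol, the one-class vs binary-baseline comparison on shared
# pools, and the runner for benchmarks stored in the two-file
# supplementary layout.

#' Run the 70/30 one-class experiment on a benchmark
#'
#' Splits the positive genes into training and held-out fractions, screens
#' training outliers, min-max scales (parameters from the training
#' positives unless `scale_all`), fits the one-class SVM on the training
#' positives only, and evaluates on the pool of held-out positives plus
#' all unlabeled genes. Precision is estimated in positive-unlabeled mode
#' (Bayes inversion with the pool's known-positive fraction as prior);
#' `naive` metrics treating unlabeled test genes as negatives are reported
#' alongside.
#'
#' @param benchmark A `pu_benchmark`.
#' @param kernel,nu,gamma Model settings, as in [ocsvm()].
#' @param train_fraction Positive-split fraction (default 0.7).
#' @param seed Seed controlling the split.
#' @param outlier_z Robust-z threshold for training-outlier removal;
#'   `NULL` disables the screen.
#' @param scale_all If `TRUE`, min-max parameters come from all benchmark
#'   genes rather than the training positives (the global-scaling
#'   compatibility mode).
#' @param cv_folds If non-`NULL`, also run k-fold cross-validated recall
#'   on the training positives.
#' @return List with `model`, `metrics` (a [pu_metrics()]), `naive`
#'   (classical metrics with unlabeled treated as negative), `candidates`
#'   (unlabeled genes predicted inlier), `pred`, `split`, `cv`, and
#'   `removed_outliers`.
#' @export
run_ocsvm_experiment <- function(benchmark, kernel = "linear", nu = 0.05,
                                 gamma = NULL, train_fraction = 0.7,
                                 seed = 1L, outlier_z = 4,
                                 scale_all = FALSE, cv_folds = NULL) {
  stopifnot(inherits(benchmark, "pu_benchmark"))
  if (length(benchmark$positives) == 0L) {
    stop("refusing to train: the benchmark has no positive genes",
         call. = FALSE)
  }
  split <- split_train_test(benchmark, train_fraction, seed = seed)
  feats <- benchmark$features
  train_f <- feats[split$train_positives, , drop = FALSE]

  removed <- character(0)
  if (!is.null(outlier_z) && nrow(train_f) >= 3L) {
    screened <- remove_outliers(train_f, z_threshold = outlier_z)
    train_f <- screened$features
    removed <- screened$removed
  }

  test_ids <- c(split$test_positives, split$test_unlabeled)
  test_f <- feats[test_ids, , drop = FALSE]
  scaled <- if (scale_all) {
    s <- minmax_scale(feats, train_f, test_f)
    list(train = s[[2]], test = s[[3]])
  } else {
    s <- minmax_scale(train_f, test_f)
    list(train = s$train, test = s[[2]])
  }

  model <- ocsvm(scaled$train, kernel = kernel, nu = nu, gamma = gamma)
  pred <- predict(model, scaled$test)
  names(pred) <- test_ids

  prior <- length(split$test_positives) / length(test_ids)
  r <- estimate_recall(pred[split$test_positives])
  rate <- estimate_positive_rate(pred)
  metrics <- if (rate > 0) pu_metrics(r, rate, prior) else NULL

  naive_truth <- c(rep("positive", length(split$test_positives)),
                   rep("negative", length(split$test_unlabeled)))
  naive <- classical_metrics(confusion_from_labels(naive_truth, pred))

  cv <- if (!is.null(cv_folds)) {
    cross_validate(scaled$train, kernel = kernel, nu = nu, gamma = gamma,
                   folds = cv_folds, seed = seed)
  }

  list(model = model, metrics = metrics, naive = naive,
       candidates = split$test_unlabeled[
         pred[split$test_unlabeled] == "inlier"],
       pred = pred, split = split, cv = cv,
       removed_outliers = removed)
}

#' Compare the one-class model against balanced binary baselines
#'
#' Runs the 70/30 one-class experiment, then trains each requested binary
#' baseline on the same training positives plus an equal-size
#' pseudo-negative sample of unlabeled genes, and scores every method on
#' the identical test pool (held-out positives plus the unlabeled genes
#' not consumed as pseudo-negatives) through the identical metric
#' functions.
#'
#' @param benchmark A `pu_benchmark`.
#' @param methods Baseline methods to run (see [baseline_config()]).
#' @param kernel,nu,gamma One-class model settings.
#' @param train_fraction,seed,outlier_z,scale_all As in
#'   [run_ocsvm_experiment()].
#' @param extra_rows Optional named list of externally supplied metric
#'   rows (e.g. published numbers) appended to the comparison table.
#' @return List with `ocsvm` (full experiment output), `baselines` (per
#'   method), `table` (the rendered comparison), and `test_pool`.
#' @export
run_comparison_experiment <- function(benchmark,
                                      methods = c("svm_binary", "knn",
                                                  "decision_tree"),
                                      kernel = "linear", nu = 0.05,
                                      gamma = NULL, train_fraction = 0.7,
                                      seed = 1L, outlier_z = 4,
                                      scale_all = FALSE,
                                      extra_rows = NULL) {
  split <- split_train_test(benchmark, train_fraction, seed = seed)
  balanced <- make_balanced_binary(
    pu_benchmark(split$train_positives,
                 benchmark$unlabeled,
                 benchmark$features), seed = seed + 1L)
  # the shared test pool excludes pseudo-negatives consumed in training
  test_unlabeled <- setdiff(benchmark$unlabeled,
                            balanced$pseudo_negatives)
  shared <- pu_benchmark(benchmark$positives, test_unlabeled,
                         benchmark$features)

  # one-class run on the shared pool, re-using the same positive split
  oc <- run_ocsvm_experiment_fixed_split(
    shared, split, kernel = kernel, nu = nu, gamma = gamma,
    outlier_z = outlier_z, scale_all = scale_all)

  feats <- benchmark$features
  train_ids <- c(split$train_positives, balanced$pseudo_negatives)
  train_labels <- c(rep("positive", length(split$train_positives)),
                    rep("negative", length(balanced$pseudo_negatives)))
  test_ids <- c(split$test_positives, test_unlabeled)
  test_labels <- c(rep("positive", length(split$test_positives)),
                   rep("unlabeled", length(test_unlabeled)))
  sc <- minmax_scale(feats[train_ids, , drop = FALSE],
                     feats[test_ids, , drop = FALSE])
  prior <- length(split$test_positives) / length(test_ids)

  baselines <- lapply(stats::setNames(methods, methods), function(m) {
    run_baseline(baseline_config(m, seed = seed + 2L),
                 sc$train, train_labels, sc[[2]], test_labels,
                 class_prior = prior)
  })

  rows <- c(list(OCSVM = oc$metrics),
            lapply(baselines, function(b) b$pu %||% b),
            extra_rows)
  list(ocsvm = oc, baselines = baselines,
       table = compare_methods(rows),
       test_pool = list(ids = test_ids, labels = test_labels))
}

# identical to run_ocsvm_experiment but on a pre-computed positive split,
# so the comparison harness can share one split across methods
run_ocsvm_experiment_fixed_split <- function(benchmark, split,
                                             kernel = "linear", nu = 0.05,
                                             gamma = NULL, outlier_z = 4,
                                             scale_all = FALSE) {
  feats <- benchmark$features
  train_f <- feats[split$train_positives, , drop = FALSE]
  removed <- character(0)
  if (!is.null(outlier_z) && nrow(train_f) >= 3L) {
    screened <- remove_outliers(train_f, z_threshold = outlier_z)
    train_f <- screened$features
    removed <- screened$removed
  }
  test_ids <- c(split$test_positives, benchmark$unlabeled)
  test_f <- feats[test_ids, , drop = FALSE]
  scaled <- if (scale_all) {
    s <- minmax_scale(feats, train_f, test_f)
    list(train = s[[2]], test = s[[3]])
  } else {
    s <- minmax_scale(train_f, test_f)
    list(train = s$train, test = s[[2]])
  }
  model <- ocsvm(scaled$train, kernel = kernel, nu = nu, gamma = gamma)
  pred <- predict(model, scaled$test)
  names(pred) <- test_ids
  prior <- length(split$test_positives) / length(test_ids)
  r <- estimate_recall(pred[split$test_positives])
  rate <- estimate_positive_rate(pred)
  naive_truth <- c(rep("positive", length(split$test_positives)),
                   rep("negative", length(benchmark$unlabeled)))
  list(model = model,
       metrics = if (rate > 0) pu_metrics(r, rate, prior) else NULL,
       naive = classical_metrics(confusion_from_labels(naive_truth, pred)),
       candidates = benchmark$unlabeled[
         pred[benchmark$unlabeled] == "inlier"],
       pred = pred, split = split, cv = NULL,
       removed_outliers = removed)
}

#' Run the one-class experiment on a supplementary-layout benchmark
#'
#' Loads a benchmark stored as a positives CSV plus a complete-matrix CSV
#' (the layout of the AML study's supplementary files), repeats the 70/30
#' one-class experiment over several seeds, and reports per-seed and mean
#' positive-unlabeled metrics together with the benchmark's counts.
#'
#' @param positives_path,full_path,condition As in [read_benchmark()].
#' @param kernel,nu,gamma,train_fraction,outlier_z,scale_all As in
#'   [run_ocsvm_experiment()].
#' @param seeds Integer vector of split seeds to average over.
#' @return List with `counts` (positives, unlabeled, disease and healthy
#'   samples), `per_seed` (data frame of percentage metrics), and `mean`
#'   (mean precision/recall/F percentages).
#' @export
run_benchmark_experiment <- function(positives_path, full_path,
                                 condition = NULL, kernel = "linear",
                                 nu = 0.05, gamma = NULL,
                                 train_fraction = 0.7, outlier_z = 4,
                                 scale_all = FALSE, seeds = 1:10) {
  loaded <- read_benchmark(positives_path, full_path,
                           condition = condition)
  bench <- loaded$benchmark
  counts <- list(
    n_positive = length(bench$positives),
    n_unlabeled = length(bench$unlabeled),
    n_disease_samples = sum(loaded$expr$condition == "disease"),
    n_healthy_samples = sum(loaded$expr$condition == "healthy"))
  per_seed <- do.call(rbind, lapply(seeds, function(s) {
    res <- run_ocsvm_experiment(bench, kernel = kernel, nu = nu,
                                gamma = gamma,
                                train_fraction = train_fraction,
                                seed = s, outlier_z = outlier_z,
                                scale_all = scale_all)
    m <- res$metrics
    data.frame(seed = s,
               precision = 100 * m$precision_hat,
               recall = 100 * m$recall_hat,
               f_measure = 100 * m$f_measure)
  }))
  list(counts = counts, per_seed = per_seed,
       mean = colMeans(per_seed[, c("precision", "recall", "f_measure")]))
}
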