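# Balanced binary-classifier baselines: the conventional treatment of
# this problem labels unlabeled genes as negatives, balances |P| = |N| by
# subsampling, and trains a two-class model. They are scored through the
# same metric functions as the one-class model so the comparison isolates
# the classification paradigm, not the bookkeeping.

#' Sample a balanced pseudo-negative set from the unlabeled genes
#'
#' @param benchmark A `pu_benchmark`.
#' @param seed Integer seed for the subsample.
#' @return List with `positives` and `pseudo_negatives` (gene id vectors
#'   of equal length).
#' @export
make_balanced_binary <- function(benchmark, seed = 1L) {
  stopifnot(inherits(benchmark, "pu_benchmark"))
  n_pos <- length(benchmark$positives)
  if (length(benchmark$unlabeled) < n_pos) {
    stop(sprintf(
      "cannot balance: %d unlabeled genes available for %d positives",
      length(benchmark$unlabeled), n_pos), call. = FALSE)
  }
  neg <- with_seed(seed, sample(benchmark$unlabeled, n_pos))
  list(positives = benchmark$positives, pseudo_negatives = neg)
}

#' Configuration of one binary-classifier baseline
#'
#' @param method `"svm_binary"` (RBF support vector machine),
#'   `"knn"` (k-nearest neighbours), or `"decision_tree"`.
#' @param hyperparameters Named list; recognized entries are `cost` and
#'   `gamma` for the SVM (defaults 1 and 1/d), `k` for KNN (default 5),
#'   and `minsplit`/`cp` for the tree (rpart defaults, i.e. effectively
#'   unlimited depth at benchmark scale).
#' @param seed Seed used for any sampling inside the baseline.
#' @return A `baseline_config` list.
#' @export
baseline_config <- function(method = c("svm_binary", "knn",
                                       "decision_tree"),
                            hyperparameters = list(), seed = 1L) {
  method <- match.arg(method)
  structure(list(method = method, hyperparameters = hyperparameters,
                 seed = as.integer(seed)),
            class = "baseline_config")
}

#' Train and evaluate one binary baseline on shared train/test pools
#'
#' Trains the configured two-class classifier on balanced
#' positive/pseudo-negative training features, predicts on the shared test
#' pool, and reports both classical confusion-matrix metrics (treating
#' pseudo-negative test labels as negatives) and, when `class_prior` is
#' given, the positive-unlabeled estimates through the same code path as
#' the one-class model.
#'
#' @param config A [baseline_config()].
#' @param train_features,train_labels Balanced training data; labels are
#'   `"positive"`/`"negative"`.
#' @param test_features,test_labels Shared test pool; labels may include
#'   `"unlabeled"`.
#' @param class_prior Optional true-positive fraction of the test pool for
#'   the PU estimates.
#' @return List with `pred` (named label vector on the test pool),
#'   `confusion`, `precision`, `recall`, `f_measure` (classical, `NA` when
#'   not computable) and `pu` (a [pu_metrics()] or `NULL`).
#' @export
run_baseline <- function(config, train_features, train_labels,
                         test_features, test_labels,
                         class_prior = NULL) {
  stopifnot(inherits(config, "baseline_config"))
  train_features <- as.matrix(train_features)
  test_features <- as.matrix(test_features)
  train_labels <- factor(train_labels, levels = c("negative", "positive"))
  hp <- config$hyperparameters
  pred <- with_seed(config$seed, switch(
    config$method,
    svm_binary = {
      fit <- e1071::svm(
        train_features, train_labels, kernel = "radial",
        cost = hp$cost %||% 1,
        gamma = hp$gamma %||% (1 / ncol(train_features)), scale = FALSE)
      as.character(predict(fit, test_features))
    },
    knn = as.character(class::knn(train_features, test_features,
                                  train_labels, k = hp$k %||% 5L)),
    decision_tree = {
      df <- data.frame(.y = train_labels, train_features,
                       check.names = FALSE)
      fit <- rpart::rpart(
        .y ~ ., data = df, method = "class",
        control = rpart::rpart.control(minsplit = hp$minsplit %||% 20L,
                                       cp = hp$cp %||% 0.01))
      as.character(predict(fit,
                           data.frame(test_features, check.names = FALSE),
                           type = "class"))
    },
    stop("unknown baseline method: ", config$method, call. = FALSE)))
  names(pred) <- rownames(test_features)

  conf <- confusion_from_labels(test_labels, pred)
  classical <- classical_metrics(conf)
  pu <- NULL
  if (!is.null(class_prior)) {
    r <- estimate_recall(pred[test_labels == "positive"])
    rate <- estimate_positive_rate(pred)
    if (rate > 0) pu <- pu_metrics(r, rate, class_prior)
  }
  c(list(pred = pred, confusion = conf, pu = pu), classical)
}

classical_metrics <- function(conf) {
  p <- if (!is.na(conf$fp) && conf$tp + conf$fp > 0) {
    conf$tp / (conf$tp + conf$fp)
  } else NA_real_
  r <- if (conf$tp + conf$fn > 0) conf$tp / (conf$tp + conf$fn) else
    NA_real_
  list(precision = p, recall = r,
       f_measure = if (!is.na(p) && !is.na(r)) f_measure(p, r) else
         NA_real_)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Render a method comparison table
#'
#' Formats named metric sets as a method x (precision, recall, F-measure)
#' table, percentages with two decimals, rows in input order. Rows may be
#' `pu_metrics` objects, lists with `precision`/`recall`/`f_measure`
#' fields, or externally supplied numbers (e.g. published results being
#' juxtaposed); missing cells render as `NA`.
#'
#' @param results Named list of result rows.
#' @return A data frame with character columns `method`, `precision`,
#'   `recall`, `f_measure` (formatted percentages).
#' @export
compare_methods <- function(results) {
  if (length(results) < 2L) {
    stop("a comparison needs at least 2 result rows", call. = FALSE)
  }
  row_of <- function(x) {
    if (inherits(x, "pu_metrics")) {
      c(x$precision_hat, x$recall_hat, x$f_measure)
    } else {
      c(x$precision %||% NA_real_, x$recall %||% NA_real_,
        x$f_measure %||% NA_real_)
    }
  }
  m <- t(vapply(results, row_of, numeric(3)))
  data.frame(method = names(results),
             precision = format_pct(m[, 1]),
             recall = format_pct(m[, 2]),
             f_measure = format_pct(m[, 3]),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Write a comparison table as TSV and JSON
#'
#' @param table Output of [compare_methods()].
#' @param path Base path; `<path>.tsv` and `<path>.json` are written.
#' @return Invisibly, the file paths.
#' @export
write_comparison <- function(table, path) {
  tsv <- paste0(path, ".tsv")
  utils::write.table(table, tsv, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  jsn <- paste0(path, ".json")
  jsonlite::write_json(table, jsn, auto_unbox = TRUE, digits = NA)
  invisible(c(tsv, jsn))
}
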