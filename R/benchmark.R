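#' Construct a condition-labelled expression matrix
#'
#' The container the whole pipeline operates on: a genes x samples matrix
#' of (typically log2-scale) expression values with a disease/healthy
#' label per sample. Each gene's row doubles as its feature vector, one
#' feature per sample.
#'
#' @param values Numeric matrix, genes in rows, samples in columns.
#' @param gene_ids Unique gene identifiers (default: rownames).
#' @param sample_ids Sample identifiers (default: colnames).
#' @param condition Per-sample labels, each `"disease"` or `"healthy"`.
#' @return An `expression_matrix` object.
#' @export
expression_matrix <- function(values, gene_ids = rownames(values),
                              sample_ids = colnames(values), condition) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (any(!is.finite(values))) {
    stop("expression values must be finite", call. = FALSE)
  }
  if (is.null(gene_ids)) gene_ids <- paste0("gene_", seq_len(nrow(values)))
  if (is.null(sample_ids)) {
    sample_ids <- paste0("sample_", seq_len(ncol(values)))
  }
  gene_ids <- as.character(gene_ids)
  sample_ids <- as.character(sample_ids)
  if (anyDuplicated(gene_ids)) {
    stop("duplicate gene identifiers: ",
         paste(utils::head(gene_ids[duplicated(gene_ids)], 3),
               collapse = ", "), call. = FALSE)
  }
  condition <- as.character(condition)
  if (length(condition) != ncol(values)) {
    stop(sprintf("%d condition labels for %d samples",
                 length(condition), ncol(values)), call. = FALSE)
  }
  if (!all(condition %in% c("disease", "healthy"))) {
    stop("condition labels must be 'disease' or 'healthy'", call. = FALSE)
  }
  rownames(values) <- gene_ids
  colnames(values) <- sample_ids
  structure(list(values = values, gene_ids = gene_ids,
                 sample_ids = sample_ids, condition = condition),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf(
    "Expression matrix: %d genes x %d samples (%d disease, %d healthy)\n",
    nrow(x$values), ncol(x$values), sum(x$condition == "disease"),
    sum(x$condition == "healthy")))
  invisible(x)
}

#' Per-gene differential expression between disease and healthy samples
#'
#' For each gene: log2 fold change as the difference of group means on the
#' log2 scale (disease minus healthy), a raw p-value from Welch's
#' two-sample t-test, and a Benjamini-Hochberg adjusted p-value across all
#' genes. If both groups are constant, the p-value is 1 when the means
#' agree and 0 when they differ (the difference is then exact).
#'
#' @param expr An [expression_matrix()].
#' @param values_are_log Set `FALSE` for raw-intensity input, which is
#'   then log2-transformed (after flooring at 1) before testing.
#' @return A data frame with columns `gene_id`, `log_fc`, `p_raw`, `p_adj`.
#' @export
differential_expression <- function(expr, values_are_log = TRUE) {
  stopifnot(inherits(expr, "expression_matrix"))
  is_dis <- expr$condition == "disease"
  if (sum(is_dis) < 2L || sum(!is_dis) < 2L) {
    stop(sprintf(
      "need at least 2 samples per condition for the t-test (%d disease, %d healthy)",
      sum(is_dis), sum(!is_dis)), call. = FALSE)
  }
  v <- expr$values
  if (!values_are_log) v <- log2(pmax(v, 1))
  d <- v[, is_dis, drop = FALSE]
  h <- v[, !is_dis, drop = FALSE]
  log_fc <- rowMeans(d) - rowMeans(h)
  p_raw <- vapply(seq_len(nrow(v)), function(i) {
    tryCatch(stats::t.test(d[i, ], h[i, ])$p.value,
             error = function(e) if (abs(log_fc[i]) < 1e-12) 1 else 0)
  }, numeric(1))
  data.frame(gene_id = expr$gene_ids, log_fc = unname(log_fc),
             p_raw = p_raw, p_adj = stats::p.adjust(p_raw, method = "BH"),
             stringsAsFactors = FALSE)
}

#' Split genes into positive and unlabeled sets by DE thresholds
#'
#' A gene is positive when its log fold change is strictly below
#' `-lfc_threshold` or strictly above `+lfc_threshold` AND its adjusted
#' p-value is strictly below `alpha`; every other gene is unlabeled.
#' Boundary values (log fold change exactly at the threshold, adjusted p
#' exactly at `alpha`) are unlabeled.
#'
#' @param de Output of [differential_expression()].
#' @param expr The [expression_matrix()] the DE table was computed from,
#'   supplying the feature vectors.
#' @param lfc_threshold Positive log2 fold-change cutoff (default 1).
#' @param alpha Adjusted-p cutoff (default 0.05).
#' @param max_unlabeled Optional cap: keep only this many unlabeled genes,
#'   those with the smallest absolute log fold change (the least
#'   differentially expressed).
#' @return A `pu_benchmark` object: `positives`, `unlabeled` (gene id
#'   vectors) and `features` (expression rows of benchmark genes).
#' @export
select_positive_unlabeled <- function(de, expr, lfc_threshold = 1,
                                      alpha = 0.05,
                                      max_unlabeled = NULL) {
  stopifnot(lfc_threshold > 0, alpha > 0)
  pos <- (de$log_fc > lfc_threshold | de$log_fc < -lfc_threshold) &
    de$p_adj < alpha
  positives <- de$gene_id[pos]
  unl <- de[!pos, , drop = FALSE]
  if (!is.null(max_unlabeled) && nrow(unl) > max_unlabeled) {
    unl <- unl[order(abs(unl$log_fc))[seq_len(max_unlabeled)], ,
               drop = FALSE]
  }
  unlabeled <- unl$gene_id
  if (length(positives) == 0L) {
    warning("no gene passed the positive-labeling thresholds; ",
            "the benchmark has an empty positive set", call. = FALSE)
  }
  keep <- c(positives, unlabeled)
  pu_benchmark(positives, unlabeled,
               expr$values[match(keep, expr$gene_ids), , drop = FALSE])
}

#' @rdname select_positive_unlabeled
#' @param positives,unlabeled Disjoint gene id vectors.
#' @param features Feature matrix with one row per benchmark gene
#'   (rownames = gene ids).
#' @export
pu_benchmark <- function(positives, unlabeled, features) {
  positives <- as.character(positives)
  unlabeled <- as.character(unlabeled)
  if (length(intersect(positives, unlabeled)) > 0L) {
    stop("positive and unlabeled sets overlap", call. = FALSE)
  }
  features <- as.matrix(features)
  missing <- setdiff(c(positives, unlabeled), rownames(features))
  if (length(missing) > 0L) {
    stop("benchmark genes missing from the feature matrix: ",
         paste(utils::head(missing, 3), collapse = ", "), call. = FALSE)
  }
  structure(list(positives = positives, unlabeled = unlabeled,
                 features = features), class = "pu_benchmark")
}

#' @export
print.pu_benchmark <- function(x, ...) {
  cat(sprintf(
    "Positive/unlabeled benchmark: %d positive, %d unlabeled genes; %d features\n",
    length(x$positives), length(x$unlabeled), ncol(x$features)))
  invisible(x)
}

#' Drop feature-space outlier genes by robust z-score
#'
#' A gene is removed when, on any feature, its robust z-score
#' `(x - median) / (1.4826 * MAD)` exceeds `z_threshold` in absolute
#' value. Features with zero MAD contribute no removals (degenerate-scale
#' guard). Used on the training positives before scaling, to avoid
#' anchoring the min-max range on aberrant profiles.
#'
#' @param features Feature matrix (>= 3 rows), rownames = gene ids.
#' @param z_threshold Robust z cutoff (default 4).
#' @return List with `features` (retained rows) and `removed` (gene ids).
#' @export
remove_outliers <- function(features, z_threshold = 4) {
  features <- as.matrix(features)
  if (nrow(features) < 3L) {
    stop("outlier screening needs at least 3 rows", call. = FALSE)
  }
  med <- apply(features, 2, stats::median)
  mad_ <- apply(features, 2, stats::mad)   # 1.4826 * raw MAD
  scale_ok <- mad_ > .Machine$double.eps
  z <- sweep(features[, scale_ok, drop = FALSE], 2, med[scale_ok])
  z <- sweep(z, 2, mad_[scale_ok], "/")
  bad <- if (ncol(z) > 0) apply(abs(z) > z_threshold, 1, any) else
    rep(FALSE, nrow(features))
  if (all(bad)) {
    stop("outlier screening removed every row; lower 'z_threshold'",
         call. = FALSE)
  }
  list(features = features[!bad, , drop = FALSE],
       removed = rownames(features)[bad])
}

#' Min-max scale features to \[0, 1\] using training-set parameters
#'
#' Per feature, `x' = (x - x_min) / (x_max - x_min)` with the minimum and
#' maximum taken from `train` only; any further matrices are transformed
#' with those same parameters and clipped to \[0, 1\], so no information
#' leaks from evaluation data into the scaling. Constant features map
#' to 0.
#'
#' @param train Training feature matrix (defines the parameters).
#' @param ... Further matrices to transform with the training parameters.
#' @return List with `train`, one entry per `...` matrix (named as
#'   passed), and `params` (`min`, `range` per feature).
#' @export
minmax_scale <- function(train, ...) {
  train <- as.matrix(train)
  if (nrow(train) == 0L) stop("empty training matrix", call. = FALSE)
  mins <- apply(train, 2, min)
  rng <- apply(train, 2, max) - mins
  rng0 <- rng <= .Machine$double.eps
  apply_scale <- function(m, clip) {
    m <- as.matrix(m)
    out <- sweep(m, 2, mins)
    out <- sweep(out, 2, ifelse(rng0, 1, rng), "/")
    out[, rng0] <- 0
    if (clip) out[] <- pmin(pmax(out, 0), 1)
    out
  }
  others <- lapply(list(...), apply_scale, clip = TRUE)
  c(list(train = apply_scale(train, clip = FALSE)), others,
    list(params = list(min = mins, range = rng)))
}

#' Train/test split of benchmark positives
#'
#' Positives are split at random into a training fraction and a held-out
#' test fraction; every unlabeled gene goes to the evaluation pool only
#' and never appears in training.
#'
#' @param benchmark A `pu_benchmark`.
#' @param train_fraction Fraction of positives used for training
#'   (default 0.7).
#' @param seed Integer seed making the split reproducible.
#' @return List with `train_positives`, `test_positives`,
#'   `test_unlabeled` (gene id vectors).
#' @export
split_train_test <- function(benchmark, train_fraction = 0.7, seed = 1L) {
  stopifnot(inherits(benchmark, "pu_benchmark"),
            train_fraction > 0, train_fraction < 1)
  pos <- benchmark$positives
  if (length(pos) < 2L) {
    stop("need at least 2 positive genes to split", call. = FALSE)
  }
  n_train <- round(train_fraction * length(pos))
  n_train <- min(max(n_train, 1L), length(pos) - 1L)
  idx <- with_seed(seed, sample.int(length(pos), n_train))
  list(train_positives = pos[idx],
       test_positives = pos[-idx],
       test_unlabeled = benchmark$unlabeled)
}

# run code under a temporary RNG state
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  expr
}

#' k-fold cross-validated recall on training positives
#'
#' Within positives-only training data, recall is the only classical
#' metric computable by cross-validation: each fold is held out in turn,
#' the one-class model is fitted on the remainder, and the fraction of
#' held-out positives predicted inlier is recorded.
#'
#' @param train_features Scaled feature matrix of training positives.
#' @param kernel,nu,gamma Model settings, as in [ocsvm()].
#' @param folds Number of folds (default 10).
#' @param seed Seed for the fold assignment.
#' @return List with `fold_recall` (length `folds`), `mean`, `sd`, and
#'   `assignments` (fold index per row).
#' @export
cross_validate <- function(train_features, kernel = "linear", nu = 0.05,
                           gamma = NULL, folds = 10L, seed = 1L) {
  train_features <- as.matrix(train_features)
  n <- nrow(train_features)
  if (folds < 2L) stop("'folds' must be at least 2", call. = FALSE)
  if (folds > n) {
    stop(sprintf("cannot make %d folds from %d training positives",
                 folds, n), call. = FALSE)
  }
  assign_ <- with_seed(seed, sample(rep_len(seq_len(folds), n)))
  fold_recall <- vapply(seq_len(folds), function(k) {
    held <- assign_ == k
    fit <- ocsvm(train_features[!held, , drop = FALSE], kernel = kernel,
                 nu = nu, gamma = gamma)
    estimate_recall(predict(fit, train_features[held, , drop = FALSE]))
  }, numeric(1))
  list(fold_recall = fold_recall, mean = mean(fold_recall),
       sd = stats::sd(fold_recall), assignments = assign_)
}
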