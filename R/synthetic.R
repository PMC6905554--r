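# Synthetic expression matrices with planted disease genes. The generator
# mimics the structure of a preprocessed two-condition microarray study on
# the log2 scale: per-gene baseline means, i.i.d. gaussian noise, a subset
# of genes whose disease-sample mean is shifted by a fixed effect size
# with random sign, and optionally a fraction of those disease genes
# withheld from the positive label so they hide in the unlabeled pool
# (the contamination every positive-unlabeled method must cope with).

#' Configuration for the synthetic expression generator
#'
#' Defaults emulate the shape of the AML benchmark study the package is
#' built around: 26 disease and 38 healthy samples, log2-scale intensities
#' with unit-SD noise, and a planted effect size comfortably above the
#' |log2 FC| > 1 labeling threshold.
#'
#' @param n_genes Number of genes.
#' @param n_disease_samples,n_healthy_samples Samples per condition.
#' @param disease_gene_fraction Fraction of genes carrying a planted
#'   disease shift, in (0, 1).
#' @param effect_size_delta Mean log2 shift added to planted genes in
#'   disease samples (sign drawn at random per gene).
#' @param noise_sd Gaussian noise SD on the log2 scale.
#' @param baseline_mean_range Interval the per-gene baseline means are
#'   drawn from, uniformly.
#' @param contamination_fraction Fraction of planted disease genes
#'   withheld from the positive label (hidden in the unlabeled set),
#'   in \[0, 1).
#' @param seed Integer seed.
#' @return A validated `synthetic_config` list.
#' @export
synthetic_config <- function(n_genes = 2000L,
                             n_disease_samples = 26L,
                             n_healthy_samples = 38L,
                             disease_gene_fraction = 0.15,
                             effect_size_delta = 3,
                             noise_sd = 1,
                             baseline_mean_range = c(4, 12),
                             contamination_fraction = 0,
                             seed = 1L) {
  cfg <- list(n_genes = as.integer(n_genes),
              n_disease_samples = as.integer(n_disease_samples),
              n_healthy_samples = as.integer(n_healthy_samples),
              disease_gene_fraction = disease_gene_fraction,
              effect_size_delta = effect_size_delta,
              noise_sd = noise_sd,
              baseline_mean_range = as.numeric(baseline_mean_range),
              contamination_fraction = contamination_fraction,
              seed = as.integer(seed))
  check <- function(ok, field, why) {
    if (!ok) stop("invalid '", field, "': ", why, call. = FALSE)
  }
  check(cfg$n_genes >= 1, "n_genes", "must be a positive count")
  check(cfg$n_disease_samples >= 1, "n_disease_samples",
        "must be a positive count")
  check(cfg$n_healthy_samples >= 1, "n_healthy_samples",
        "must be a positive count")
  check(cfg$disease_gene_fraction > 0 && cfg$disease_gene_fraction < 1,
        "disease_gene_fraction", "must lie in (0, 1)")
  check(is.finite(cfg$effect_size_delta), "effect_size_delta",
        "must be finite")
  check(cfg$noise_sd > 0, "noise_sd", "must be positive")
  check(length(cfg$baseline_mean_range) == 2L &&
          diff(cfg$baseline_mean_range) >= 0, "baseline_mean_range",
        "must be an increasing interval c(lo, hi)")
  check(cfg$contamination_fraction >= 0 && cfg$contamination_fraction < 1,
        "contamination_fraction", "must lie in [0, 1)")
  structure(cfg, class = "synthetic_config")
}

#' Generate a synthetic expression matrix with known ground truth
#'
#' @param config A [synthetic_config()].
#' @return List with `expr` (an [expression_matrix()]) and `truth`, a
#'   `synthetic_truth` object holding `disease_genes`,
#'   `labeled_positives`, `hidden_positives`, and the signed per-gene
#'   effect `effects`.
#' @export
generate_expression <- function(config = synthetic_config()) {
  if (!inherits(config, "synthetic_config")) {
    config <- do.call(synthetic_config, config)
  }
  with_seed(config$seed, {
    ng <- config$n_genes
    nd <- config$n_disease_samples
    nh <- config$n_healthy_samples
    gene_ids <- sprintf("gene_%04d", seq_len(ng))
    n_disease_genes <- max(1L, round(config$disease_gene_fraction * ng))
    disease_idx <- sort(sample.int(ng, n_disease_genes))
    effects <- numeric(ng)
    effects[disease_idx] <- sample(c(-1, 1), n_disease_genes,
                                   replace = TRUE) *
      config$effect_size_delta

    mu <- stats::runif(ng, config$baseline_mean_range[1],
                       config$baseline_mean_range[2])
    vals <- matrix(stats::rnorm(ng * (nd + nh), sd = config$noise_sd),
                   nrow = ng) + mu
    vals[, seq_len(nd)] <- vals[, seq_len(nd)] + effects

    n_hidden <- round(config$contamination_fraction * n_disease_genes)
    hidden_idx <- if (n_hidden > 0) {
      sort(sample(disease_idx, n_hidden))
    } else integer(0)

    expr <- expression_matrix(
      vals, gene_ids = gene_ids,
      sample_ids = c(sprintf("AML_%02d", seq_len(nd)),
                     sprintf("healthy_%02d", seq_len(nh))),
      condition = c(rep("disease", nd), rep("healthy", nh)))
    truth <- structure(list(
      disease_genes = gene_ids[disease_idx],
      labeled_positives = gene_ids[setdiff(disease_idx, hidden_idx)],
      hidden_positives = gene_ids[hidden_idx],
      effects = stats::setNames(effects, gene_ids)
    ), class = "synthetic_truth")
    list(expr = expr, truth = truth)
  })
}

#' True precision/recall/F-measure against synthetic ground truth
#'
#' The oracle the positive-unlabeled estimators are validated against:
#' with the generator's hidden labels in hand, all four confusion counts
#' are computable and the classical metrics are exact.
#'
#' @param pred Named prediction vector (`"inlier"`/`"outlier"`), names =
#'   gene ids of every evaluated gene.
#' @param truth A `synthetic_truth` object.
#' @return List with `tp`, `fp`, `fn`, `tn`, `precision`, `recall`,
#'   `f_measure`, computed over the evaluated genes.
#' @export
ground_truth_metrics <- function(pred, truth) {
  stopifnot(inherits(truth, "synthetic_truth"))
  ids <- names(pred)
  if (is.null(ids) || any(!nzchar(ids))) {
    stop("'pred' must be named by gene id", call. = FALSE)
  }
  is_pos <- ids %in% truth$disease_genes
  pred_pos <- pred %in% c("inlier", "positive")
  tp <- sum(is_pos & pred_pos)
  fp <- sum(!is_pos & pred_pos)
  fn <- sum(is_pos & !pred_pos)
  tn <- sum(!is_pos & !pred_pos)
  precision <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  recall <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  list(tp = tp, fp = fp, fn = fn, tn = tn, precision = precision,
       recall = recall,
       f_measure = if (!is.na(precision) && !is.na(recall)) {
         f_measure(precision, recall)
       } else NA_real_)
}
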