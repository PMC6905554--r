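# Evaluation for positive-unlabeled validation. With no labelled
# negatives, recall r = P[f(x)=1 | Y=1] is estimable directly on held-out
# positives, and precision p = P[Y=1 | f(x)=1] is recovered by Bayes
# inversion p = r * P[Y=1] / P[f(x)=1], with the class prior P[Y=1] taken
# as the fraction of known positives in the validation pool. When the
# predicted-positive rate equals the prior, p equals r exactly.

#' Confusion counts from truth and prediction labels
#'
#' Entries whose truth is `"unlabeled"` are excluded from every count: in
#' positive-unlabeled data only true positives and false negatives are
#' observable, so with no `"negative"` truths the result carries `tp` and
#' `fn` only (`fp`/`tn` are `NA`).
#'
#' @param truth Character vector in `"positive"`, `"negative"`,
#'   `"unlabeled"`.
#' @param pred Character vector of predictions, `"inlier"`/`"positive"` vs
#'   `"outlier"`/`"negative"`, same length as `truth`.
#' @return A `confusion_counts` list with `tp`, `fn`, `fp`, `tn`,
#'   `n_evaluated`, and `degenerate` (TRUE when every entry was unlabeled).
#' @export
confusion_from_labels <- function(truth, pred) {
  if (length(truth) != length(pred)) {
    stop(sprintf("'truth' (%d) and 'pred' (%d) differ in length",
                 length(truth), length(pred)), call. = FALSE)
  }
  pred_pos <- pred %in% c("inlier", "positive")
  keep <- truth != "unlabeled"
  truth <- truth[keep]
  pred_pos <- pred_pos[keep]
  pu_mode <- !any(truth == "negative")
  counts <- list(
    tp = sum(truth == "positive" & pred_pos),
    fn = sum(truth == "positive" & !pred_pos),
    fp = if (pu_mode) NA_integer_ else sum(truth == "negative" & pred_pos),
    tn = if (pu_mode) NA_integer_ else sum(truth == "negative" & !pred_pos),
    n_evaluated = length(truth),
    degenerate = length(truth) == 0L
  )
  structure(counts, class = "confusion_counts")
}

#' Estimated recall from predictions on held-out positives
#'
#' The proportion of genuinely positive held-out samples the classifier
#' predicts as inliers: the direct estimator of P\[f(x)=1 | Y=1\].
#'
#' @param pred_on_heldout_positives Prediction labels
#'   (`"inlier"`/`"outlier"`) on known positives only.
#' @return Estimated recall in \[0, 1\].
#' @export
estimate_recall <- function(pred_on_heldout_positives) {
  if (length(pred_on_heldout_positives) == 0L) {
    stop("recall is undefined on an empty set of held-out positives",
         call. = FALSE)
  }
  mean(pred_on_heldout_positives %in% c("inlier", "positive"))
}

#' Estimated positive-prediction rate on the whole validation pool
#'
#' The proportion of the full validation set (held-out positives plus
#' unlabeled) predicted inlier: the estimator of P\[f(x)=1\].
#'
#' @param pred_on_full_validation Prediction labels over the whole pool.
#' @return Estimated rate in \[0, 1\].
#' @export
estimate_positive_rate <- function(pred_on_full_validation) {
  if (length(pred_on_full_validation) == 0L) {
    stop("positive rate is undefined on an empty validation set",
         call. = FALSE)
  }
  mean(pred_on_full_validation %in% c("inlier", "positive"))
}

#' Precision by Bayes inversion from PU-estimable quantities
#'
#' `p = r * P[Y=1] / P[f(x)=1]`, clipped to \[0, 1\] (sampling noise can
#' push the raw ratio above 1; clipping is reported via a message).
#'
#' @param recall_hat Estimated recall in \[0, 1\].
#' @param class_prior Fraction of true positives in the validation pool,
#'   in (0, 1\].
#' @param positive_rate_hat Estimated P\[f(x)=1\], must be positive.
#' @return Estimated precision in \[0, 1\].
#' @export
estimate_precision <- function(recall_hat, class_prior,
                               positive_rate_hat) {
  if (!is.numeric(class_prior) || class_prior <= 0 || class_prior > 1) {
    stop("'class_prior' must lie in (0, 1]", call. = FALSE)
  }
  if (!is.numeric(positive_rate_hat) || positive_rate_hat <= 0) {
    stop("precision is undefined when the predicted-positive rate is 0",
         call. = FALSE)
  }
  p <- recall_hat * class_prior / positive_rate_hat
  if (p > 1) {
    message(sprintf(
      "precision estimate %.4f > 1 (sampling noise); clipped to 1", p))
    p <- 1
  }
  max(0, p)
}

#' Harmonic mean of precision and recall
#'
#' @param p,r Precision and recall in \[0, 1\].
#' @return `2 * p * r / (p + r)`, or 0 when both are 0.
#' @export
f_measure <- function(p, r) {
  stopifnot(is.numeric(p), is.numeric(r))
  ifelse(p + r > 0, 2 * p * r / (p + r), 0)
}

#' Positives-only model selection criterion
#'
#' `r^2 / P[f(x)=1]`, proportional to precision times recall under the
#' Bayes inversion, hence usable to rank models without knowing the class
#' prior.
#'
#' @param recall_hat Estimated recall.
#' @param positive_rate_hat Estimated positive-prediction rate (> 0).
#' @return Non-negative criterion value.
#' @export
pu_criterion <- function(recall_hat, positive_rate_hat) {
  if (positive_rate_hat <= 0) {
    stop("criterion undefined when the predicted-positive rate is 0",
         call. = FALSE)
  }
  recall_hat^2 / positive_rate_hat
}

#' Bundle positive-unlabeled evaluation metrics
#'
#' @param recall_hat,positive_rate_hat,class_prior The three estimable
#'   quantities (see [estimate_recall()], [estimate_positive_rate()],
#'   [estimate_precision()]).
#' @return A `pu_metrics` object with `recall_hat`, `positive_rate_hat`,
#'   `class_prior`, `precision_hat`, `f_measure`, `pu_criterion`.
#' @export
pu_metrics <- function(recall_hat, positive_rate_hat, class_prior) {
  p <- estimate_precision(recall_hat, class_prior, positive_rate_hat)
  structure(list(
    recall_hat = recall_hat,
    positive_rate_hat = positive_rate_hat,
    class_prior = class_prior,
    precision_hat = p,
    f_measure = f_measure(p, recall_hat),
    pu_criterion = pu_criterion(recall_hat, positive_rate_hat)
  ), class = "pu_metrics")
}

#' @export
print.pu_metrics <- function(x, ...) {
  cat("Positive-unlabeled evaluation\n")
  cat(sprintf("  precision: %s   recall: %s   F-measure: %s\n",
              format_pct(x$precision_hat), format_pct(x$recall_hat),
              format_pct(x$f_measure)))
  cat(sprintf("  P[f(x)=1]: %.4f   class prior: %.4f   criterion: %.4f\n",
              x$positive_rate_hat, x$class_prior, x$pu_criterion))
  invisible(x)
}

# percentage with 2 decimals, the convention of published comparison tables
format_pct <- function(x) {
  ifelse(is.na(x), "NA", sprintf("%.2f", 100 * x))
}

#' Write a metrics report as flat key/value text and JSON
#'
#' @param metrics A `pu_metrics` object (or plain named list of numbers).
#' @param path Base path; `<path>.txt` and `<path>.json` are written.
#' @return Invisibly, the two file paths.
#' @export
write_metrics_report <- function(metrics, path) {
  vals <- unclass(metrics)
  vals <- vals[vapply(vals, is.numeric, logical(1))]
  txt <- file.path(paste0(path, ".txt"))
  lines <- sprintf("%s\t%s", names(vals), vapply(vals, format, character(1)))
  if (!is.null(metrics$precision_hat)) {
    lines <- c(lines, sprintf(
      "%s_pct\t%s", c("precision", "recall", "f_measure"),
      format_pct(c(metrics$precision_hat, metrics$recall_hat,
                   metrics$f_measure))))
  }
  writeLines(lines, txt)
  jsn <- paste0(path, ".json")
  jsonlite::write_json(vals, jsn, auto_unbox = TRUE, digits = NA)
  invisible(c(txt, jsn))
}
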