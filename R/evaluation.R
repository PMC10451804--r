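# Diagnostic metrics for the "bilateral opacities present" class:
# precision, sensitivity, specificity, balanced accuracy, diagnostic odds
# ratio, F-score, AUROC, AUPRC, with percentile bootstrap intervals.

#' Binarize labels and predictions around the present class
#'
#' Truth is 1 iff the adjudicated label is \code{"present"} (equivocal
#' counts as negative). The score is the softmax probability of the
#' present class; the hard prediction is 1 iff present is the argmax
#' class, so a predicted-equivocal image counts as a negative call.
#'
#' @param truth_labels character labels or class indices.
#' @param probs B x K probability matrix (class order absent, present,
#'   then equivocal when K = 3), or a vector of present-class scores.
#' @return list with \code{truth} (0/1), \code{score} (present-class
#'   probability) and \code{pred} (0/1 hard call).
#' @export
binarize_present <- function(truth_labels, probs) {
  if (length(truth_labels) == 0L) stop("empty input")
  truth <- if (is.character(truth_labels))
    as.integer(truth_labels == "present")
  else as.integer(as.integer(truth_labels) == 2L)
  if (is.matrix(probs)) {
    if (nrow(probs) != length(truth)) stop("row count mismatch")
    score <- probs[, 2L]
    pred <- as.integer(max.col(probs, ties.method = "first") == 2L)
  } else {
    if (length(probs) != length(truth)) stop("length mismatch")
    score <- as.numeric(probs)
    pred <- as.integer(score >= 0.5)
  }
  list(truth = truth, score = score, pred = pred)
}

#' Confusion counts
#'
#' @param truth,pred equal-length 0/1 vectors.
#' @return list with TP, FP, TN, FN.
#' @export
confusion_counts <- function(truth, pred) {
  if (length(truth) != length(pred)) stop("length mismatch")
  truth <- as.integer(truth); pred <- as.integer(pred)
  list(TP = sum(truth == 1L & pred == 1L),
       FP = sum(truth == 0L & pred == 1L),
       TN = sum(truth == 0L & pred == 0L),
       FN = sum(truth == 1L & pred == 0L))
}

#' Diagnostic metrics from confusion counts
#'
#' precision = TP / (TP + FP); sensitivity = TP / (TP + FN);
#' specificity = TN / (TN + FP); balanced accuracy =
#' (sensitivity + specificity) / 2; DOR = (sens x spec) /
#' ((1 - sens) x (1 - spec)); F-score = harmonic mean of precision and
#' sensitivity. A metric whose denominator is zero is reported as
#' \code{NA} (undefined, distinct from 0) with a warning; a DOR with
#' perfect sensitivity or specificity is \code{Inf}. Setting
#' \code{dor_correction} adds 0.5 to every cell for the DOR only.
#'
#' @param counts result of \code{\link{confusion_counts}}.
#' @param dor_correction apply the Haldane 0.5 continuity correction to
#'   the DOR.
#' @return named list of the six metrics.
#' @export
diagnostic_metrics <- function(counts, dor_correction = FALSE) {
  safe_div <- function(num, den, what) {
    if (den == 0) { warning(what, " undefined: zero denominator"); NA_real_ }
    else num / den
  }
  precision <- safe_div(counts$TP, counts$TP + counts$FP, "precision")
  sensitivity <- safe_div(counts$TP, counts$TP + counts$FN, "sensitivity")
  specificity <- safe_div(counts$TN, counts$TN + counts$FP, "specificity")
  balanced_accuracy <-
    if (is.na(sensitivity) || is.na(specificity)) NA_real_
    else (sensitivity + specificity) / 2
  dor <- if (dor_correction) {
    TP <- counts$TP + 0.5; FP <- counts$FP + 0.5
    TN <- counts$TN + 0.5; FN <- counts$FN + 0.5
    (TP / (TP + FN)) * (TN / (TN + FP)) /
      ((FN / (TP + FN)) * (FP / (TN + FP)))
  } else if (is.na(sensitivity) || is.na(specificity)) NA_real_
  else {
    num <- sensitivity * specificity
    den <- (1 - sensitivity) * (1 - specificity)
    if (den == 0) Inf else num / den
  }
  f_score <- if (is.na(precision) || is.na(sensitivity) ||
                 precision + sensitivity == 0) NA_real_
  else 2 * precision * sensitivity / (precision + sensitivity)
  list(precision = precision, sensitivity = sensitivity,
       specificity = specificity, balanced_accuracy = balanced_accuracy,
       dor = dor, f_score = f_score)
}

#' Balanced accuracy from an operating point
#'
#' Convenience wrapper: (sensitivity + specificity) / 2.
#'
#' @param sensitivity,specificity values in [0, 1].
#' @return balanced accuracy.
#' @export
balanced_accuracy <- function(sensitivity, specificity) {
  (sensitivity + specificity) / 2
}

#' Area under the ROC curve
#'
#' Mann-Whitney formulation: the probability that a random positive
#' outscores a random negative, ties counted one half. Identical (to
#' 1e-9) to trapezoidal integration of the ROC curve.
#'
#' @param truth 0/1 vector containing both classes.
#' @param scores numeric scores, higher = more positive.
#' @return AUROC in [0, 1], or \code{NA} with a warning if only one class
#'   is present.
#' @export
auroc <- function(truth, scores) {
  truth <- as.integer(truth)
  npos <- sum(truth == 1L); nneg <- sum(truth == 0L)
  if (npos == 0L || nneg == 0L) {
    warning("AUROC undefined: single-class truth")
    return(NA_real_)
  }
  r <- rank(scores, ties.method = "average")
  (sum(r[truth == 1L]) - npos * (npos + 1) / 2) / (npos * nneg)
}

#' Area under the precision-recall curve
#'
#' Step-wise average precision: thresholds sweep the distinct score
#' values from high to low; each increment in recall is weighted by the
#' precision at that threshold.
#'
#' @param truth 0/1 vector with at least one positive.
#' @param scores numeric scores.
#' @return AUPRC in (0, 1], or \code{NA} with a warning if no positives.
#' @export
auprc <- function(truth, scores) {
  truth <- as.integer(truth)
  npos <- sum(truth == 1L)
  if (npos == 0L) {
    warning("AUPRC undefined: no positive examples")
    return(NA_real_)
  }
  o <- order(scores, decreasing = TRUE)
  truth <- truth[o]; scores <- scores[o]
  # group tied scores: cumulative counts at each distinct threshold
  last_of_group <- which(diff(scores) != 0)
  cut_idx <- c(last_of_group, length(scores))
  tp <- cumsum(truth)[cut_idx]
  fp <- cumsum(1L - truth)[cut_idx]
  precision <- tp / (tp + fp)
  recall <- tp / npos
  sum(diff(c(0, recall)) * precision)
}

#' Percentile bootstrap confidence interval
#'
#' Resamples examples with replacement B times and reports the
#' percentile interval of the metric. Resamples on which the metric is
#' undefined (\code{NA}) are skipped and counted.
#'
#' @param metric_fn function of \code{(truth, scores)} returning a
#'   scalar.
#' @param truth,scores the evaluation data.
#' @param B number of resamples (default 1000).
#' @param level confidence level (default 0.95).
#' @param seed integer seed.
#' @return list with \code{point}, \code{low}, \code{high},
#'   \code{n_undefined}. When the metric is undefined on every resample
#'   the interval is \code{NA} with a warning.
#' @export
bootstrap_ci <- function(metric_fn, truth, scores, B = 1000L, level = 0.95,
                         seed = 1L) {
  n <- length(truth)
  if (n == 0L) stop("empty data")
  if (B < 1L) stop("B must be >= 1")
  point <- suppressWarnings(metric_fn(truth, scores))
  set.seed(as.integer(seed))
  stats_b <- vapply(seq_len(B), function(b) {
    i <- sample.int(n, n, replace = TRUE)
    suppressWarnings(metric_fn(truth[i], scores[i]))
  }, numeric(1))
  ok <- !is.na(stats_b)
  if (!any(ok)) {
    warning("metric undefined on every bootstrap resample")
    return(list(point = point, low = NA_real_, high = NA_real_,
                n_undefined = B))
  }
  qs <- stats::quantile(stats_b[ok],
                        c((1 - level) / 2, 1 - (1 - level) / 2),
                        names = FALSE, type = 1)  # order statistic:
  # no interpolation, so infinite resample values (e.g. a DOR with an
  # empty error cell) cannot produce NaN endpoints
  # the interval always brackets the full-sample point estimate
  low <- if (is.na(point)) qs[1] else min(qs[1], point)
  high <- if (is.na(point)) qs[2] else max(qs[2], point)
  list(point = point, low = low, high = high,
       n_undefined = sum(!ok))
}

# Metric closures over binarized data, used by evaluate_classifier.
.metric_functions <- function() {
  list(
    precision = function(t, p) diagnostic_metrics(confusion_counts(t, p))$precision,
    sensitivity = function(t, p) diagnostic_metrics(confusion_counts(t, p))$sensitivity,
    specificity = function(t, p) diagnostic_metrics(confusion_counts(t, p))$specificity,
    balanced_accuracy = function(t, p)
      diagnostic_metrics(confusion_counts(t, p))$balanced_accuracy,
    dor = function(t, p) diagnostic_metrics(confusion_counts(t, p))$dor,
    f_score = function(t, p) diagnostic_metrics(confusion_counts(t, p))$f_score,
    auroc = auroc,
    auprc = auprc)
}

#' Evaluate a classifier on a labeled test set
#'
#' Computes all eight diagnostic metrics for the present class with
#' percentile bootstrap confidence intervals. Threshold metrics use the
#' argmax hard call (equivocal predictions count as negative); ranking
#' metrics use the present-class probability.
#'
#' @param model a \code{classifier}, or \code{NULL} when \code{probs} is
#'   given directly.
#' @param images list of test-transformed images (ignored when
#'   \code{probs} given).
#' @param truth_labels adjudicated labels for the test rows.
#' @param probs optional precomputed B x K probability matrix.
#' @param B bootstrap resamples.
#' @param level confidence level.
#' @param seed integer seed for the bootstrap.
#' @return data.frame with metric, point estimate and CI bounds (class
#'   \code{eval_report}).
#' @export
evaluate_classifier <- function(model = NULL, images = NULL, truth_labels,
                                probs = NULL, B = 1000L, level = 0.95,
                                seed = 1L) {
  if (is.null(probs)) probs <- predict_classifier(model, images)
  bz <- binarize_present(truth_labels, probs)
  fns <- .metric_functions()
  rows <- lapply(names(fns), function(nm) {
    uses_score <- nm %in% c("auroc", "auprc")
    y <- if (uses_score) bz$score else bz$pred
    ci <- bootstrap_ci(fns[[nm]], bz$truth, y, B = B, level = level,
                       seed = seed)
    data.frame(metric = nm, point = ci$point, ci_low = ci$low,
               ci_high = ci$high, n_undefined_resamples = ci$n_undefined,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("eval_report", class(out))
  out
}
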