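# Confidence binning, Maximum Calibration Error and reliability-diagram
# data. Confidence is the maximum softmax probability (or, optionally,
# the present-class probability for binary calibration); correctness is
# whether the argmax class equals the truth.

#' Bin prediction confidences
#'
#' Partitions [0, 1] into \code{n_bins} equal-width half-open intervals
#' [l, u) — the last bin closed at 1 — and assigns each prediction to the
#' bin containing its confidence. Per bin: count, mean confidence, and
#' accuracy (fraction correct).
#'
#' @param probs B x K probability matrix, or a vector of confidences.
#' @param correctness 0/1 vector, one flag per prediction; if
#'   \code{probs} is a matrix and \code{truth} is given instead,
#'   correctness is computed as argmax == truth.
#' @param n_bins number of bins (default 10).
#' @param truth optional 1-based true class indices (alternative to
#'   \code{correctness}).
#' @param positive_class_only use the present-class (column 2)
#'   probability as the confidence instead of the max probability.
#' @return an object of class \code{calibration_bins}: data.frame with
#'   bin edges, count, mean confidence and accuracy.
#' @export
bin_confidences <- function(probs, correctness = NULL, n_bins = 10L,
                            truth = NULL, positive_class_only = FALSE) {
  n_bins <- as.integer(n_bins)
  if (is.na(n_bins) || n_bins < 1L) stop("n_bins must be >= 1")
  if (is.matrix(probs)) {
    conf <- if (positive_class_only) probs[, 2L]
            else if (nrow(probs) == 0L) numeric(0)
            else apply(probs, 1L, max)
    if (is.null(correctness)) {
      if (is.null(truth)) stop("provide correctness or truth")
      tr <- if (is.character(truth)) class_index(truth) else as.integer(truth)
      correctness <- if (positive_class_only) {
        # binary calibration of the present-class probability: the
        # "event" is the present class itself, comparable across schemes
        as.integer(tr == 2L)
      } else {
        as.integer(max.col(probs, ties.method = "first") == tr)
      }
    }
  } else {
    conf <- as.numeric(probs)
    if (is.null(correctness)) stop("provide correctness for vector input")
  }
  if (length(conf) != length(correctness) && length(conf) > 0L)
    stop("one correctness flag per prediction required")
  edges <- seq(0, 1, length.out = n_bins + 1L)
  # half-open [l, u), last bin closed: confidence 1.0 falls in bin n_bins
  bin <- pmin(floor(conf * n_bins) + 1L, n_bins)
  count <- integer(n_bins); mean_conf <- rep(NA_real_, n_bins)
  accuracy <- rep(NA_real_, n_bins)
  for (k in seq_len(n_bins)) {
    in_k <- which(bin == k)
    count[k] <- length(in_k)
    if (count[k] > 0L) {
      mean_conf[k] <- mean(conf[in_k])
      accuracy[k] <- mean(correctness[in_k])
    }
  }
  structure(data.frame(bin = seq_len(n_bins),
                       lower = edges[-(n_bins + 1L)], upper = edges[-1L],
                       count = count, mean_confidence = mean_conf,
                       accuracy = accuracy),
            class = c("calibration_bins", "data.frame"))
}

#' Maximum Calibration Error
#'
#' The largest absolute gap between mean confidence and accuracy over
#' the non-empty confidence bins — the worst-case calibration error.
#'
#' @param bins a \code{calibration_bins} object.
#' @return MCE in [0, 1]; \code{NA} with a warning if every bin is empty.
#' @export
mce <- function(bins) {
  nonempty <- bins$count > 0L
  if (!any(nonempty)) {
    warning("MCE undefined: all bins empty")
    return(NA_real_)
  }
  max(abs(bins$mean_confidence[nonempty] - bins$accuracy[nonempty]))
}

#' Reliability-diagram table
#'
#' One row per bin with the bin midpoint, accuracy, mean confidence and
#' count; empty bins are flagged. Plotting accuracy against confidence
#' with the diagonal shows calibration at a glance.
#'
#' @param bins a \code{calibration_bins} object.
#' @return data.frame with midpoint, accuracy, mean confidence, count
#'   and an \code{empty} flag.
#' @export
reliability_table <- function(bins) {
  data.frame(midpoint = (bins$lower + bins$upper) / 2,
             accuracy = bins$accuracy,
             mean_confidence = bins$mean_confidence,
             count = bins$count,
             empty = bins$count == 0L)
}
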