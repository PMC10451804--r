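# Canonical three-class order used throughout the package:
# absent -> 1, present -> 2, equivocal -> 3 (1-based; index 0/1/2 in docs).
CLASS_LEVELS <- c("absent", "present", "equivocal")

#' Canonical class index
#'
#' Maps a class label (\code{"absent"}, \code{"present"}, \code{"equivocal"})
#' to its 1-based position in the canonical class order used by every target
#' vector and prediction in the package.
#'
#' @param label character vector of class labels.
#' @return integer vector of 1-based class indices.
#' @export
class_index <- function(label) {
  idx <- match(label, CLASS_LEVELS)
  if (anyNA(idx)) {
    stop("unknown class label(s): ",
         paste(unique(label[is.na(idx)]), collapse = ", "))
  }
  idx
}

#' Loss configuration
#'
#' @param kind one of \code{"cross_entropy"}, \code{"focal"},
#'   \code{"smoothed_ce"}, \code{"uncertainty_ce"}.
#' @param focal_gamma focusing exponent of the focal loss (>= 0). The
#'   modulating factor is \code{(1 - p)^focal_gamma}; 2 is the standard
#'   choice. Distinct from the display-gamma of the preprocessing module.
#' @param smoothing_alpha label-smoothing strength in [0, 1).
#' @param normalize_equivocal_target if \code{TRUE}, the equivocal
#'   probability target (0.5, 0.5, 1) is rescaled to sum to one,
#'   i.e. (0.25, 0.25, 0.5). Both variants share the same minimiser;
#'   the unnormalized form is the default.
#' @return an object of class \code{loss_config}.
#' @export
loss_config <- function(kind = c("cross_entropy", "focal", "smoothed_ce",
                                 "uncertainty_ce"),
                        focal_gamma = 2,
                        smoothing_alpha = 0.1,
                        normalize_equivocal_target = FALSE) {
  kind <- match.arg(kind)
  if (!is.numeric(focal_gamma) || length(focal_gamma) != 1L || focal_gamma < 0)
    stop("focal_gamma must be a single real >= 0")
  if (!is.numeric(smoothing_alpha) || length(smoothing_alpha) != 1L ||
      smoothing_alpha < 0 || smoothing_alpha >= 1)
    stop("smoothing_alpha must lie in [0, 1)")
  structure(list(kind = kind,
                 focal_gamma = focal_gamma,
                 smoothing_alpha = smoothing_alpha,
                 normalize_equivocal_target = normalize_equivocal_target),
            class = "loss_config")
}

#' Numerically stable softmax
#'
#' Converts a logit vector (or a batch of logit rows) to class likelihoods.
#' The maximum logit is subtracted before exponentiation so arbitrarily
#' large scores do not overflow; the result is invariant to adding any
#' constant to all logits.
#'
#' @param logits numeric vector of length K, or a B x K matrix of logits.
#' @return probabilities of the same shape, each (row) summing to one.
#' @export
softmax <- function(logits) {
  if (is.matrix(logits)) {
    if (any(!is.finite(logits))) stop("non-finite logits")
    z <- logits - apply(logits, 1L, max)
    e <- exp(z)
    return(e / rowSums(e))
  }
  if (!is.numeric(logits) || length(logits) < 1L) stop("logits must be numeric")
  if (any(!is.finite(logits))) stop("non-finite logits")
  e <- exp(logits - max(logits))
  e / sum(e)
}

#' One-hot target vector
#'
#' @param label class label string or 1-based class index.
#' @param K number of classes.
#' @return numeric length-K vector with a single 1 at the class position.
#' @export
one_hot <- function(label, K = 3L) {
  idx <- if (is.character(label)) class_index(label) else as.integer(label)
  if (length(idx) != 1L || is.na(idx) || idx < 1L || idx > K)
    stop("class index ", idx, " out of range for K = ", K)
  y <- numeric(K)
  y[idx] <- 1
  y
}

#' Label-smoothed target
#'
#' Standard label smoothing: \code{ys = y * (1 - alpha) + alpha / K}.
#' The uniform distribution is a fixed point; smoothed targets always sum
#' to one when the input does.
#'
#' @param y numeric target vector summing to one.
#' @param alpha smoothing strength in [0, 1).
#' @param K number of classes (defaults to \code{length(y)}).
#' @return smoothed target vector.
#' @export
smooth_targets <- function(y, alpha, K = length(y)) {
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha < 0 || alpha >= 1)
    stop("alpha must lie in [0, 1)")
  if (length(y) != K) stop("length(y) != K")
  y * (1 - alpha) + alpha / K
}

#' Uncertainty-aware probability targets
#'
#' Three-class soft targets in class order (absent, present, equivocal):
#' absent images get (1, 0, 0), present images (0, 1, 0), and equivocal
#' images the probability target (0.5, 0.5, 1) — the present/absent entries
#' encode that either reading is equally plausible while the equivocal
#' entry keeps full weight. The equivocal target deliberately does not sum
#' to one; the generalized cross-entropy below handles it, and its
#' minimiser over the simplex is the normalized target (0.25, 0.25, 0.5).
#'
#' @param label class label (\code{"absent"}, \code{"present"},
#'   \code{"equivocal"}) or 1-based index.
#' @param normalize if \code{TRUE} the equivocal target is rescaled to sum
#'   to one.
#' @param K must be 3; present for interface symmetry.
#' @return numeric length-3 target vector.
#' @export
uncertainty_targets <- function(label, normalize = FALSE, K = 3L) {
  if (K != 3L) stop("uncertainty probability targets are defined for K = 3")
  idx <- if (is.character(label)) class_index(label) else as.integer(label)
  t <- switch(idx,
              c(1, 0, 0),
              c(0, 1, 0),
              c(0.5, 0.5, 1))
  if (is.null(t)) stop("class index out of range")
  if (normalize && idx == 3L) t <- t / sum(t)
  t
}

# Clip likelihoods away from zero before taking logs. 1e-12 is far below any
# reportable precision and keeps every loss finite.
.clip_probs <- function(p, eps = 1e-12) pmin(pmax(p, eps), 1)

#' Generalized cross-entropy
#'
#' \code{H(t, p) = sum_k -t_k log(p_k)}. Targets need not sum to one
#' (the equivocal probability target (0.5, 0.5, 1) is used as-is); over
#' the probability simplex the loss is minimised at \code{p = t / sum(t)}.
#'
#' @param target numeric target vector.
#' @param pred numeric probability vector of the same length.
#' @return the scalar loss.
#' @export
cross_entropy <- function(target, pred) {
  if (length(target) != length(pred)) stop("target/prediction length mismatch")
  sum(-target * log(.clip_probs(pred)))
}

#' Focal loss with soft-target support
#'
#' \code{sum_k -t_k (1 - p_k)^gamma log(p_k)}. With one-hot targets this is
#' the standard focal loss; with \code{gamma = 0} it reduces exactly to the
#' cross-entropy above.
#'
#' @param target numeric target vector.
#' @param pred numeric probability vector.
#' @param focal_gamma focusing exponent, >= 0.
#' @return the scalar loss.
#' @export
focal_loss <- function(target, pred, focal_gamma = 2) {
  if (!is.numeric(focal_gamma) || focal_gamma < 0)
    stop("focal_gamma must be >= 0")
  if (length(target) != length(pred)) stop("target/prediction length mismatch")
  p <- .clip_probs(pred)
  sum(-target * (1 - p)^focal_gamma * log(p))
}

#' Build per-example targets for a loss configuration
#'
#' @param labels character vector or 1-based integer class indices.
#' @param config a \code{loss_config}.
#' @param K number of classes.
#' @return a B x K matrix of targets, one row per example.
#' @export
make_targets <- function(labels, config, K = 3L) {
  idx <- if (is.character(labels)) class_index(labels) else as.integer(labels)
  t(vapply(idx, function(i) {
    switch(config$kind,
      cross_entropy = one_hot(i, K),
      focal         = one_hot(i, K),
      smoothed_ce   = smooth_targets(one_hot(i, K), config$smoothing_alpha, K),
      uncertainty_ce = uncertainty_targets(
        i, normalize = config$normalize_equivocal_target, K = K))
  }, numeric(K)))
}

# Per-example loss given a target row and probability row.
.example_loss <- function(target, pred, config) {
  if (config$kind == "focal") focal_loss(target, pred, config$focal_gamma)
  else cross_entropy(target, pred)
}

#' Mean loss over a batch
#'
#' @param targets B x K matrix (or list) of target vectors.
#' @param preds B x K matrix (or list) of probability vectors.
#' @param config a \code{loss_config}.
#' @return mean per-example loss.
#' @export
batch_loss <- function(targets, preds, config) {
  if (is.list(targets)) targets <- do.call(rbind, targets)
  if (is.list(preds)) preds <- do.call(rbind, preds)
  targets <- rbind(targets); preds <- rbind(preds)
  if (nrow(targets) == 0L) stop("empty batch")
  if (!all(dim(targets) == dim(preds))) stop("target/prediction shape mismatch")
  mean(vapply(seq_len(nrow(targets)),
              function(i) .example_loss(targets[i, ], preds[i, ], config),
              numeric(1)))
}

# Gradient of the mean batch loss with respect to the logits.
# probs: B x K softmax outputs; targets: B x K.
# For generalized CE, dL/dz = s * p - t with s = sum(t) per row.
# For focal, chain dL/dp through the softmax Jacobian.
loss_grad_logits <- function(targets, probs, config) {
  B <- nrow(probs)
  if (config$kind == "focal") {
    g <- config$focal_gamma
    p <- .clip_probs(probs)
    # dL/dp_k = t_k * ( g (1-p)^(g-1) log p - (1-p)^g / p )
    dLdp <- targets * (g * (1 - p)^(max(g - 1, 0)) * log(p) - (1 - p)^g / p)
    if (g == 0) dLdp <- -targets / p
    # softmax Jacobian: dz_j = p_j (dp_j - sum_k dp_k p_k)
    s <- rowSums(dLdp * probs)
    dz <- probs * (dLdp - s)
  } else {
    dz <- rowSums(targets) * probs - targets
  }
  dz / B
}
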