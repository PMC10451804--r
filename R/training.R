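#' Training configuration
#'
#' @param scheme \code{"three_class"} (absent / present / equivocal),
#'   \code{"two_class"} (equivocal treated as controls, i.e. absent), or
#'   \code{"two_class_disregard_equivocal"} (equivocal rows dropped from
#'   both training and testing).
#' @param loss a \code{\link{loss_config}}.
#' @param epochs number of passes (default 30).
#' @param learning_rate Adam learning rate (default 1e-4, the fine-tuning
#'   rate; from-scratch small_cnn recipes in this package use 1e-3).
#' @param batch_size minibatch size (default 32).
#' @param augment logical: apply stochastic training augmentations.
#' @param augment_config a \code{\link{preprocess_config}} controlling
#'   augmentation ranges.
#' @param seed integer seed governing sampling, augmentation and weight
#'   initialization.
#' @return an object of class \code{train_config}.
#' @export
train_config <- function(scheme = c("three_class", "two_class",
                                    "two_class_disregard_equivocal"),
                         loss = loss_config("cross_entropy"),
                         epochs = 30L, learning_rate = 1e-4,
                         batch_size = 32L, augment = TRUE,
                         augment_config = preprocess_config(),
                         seed = 1L) {
  scheme <- match.arg(scheme)
  if (epochs < 1L) stop("epochs must be >= 1")
  if (learning_rate <= 0) stop("learning_rate must be > 0")
  n_classes <- if (scheme == "three_class") 3L else 2L
  if (loss$kind == "uncertainty_ce" && n_classes != 3L)
    stop("uncertainty_ce requires the three_class scheme")
  structure(list(scheme = scheme, loss = loss, epochs = as.integer(epochs),
                 learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 augment = augment, augment_config = augment_config,
                 seed = as.integer(seed), n_classes = n_classes),
            class = "train_config")
}

#' Class-balanced weights
#'
#' \code{w_c = n_total / (K * n_c)}: weights inversely proportional to
#' class counts, normalized so \code{sum(w_c * n_c) = n_total}.
#'
#' @param counts positive integer class counts.
#' @return numeric weights, one per class.
#' @export
class_balanced_weights <- function(counts) {
  if (any(counts <= 0)) stop("cannot balance a class with zero count")
  n <- sum(counts)
  K <- length(counts)
  n / (K * counts)
}

#' Class-balanced example sampler
#'
#' Draws example indices with replacement, each example weighted by its
#' class weight, so expected class frequencies are uniform: the majority
#' class is undersampled and minority classes upsampled within each
#' epoch-sized draw.
#'
#' @param labels per-example class labels (character or integer).
#' @param weights per-class weights, named by class or ordered by the
#'   sorted unique labels; defaults to class-balanced weights.
#' @param n number of draws (defaults to \code{length(labels)}).
#' @param seed integer seed.
#' @return integer vector of sampled example indices.
#' @export
make_sampler <- function(labels, weights = NULL, n = length(labels),
                         seed = 1L) {
  f <- factor(labels)
  counts <- table(f)
  if (is.null(weights)) weights <- class_balanced_weights(as.numeric(counts))
  if (!is.null(names(weights))) weights <- weights[levels(f)]
  if (length(weights) != nlevels(f)) stop("one weight per class required")
  prob <- weights[as.integer(f)]
  set.seed(as.integer(seed))
  sample.int(length(labels), n, replace = TRUE, prob = prob)
}

#' Patient-level train/test or k-fold split
#'
#' Splits at the patient level so no patient contributes images to both
#' sides of any split. With \code{k_folds} set, returns k disjoint
#' patient partitions covering every patient.
#'
#' @param manifest data.frame with a \code{patient_id} column.
#' @param train_fraction fraction of patients assigned to training.
#' @param k_folds optional integer >= 2 for cross-validation folds.
#' @param seed integer seed.
#' @return with \code{k_folds = NULL}, a list \code{train}/\code{test} of
#'   manifest subsets; otherwise a list of k folds, each with
#'   \code{train}/\code{test}.
#' @export
split_patients <- function(manifest, train_fraction = 0.7, k_folds = NULL,
                           seed = 1L) {
  if (nrow(manifest) == 0L) stop("empty manifest")
  if (train_fraction <= 0 || train_fraction >= 1)
    stop("train_fraction must lie in (0, 1)")
  patients <- unique(manifest$patient_id)
  set.seed(as.integer(seed))
  patients <- sample(patients)
  if (is.null(k_folds)) {
    n_train <- round(train_fraction * length(patients))
    n_train <- min(max(n_train, 1L), length(patients) - 1L)
    tr <- patients[seq_len(n_train)]
    list(train = manifest[manifest$patient_id %in% tr, , drop = FALSE],
         test = manifest[!manifest$patient_id %in% tr, , drop = FALSE])
  } else {
    k_folds <- as.integer(k_folds)
    if (k_folds < 2L) stop("k_folds must be >= 2")
    if (length(patients) < k_folds)
      stop("fewer patients than folds")
    fold_of <- rep(seq_len(k_folds), length.out = length(patients))
    lapply(seq_len(k_folds), function(k) {
      te <- patients[fold_of == k]
      list(train = manifest[!manifest$patient_id %in% te, , drop = FALSE],
           test = manifest[manifest$patient_id %in% te, , drop = FALSE])
    })
  }
}

#' Map adjudicated labels to scheme class indices
#'
#' \code{three_class}: absent 1, present 2, equivocal 3 (1-based).
#' \code{two_class}: equivocal treated as controls (absent).
#' \code{two_class_disregard_equivocal}: equivocal rows removed.
#'
#' @param manifest data.frame with an \code{adjudicated_label} column.
#' @param scheme training scheme string.
#' @return the manifest with a \code{class_index} column appended
#'   (equivocal rows dropped under the disregard scheme).
#' @export
prepare_labels <- function(manifest, scheme = "three_class") {
  lab <- manifest$adjudicated_label
  if (!all(lab %in% CLASS_LEVELS))
    stop("unknown adjudicated label(s): ",
         paste(setdiff(lab, CLASS_LEVELS), collapse = ", "))
  if (scheme == "three_class") {
    manifest$class_index <- class_index(lab)
  } else if (scheme == "two_class") {
    manifest$class_index <- ifelse(lab == "present", 2L, 1L)
  } else if (scheme == "two_class_disregard_equivocal") {
    manifest <- manifest[lab != "equivocal", , drop = FALSE]
    manifest$class_index <- ifelse(manifest$adjudicated_label == "present",
                                   2L, 1L)
  } else stop("unknown scheme: ", scheme)
  manifest
}

#' Train a classifier
#'
#' Minibatch gradient descent with Adam under the configured loss and a
#' class-balanced weighted random sampler; optional on-the-fly
#' augmentation. Images must already be at the model input size (the
#' usual pipeline applies \code{\link{test_transform}} first).
#' Deterministic given \code{config$seed}.
#'
#' @param model a \code{classifier} from \code{\link{build_model}}.
#' @param images list of pixel matrices at the model input size.
#' @param labels per-image 1-based class indices (or label strings).
#' @param config a \code{\link{train_config}}.
#' @param verbose print per-epoch mean loss.
#' @return a list with \code{model} (trained) and \code{history}
#'   (data.frame of epoch and mean training loss).
#' @export
train_classifier <- function(model, images, labels, config, verbose = FALSE) {
  if (config$n_classes != model$n_classes)
    stop("scheme implies ", config$n_classes, " classes but model has ",
         model$n_classes)
  idx <- if (is.character(labels)) class_index(labels) else as.integer(labels)
  if (any(idx < 1L | idx > model$n_classes)) stop("label index out of range")
  n <- length(images)
  if (n == 0L) stop("no training images")
  counts <- tabulate(idx, nbins = model$n_classes)
  weights <- class_balanced_weights(pmax(counts, 1L))
  weights[counts == 0L] <- 0
  params <- model$params
  state <- adam_init(params)
  history <- numeric(config$epochs)
  set.seed(config$seed)
  aug_seeds <- sample.int(2^30, config$epochs * n)
  for (ep in seq_len(config$epochs)) {
    order_idx <- make_sampler(idx, weights = weights[sort(unique(idx))],
                              n = n, seed = config$seed * 131L + ep)
    ep_loss <- 0; n_batch <- 0L
    for (start in seq(1L, n, by = config$batch_size)) {
      bidx <- order_idx[start:min(start + config$batch_size - 1L, n)]
      imgs <- images[bidx]
      if (config$augment) {
        imgs <- lapply(seq_along(bidx), function(j)
          augment_image(images[[bidx[j]]], config$augment_config,
                        seed = aug_seeds[(ep - 1L) * n + start + j - 1L]))
      }
      x <- .stack_images(imgs)
      targets <- make_targets(idx[bidx], config$loss, K = model$n_classes)
      m <- model; m$params <- params
      fw <- cnn_forward(m, x)
      probs <- softmax(fw$logits)
      ep_loss <- ep_loss + batch_loss(targets, probs, config$loss)
      n_batch <- n_batch + 1L
      dlogits <- loss_grad_logits(targets, probs, config$loss)
      bk <- cnn_backward(m, fw, dlogits)
      upd <- adam_step(params, bk$grads, state, lr = config$learning_rate)
      params <- upd$params
      state <- upd$state
    }
    history[ep] <- ep_loss / n_batch
    if (verbose)
      message(sprintf("epoch %d/%d  mean loss %.4f", ep, config$epochs,
                      history[ep]))
  }
  model$params <- params
  list(model = model,
       history = data.frame(epoch = seq_len(config$epochs),
                            mean_loss = history))
}
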