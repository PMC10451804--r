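#' @useDynLib opaxr, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

# Small convolutional network with hand-derived backpropagation.
#
# Architecture (input S x S x 1, S divisible by 16):
#   conv 3x3/stride 2 -> 8ch  -> ReLU
#   conv 3x3/stride 2 -> 16ch -> ReLU
#   conv 3x3/stride 2 -> 32ch -> ReLU
#   conv 3x3/stride 2 -> 32ch -> ReLU   (the "last convolutional block")
#   global average pool -> fully connected -> n_classes logits
#
# Convolutions are computed by im2col + matrix multiplication so the whole
# batch runs through BLAS; the backward pass mirrors the same layout.

# --- im2col convolution -----------------------------------------------------

# Flatten a (k, k, C, Cout) kernel into the (k*k*C, Cout) matrix layout
# shared by the R and compiled engines (channel fastest within offset).
.flatten_w <- function(w) {
  wmat <- aperm(w, c(3L, 1L, 2L, 4L))
  dim(wmat) <- c(prod(dim(w)[1:3]), dim(w)[4])
  wmat
}

# x: array (H, W, C, B); w: array (3, 3, C, Cout). The compiled engine is
# the default; the pure-R engine is retained as an independent reference
# implementation of the same layout.
conv_forward <- function(x, w, b, stride = 2L, pad = 1L,
                         engine = c("cpp", "r")) {
  engine <- match.arg(engine)
  if (engine == "cpp") {
    res <- .conv_fwd_cpp(x, dim(x), .flatten_w(w), b, dim(w)[1],
                         as.integer(stride), as.integer(pad))
    return(list(out = res$out, xcol = res$xcol, xdim = dim(x),
                wdim = dim(w), stride = as.integer(stride),
                pad = as.integer(pad), engine = "cpp"))
  }
  conv_forward_r(x, w, b, stride, pad)
}

conv_forward_r <- function(x, w, b, stride = 2L, pad = 1L) {
  d <- dim(x); H <- d[1]; W <- d[2]; C <- d[3]; B <- d[4]
  k <- dim(w)[1]
  Ho <- (H + 2L * pad - k) %/% stride + 1L
  Wo <- (W + 2L * pad - k) %/% stride + 1L
  xp <- array(0, c(H + 2L * pad, W + 2L * pad, C, B))
  xp[pad + seq_len(H), pad + seq_len(W), , ] <- x
  xcol <- matrix(0, Ho * Wo * B, k * k * C)
  for (dj in seq_len(k)) for (di in seq_len(k)) {
    sl <- xp[seq(di, by = stride, length.out = Ho),
             seq(dj, by = stride, length.out = Wo), , , drop = FALSE]
    # (Ho, Wo, C, B) -> (Ho, Wo, B, C) -> (Ho*Wo*B, C)
    sl <- aperm(sl, c(1L, 2L, 4L, 3L))
    dim(sl) <- c(Ho * Wo * B, C)
    kk <- (dj - 1L) * k + di
    xcol[, ((kk - 1L) * C + 1L):(kk * C)] <- sl
  }
  # rows of wmat ordered (c fastest, then di, then dj) to match xcol columns
  wmat <- aperm(w, c(3L, 1L, 2L, 4L))
  dim(wmat) <- c(k * k * C, dim(w)[4])
  y <- xcol %*% wmat
  y <- sweep(y, 2L, b, "+")
  dim(y) <- c(Ho, Wo, B, dim(w)[4])
  y <- aperm(y, c(1L, 2L, 4L, 3L))
  list(out = y, xcol = xcol, xdim = d, wdim = dim(w),
       stride = stride, pad = pad, engine = "r")
}

# dy: array (Ho, Wo, Cout, B) matching cache$out.
conv_backward <- function(dy, w, cache) {
  if (identical(cache$engine, "cpp")) {
    res <- .conv_bwd_cpp(dy, dim(dy), cache$xcol, .flatten_w(w),
                         cache$xdim, cache$wdim[1], cache$stride,
                         cache$pad)
    k <- cache$wdim[1]; C <- cache$wdim[3]; Cout <- cache$wdim[4]
    dw <- array(res$dwmat, c(C, k, k, Cout))
    dw <- aperm(dw, c(2L, 3L, 1L, 4L))
    return(list(dx = res$dx, dw = dw, db = as.numeric(res$db)))
  }
  conv_backward_r(dy, w, cache)
}

conv_backward_r <- function(dy, w, cache) {
  k <- cache$wdim[1]; C <- cache$wdim[3]; Cout <- cache$wdim[4]
  H <- cache$xdim[1]; W <- cache$xdim[2]; B <- cache$xdim[4]
  stride <- cache$stride; pad <- cache$pad
  Ho <- dim(dy)[1]; Wo <- dim(dy)[2]
  dymat <- aperm(dy, c(1L, 2L, 4L, 3L))
  dim(dymat) <- c(Ho * Wo * B, Cout)
  db <- colSums(dymat)
  dwmat <- crossprod(cache$xcol, dymat)          # (k*k*C, Cout)
  dw <- array(dwmat, c(C, k, k, Cout))
  dw <- aperm(dw, c(2L, 3L, 1L, 4L))
  wmat <- aperm(w, c(3L, 1L, 2L, 4L))
  dim(wmat) <- c(k * k * C, Cout)
  dxcol <- tcrossprod(dymat, wmat)               # (Ho*Wo*B, k*k*C)
  dxp <- array(0, c(H + 2L * pad, W + 2L * pad, C, B))
  for (dj in seq_len(k)) for (di in seq_len(k)) {
    kk <- (dj - 1L) * k + di
    blk <- dxcol[, ((kk - 1L) * C + 1L):(kk * C), drop = FALSE]
    dim(blk) <- c(Ho, Wo, B, C)
    blk <- aperm(blk, c(1L, 2L, 4L, 3L))
    ri <- seq(di, by = stride, length.out = Ho)
    ci <- seq(dj, by = stride, length.out = Wo)
    dxp[ri, ci, , ] <- dxp[ri, ci, , , drop = FALSE] + blk
  }
  dx <- dxp[pad + seq_len(H), pad + seq_len(W), , , drop = FALSE]
  list(dx = dx, dw = dw, db = db)
}

# --- model construction -----------------------------------------------------

.small_cnn_channels <- c(8L, 16L, 32L, 32L)

#' Build a classifier
#'
#' \code{"small_cnn"} is a four-block convolutional network (stride-2
#' 3x3 convolutions with 8/16/32/32 channels, ReLU, global average
#' pooling, one fully connected layer) sized so that CPU training on a
#' few hundred 64-pixel images completes in seconds. Weights use He
#' initialization; construction is deterministic given the seed.
#'
#' \code{"densenet121"} — the full-scale architecture used for clinical
#' imagery — requires a GPU tensor backend and externally supplied
#' pretrained weights, neither of which this package provides; requesting
#' it raises an informative error.
#'
#' @param architecture \code{"small_cnn"} or \code{"densenet121"}.
#' @param n_classes 2 or 3.
#' @param input_size input side length; must be divisible by 16.
#' @param pretrained only meaningful for densenet121; invalid for
#'   small_cnn.
#' @param seed integer seed for weight initialization.
#' @return an object of class \code{classifier}.
#' @export
build_model <- function(architecture = c("small_cnn", "densenet121"),
                        n_classes = 3L, input_size = 64L,
                        pretrained = FALSE, seed = 1L) {
  architecture <- match.arg(architecture)
  n_classes <- as.integer(n_classes)
  if (!n_classes %in% c(2L, 3L)) stop("n_classes must be 2 or 3")
  if (architecture == "densenet121")
    stop("densenet121 requires an external tensor backend and pretrained ",
         "weights; use architecture = \"small_cnn\"")
  if (isTRUE(pretrained))
    stop("pretrained weights are not available for small_cnn")
  input_size <- as.integer(input_size)
  if (input_size < 32L || input_size %% 16L != 0L)
    stop("input_size must be a multiple of 16, >= 32")
  set.seed(as.integer(seed))
  ch <- c(1L, .small_cnn_channels)
  params <- list()
  for (l in 1:4) {
    fan_in <- 9L * ch[l]
    params[[paste0("w", l)]] <- array(
      stats::rnorm(9L * ch[l] * ch[l + 1L], 0, sqrt(2 / fan_in)),
      c(3L, 3L, ch[l], ch[l + 1L]))
    params[[paste0("b", l)]] <- numeric(ch[l + 1L])
  }
  # final feature map is (S/16) x (S/16) x 32, flattened for the head so
  # laterality (left vs right lung) stays linearly separable
  feat <- (input_size %/% 16L)^2 * ch[5L]
  params$wfc <- matrix(stats::rnorm(feat * n_classes, 0, sqrt(2 / feat)),
                       feat, n_classes)
  params$bfc <- numeric(n_classes)
  structure(list(architecture = architecture, params = params,
                 n_classes = n_classes, input_size = input_size,
                 seed = as.integer(seed)),
            class = "classifier")
}

# Stack a list of equally sized matrices into an (H, W, 1, B) array.
.stack_images <- function(images) {
  if (is.array(images) && length(dim(images)) == 4L) return(images)
  if (is.matrix(images)) images <- list(images)
  if (inherits(images, "image_record")) images <- list(images$pixels)
  images <- lapply(images, as_pixels)
  H <- nrow(images[[1]]); W <- ncol(images[[1]])
  if (!all(vapply(images, function(m) nrow(m) == H && ncol(m) == W,
                  logical(1))))
    stop("all images in a batch must share the same size")
  array(unlist(images, use.names = FALSE), c(H, W, 1L, length(images)))
}

# Full forward pass; keeps every intermediate needed by backward and by
# Grad-CAM. Returns logits as a B x K matrix.
cnn_forward <- function(model, x, keep_cache = TRUE) {
  p <- model$params
  caches <- vector("list", 4L)
  acts <- vector("list", 4L)   # post-ReLU activations per block
  h <- x
  for (l in 1:4) {
    cf <- conv_forward(h, p[[paste0("w", l)]], p[[paste0("b", l)]])
    a <- pmax(cf$out, 0)
    caches[[l]] <- if (keep_cache) cf else NULL
    acts[[l]] <- a
    h <- a
  }
  d <- dim(h)                                   # (h, w, C, B)
  fmat <- h
  dim(fmat) <- c(d[1] * d[2] * d[3], d[4])      # flatten per image
  logits <- t(fmat) %*% p$wfc + matrix(p$bfc, d[4], model$n_classes,
                                       byrow = TRUE)
  list(logits = logits, fmat = fmat, acts = acts, caches = caches,
       pool_dim = d)
}

# Backward pass from dlogits (B x K). Returns gradients for every
# parameter plus (optionally) the gradient on a chosen block's post-ReLU
# activations (used by Grad-CAM).
cnn_backward <- function(model, fw, dlogits, upto_layer = 0L) {
  p <- model$params
  grads <- list()
  grads$wfc <- fw$fmat %*% dlogits               # feat x K
  grads$bfc <- colSums(dlogits)
  dfmat <- p$wfc %*% t(dlogits)                  # feat x B
  d <- fw$pool_dim
  dh <- array(as.vector(dfmat), d)               # unflatten
  act_grad <- NULL
  for (l in 4:1) {
    if (upto_layer == l) { act_grad <- dh; break }
    dh <- dh * (fw$acts[[l]] > 0)                # ReLU gate
    bk <- conv_backward(dh, p[[paste0("w", l)]], fw$caches[[l]])
    grads[[paste0("w", l)]] <- bk$dw
    grads[[paste0("b", l)]] <- bk$db
    dh <- bk$dx
  }
  list(grads = grads, act_grad = act_grad)
}

#' Predict class likelihoods
#'
#' Runs the forward pass and softmax for a batch of test-transformed
#' images, preserving batch order.
#'
#' @param model a \code{classifier}.
#' @param images a list of pixel matrices (or a single matrix /
#'   \code{image_record}), already test-transformed to the model's input
#'   size.
#' @return B x K matrix of class probabilities, rows summing to one.
#' @export
predict_classifier <- function(model, images) {
  x <- .stack_images(images)
  if (dim(x)[1] != model$input_size || dim(x)[2] != model$input_size)
    stop("images must be ", model$input_size, "x", model$input_size,
         " (apply test_transform first)")
  fw <- cnn_forward(model, x, keep_cache = FALSE)
  softmax(fw$logits)
}

# --- Adam -------------------------------------------------------------------

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

adam_step <- function(params, grads, state, lr = 1e-3,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    mhat <- state$m[[nm]] / bc1
    vhat <- state$v[[nm]] / bc2
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

#' Save / load a classifier checkpoint
#'
#' Checkpoints are written as plain JSON (flattened parameter arrays with
#' their dimensions) plus metadata: architecture, class count, input
#' size, seed.
#'
#' @param model a \code{classifier}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
save_classifier <- function(model, path) {
  flat <- lapply(model$params, function(p)
    list(dim = if (is.null(dim(p))) length(p) else dim(p),
         data = as.vector(p)))
  jsonlite::write_json(
    list(architecture = model$architecture, n_classes = model$n_classes,
         input_size = model$input_size, seed = model$seed, params = flat),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_classifier
#' @export
load_classifier <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  params <- lapply(obj$params, function(p) {
    if (length(p$dim) > 1L) array(p$data, p$dim)
    else if (!is.null(names(p)) && length(p$dim) == 1L && p$dim > 1L &&
             is.null(dim(p$data))) as.numeric(p$data)
    else as.numeric(p$data)
  })
  # matrices (the fully connected layer) come back as arrays; fix class
  if (length(dim(params$wfc)) == 2L) params$wfc <- as.matrix(params$wfc)
  structure(list(architecture = obj$architecture, params = params,
                 n_classes = obj$n_classes, input_size = obj$input_size,
                 seed = obj$seed),
            class = "classifier")
}
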