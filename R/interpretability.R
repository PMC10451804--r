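# Saliency methods: Grad-CAM on the last convolutional block, and
# occlusion sensitivity maps.

#' Grad-CAM heatmap
#'
#' Gradients of the target-class score (logit) with respect to the
#' selected convolutional block's post-activation feature maps are
#' spatially averaged into per-channel weights; the weighted sum of
#' feature maps is rectified (negatives zeroed), bilinearly upsampled to
#' the input size, and normalized to [0, 1] by its maximum when positive.
#' Raw (pre-normalization) values are kept in the \code{raw} attribute.
#'
#' @param model a \code{classifier}.
#' @param image a test-transformed pixel matrix (or \code{image_record})
#'   at the model input size.
#' @param target_class 1-based class index whose score is explained.
#' @param layer convolutional block index 1-4 (default 4, the last one).
#' @return a \code{saliency_map} object: matrix of values in [0, 1]
#'   aligned to the input image, with attributes \code{method},
#'   \code{target_class}, \code{raw}.
#' @export
grad_cam <- function(model, image, target_class = 2L, layer = 4L) {
  layer <- as.integer(layer)
  if (layer < 1L || layer > 4L)
    stop("layer must select one of the four convolutional blocks")
  target_class <- as.integer(target_class)
  if (target_class < 1L || target_class > model$n_classes)
    stop("target_class out of range")
  x <- .stack_images(image)
  fw <- cnn_forward(model, x)
  dlogits <- matrix(0, 1L, model$n_classes)
  dlogits[1L, target_class] <- 1
  bk <- cnn_backward(model, fw, dlogits, upto_layer = layer)
  A <- fw$acts[[layer]]            # (h, w, C, 1)
  G <- bk$act_grad
  d <- dim(A)
  weights <- apply(G[, , , 1L, drop = FALSE], 3L, mean)   # spatial mean
  cam <- matrix(0, d[1], d[2])
  for (c in seq_len(d[3])) cam <- cam + weights[c] * A[, , c, 1L]
  cam <- pmax(cam, 0)
  up <- as_pixels(resize_image(cam / max(max(cam), 1), nrow(as_pixels(image))))
  raw <- up * max(max(cam), 1)
  norm <- if (max(up) > 0) up / max(up) else up
  structure(norm, class = "saliency_map", method = "grad_cam",
            target_class = target_class, raw = raw)
}

#' Occlusion sensitivity map
#'
#' Slides a square patch of constant fill over the image; at each
#' position the map value is the baseline target-class probability minus
#' the probability with that patch occluded. Positive values mark
#' regions whose content supports the class (occluding them lowers
#' confidence); negative values mark confusing regions. Overlapping
#' patch contributions are averaged per pixel.
#'
#' @param model a \code{classifier}.
#' @param image test-transformed pixel matrix at the model input size.
#' @param target_class 1-based class index.
#' @param patch_size occluding patch side in pixels (default 16).
#' @param stride patch step in pixels (default 8).
#' @param fill occluder intensity; defaults to the image mean.
#' @param predict_fn optional function(list of images) -> B x K
#'   probability matrix, for explaining models other than the built-in
#'   classifier.
#' @return a \code{saliency_map} matrix aligned to the input image.
#' @export
occlusion_map <- function(model, image, target_class = 2L,
                          patch_size = 16L, stride = 8L, fill = NULL,
                          predict_fn = NULL) {
  px <- as_pixels(image)
  patch_size <- as.integer(patch_size); stride <- as.integer(stride)
  if (patch_size < 1L || stride < 1L) stop("patch_size and stride must be >= 1")
  H <- nrow(px); W <- ncol(px)
  if (patch_size > H || patch_size > W)
    stop("patch larger than image")
  if (is.null(fill)) fill <- mean(px)
  if (is.null(predict_fn))
    predict_fn <- function(imgs) predict_classifier(model, imgs)
  r_starts <- unique(c(seq(1L, H - patch_size + 1L, by = stride),
                       H - patch_size + 1L))
  c_starts <- unique(c(seq(1L, W - patch_size + 1L, by = stride),
                       W - patch_size + 1L))
  occluded <- list(); pos <- list(); k <- 0L
  for (r0 in r_starts) for (c0 in c_starts) {
    k <- k + 1L
    im <- px
    im[r0:(r0 + patch_size - 1L), c0:(c0 + patch_size - 1L)] <- fill
    occluded[[k]] <- im
    pos[[k]] <- c(r0, c0)
  }
  base_p <- predict_fn(list(px))[1L, target_class]
  occ_p <- predict_fn(occluded)[, target_class]
  acc <- matrix(0, H, W); cnt <- matrix(0, H, W)
  for (k in seq_along(occluded)) {
    r0 <- pos[[k]][1]; c0 <- pos[[k]][2]
    ri <- r0:(r0 + patch_size - 1L); ci <- c0:(c0 + patch_size - 1L)
    acc[ri, ci] <- acc[ri, ci] + (base_p - occ_p[k])
    cnt[ri, ci] <- cnt[ri, ci] + 1
  }
  vals <- ifelse(cnt > 0, acc / cnt, 0)
  structure(vals, class = "saliency_map", method = "occlusion",
            target_class = as.integer(target_class))
}

#' Export a saliency map
#'
#' Writes the map normalized to [0, 1] as an 8-bit grayscale PNG and the
#' raw values as CSV.
#'
#' @param map a \code{saliency_map}.
#' @param png_path,csv_path output paths (either may be \code{NULL}).
#' @return invisibly, the normalized matrix.
#' @export
export_saliency <- function(map, png_path = NULL, csv_path = NULL) {
  vals <- unclass(map)
  attributes(vals) <- list(dim = dim(map))
  rng <- range(vals)
  norm <- if (rng[2] > rng[1]) (vals - rng[1]) / (rng[2] - rng[1])
          else vals * 0
  if (!is.null(png_path)) png::writePNG(norm, png_path)
  if (!is.null(csv_path))
    utils::write.table(vals, csv_path, sep = ",", row.names = FALSE,
                       col.names = FALSE)
  invisible(norm)
}
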