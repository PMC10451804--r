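#' Preprocessing configuration
#'
#' Deterministic test-time transform parameters and stochastic
#' training-time augmentation ranges. Test-time images are resized,
#' histogram normalized, and contrast adjusted with a display gamma of
#' 1.5 (out = in^gamma on [0, 1], darkening midtones). Augmentation
#' defaults emulate the variability of bedside ICU films: rotation within
#' +/-15 degrees, shifts within +/-10% of the image side, scaling in
#' [0.9, 1.1], brightness/contrast jitter within +/-20%, and a 50%
#' left-right flip.
#'
#' @param target_size side length after resizing (>= 32).
#' @param gamma display gamma (> 0). Set \code{invert_gamma = TRUE} to use
#'   the exponent 1/gamma instead.
#' @param invert_gamma apply \code{in^(1/gamma)} rather than
#'   \code{in^gamma}.
#' @param equalize \code{"histogram"} for per-image histogram
#'   equalization, \code{"minmax"} for plain rescaling to [0, 1].
#' @param rotation_deg maximum absolute rotation in degrees.
#' @param shift_frac maximum absolute shift as a fraction of the side.
#' @param scale_range length-2 multiplicative scale interval.
#' @param brightness_delta,contrast_delta maximum absolute jitter.
#' @param flip_prob horizontal flip probability in [0, 1].
#' @return an object of class \code{preprocess_config}.
#' @export
preprocess_config <- function(target_size = 256L,
                              gamma = 1.5,
                              invert_gamma = FALSE,
                              equalize = c("histogram", "minmax"),
                              rotation_deg = 15,
                              shift_frac = 0.10,
                              scale_range = c(0.9, 1.1),
                              brightness_delta = 0.2,
                              contrast_delta = 0.2,
                              flip_prob = 0.5) {
  equalize <- match.arg(equalize)
  target_size <- as.integer(target_size)
  if (is.na(target_size) || target_size < 32L) stop("target_size must be >= 32")
  if (!is.numeric(gamma) || gamma <= 0) stop("gamma must be > 0")
  if (flip_prob < 0 || flip_prob > 1) stop("flip_prob must lie in [0, 1]")
  structure(list(target_size = target_size, gamma = gamma,
                 invert_gamma = invert_gamma, equalize = equalize,
                 rotation_deg = rotation_deg, shift_frac = shift_frac,
                 scale_range = scale_range,
                 brightness_delta = brightness_delta,
                 contrast_delta = contrast_delta, flip_prob = flip_prob),
            class = "preprocess_config")
}

# Rebuild an image_record around transformed pixels, or return the bare
# matrix if a matrix came in.
.rewrap <- function(image, pixels) {
  if (inherits(image, "image_record"))
    image_record(pixels, image$patient_id, image$image_id)
  else pixels
}

#' Histogram normalization
#'
#' Global histogram equalization: each intensity maps to its empirical
#' CDF value, so the output distribution is approximately uniform on
#' [0, 1] and the rank order of distinct intensities is preserved. A
#' constant image is returned unchanged with a warning (its CDF is
#' degenerate).
#'
#' @param image an \code{image_record} or pixel matrix in [0, 1].
#' @return transformed image of the same type and shape.
#' @export
normalize_histogram <- function(image) {
  px <- as_pixels(image)
  if (length(px) == 0L) stop("empty image")
  rng <- range(px)
  if (rng[1] == rng[2]) {
    warning("constant image: histogram normalization is a no-op")
    return(.rewrap(image, px))
  }
  out <- matrix(stats::ecdf(px)(px), nrow(px), ncol(px))
  .rewrap(image, out)
}

# Min-max rescale alternative to equalization.
normalize_minmax <- function(image) {
  px <- as_pixels(image)
  rng <- range(px)
  if (rng[1] == rng[2]) {
    warning("constant image: min-max normalization is a no-op")
    return(.rewrap(image, px))
  }
  .rewrap(image, (px - rng[1]) / (rng[2] - rng[1]))
}

#' Gamma contrast adjustment
#'
#' \code{out = in^gamma} elementwise on [0, 1]; strictly monotone on
#' (0, 1) and fixing 0 and 1 for any positive gamma.
#'
#' @param image an \code{image_record} or pixel matrix in [0, 1].
#' @param gamma positive exponent (default 1.5).
#' @return transformed image.
#' @export
adjust_gamma <- function(image, gamma = 1.5) {
  if (!is.numeric(gamma) || length(gamma) != 1L || gamma <= 0)
    stop("gamma must be a single positive real")
  px <- as_pixels(image)
  .rewrap(image, px^gamma)
}

# Vectorized bilinear sampling of img at fractional (row, col) positions
# (align-corners convention; coordinates outside the grid are clamped).
.bilinear_sample <- function(img, rows, cols) {
  H <- nrow(img); W <- ncol(img)
  rows <- pmin(pmax(rows, 1), H)
  cols <- pmin(pmax(cols, 1), W)
  r0 <- floor(rows); c0 <- floor(cols)
  r1 <- pmin(r0 + 1, H); c1 <- pmin(c0 + 1, W)
  fr <- rows - r0; fc <- cols - c0
  img[cbind(r0, c0)] * (1 - fr) * (1 - fc) +
    img[cbind(r1, c0)] * fr * (1 - fc) +
    img[cbind(r0, c1)] * (1 - fr) * fc +
    img[cbind(r1, c1)] * fr * fc
}

#' Bilinear resize
#'
#' Resizes to \code{target_size x target_size} with bilinear
#' interpolation under the align-corners convention, so corner pixels are
#' preserved exactly and resizing to the input size is the identity.
#'
#' @param image an \code{image_record} or pixel matrix.
#' @param target_size output side length (> 0).
#' @return resized image, values clipped to [0, 1].
#' @export
resize_image <- function(image, target_size) {
  target_size <- as.integer(target_size)
  if (is.na(target_size) || target_size <= 0L) stop("target_size must be > 0")
  px <- as_pixels(image)
  H <- nrow(px); W <- ncol(px)
  src_r <- if (target_size == 1L) rep((H + 1) / 2, 1L)
           else 1 + (seq_len(target_size) - 1) * (H - 1) / (target_size - 1)
  src_c <- if (target_size == 1L) rep((W + 1) / 2, 1L)
           else 1 + (seq_len(target_size) - 1) * (W - 1) / (target_size - 1)
  rows <- matrix(src_r, target_size, target_size)
  cols <- matrix(src_c, target_size, target_size, byrow = TRUE)
  out <- matrix(.bilinear_sample(px, as.vector(rows), as.vector(cols)),
                target_size, target_size)
  .rewrap(image, pmin(pmax(out, 0), 1))
}

# Apply an inverse-mapped affine warp about the image center:
# rotation (degrees, counterclockwise), isotropic scale, then shift
# (fractions of the side). Bilinear sampling, edge-clamped.
.affine_warp <- function(px, rot_deg = 0, scale = 1, shift_r = 0, shift_c = 0) {
  H <- nrow(px); W <- ncol(px)
  cr <- (H + 1) / 2; cc <- (W + 1) / 2
  th <- rot_deg * pi / 180
  # inverse transform: undo shift, then undo rotation+scale
  gr <- matrix(seq_len(H), H, W) - cr - shift_r * H
  gc <- matrix(seq_len(W), H, W, byrow = TRUE) - cc - shift_c * W
  inv_s <- 1 / scale
  src_r <- (cos(th) * gr + sin(th) * gc) * inv_s + cr
  src_c <- (-sin(th) * gr + cos(th) * gc) * inv_s + cc
  matrix(.bilinear_sample(px, as.vector(src_r), as.vector(src_c)), H, W)
}

#' Stochastic training augmentation
#'
#' Applies, in order: random rotation, horizontal flip, affine shift,
#' scale, then brightness and contrast jitter, all drawn uniformly from
#' the configured ranges. Deterministic given the seed; output is clipped
#' to [0, 1] and keeps the input size. With all ranges zero and flip
#' probability zero the transform is the identity.
#'
#' @param image an \code{image_record} or pixel matrix in [0, 1].
#' @param config a \code{preprocess_config}.
#' @param seed integer seed.
#' @return augmented image.
#' @export
augment_image <- function(image, config = preprocess_config(), seed = 1L) {
  px <- as_pixels(image)
  set.seed(as.integer(seed))
  rot <- stats::runif(1L, -config$rotation_deg, config$rotation_deg)
  flip <- stats::runif(1L) < config$flip_prob
  sh_r <- stats::runif(1L, -config$shift_frac, config$shift_frac)
  sh_c <- stats::runif(1L, -config$shift_frac, config$shift_frac)
  sc <- stats::runif(1L, config$scale_range[1], config$scale_range[2])
  br <- stats::runif(1L, -config$brightness_delta, config$brightness_delta)
  co <- stats::runif(1L, -config$contrast_delta, config$contrast_delta)

  if (rot != 0 || sh_r != 0 || sh_c != 0 || sc != 1)
    px <- .affine_warp(px, rot, sc, sh_r, sh_c)
  if (flip) px <- px[, rev(seq_len(ncol(px))), drop = FALSE]
  px <- (px - 0.5) * (1 + co) + 0.5 + br
  .rewrap(image, pmin(pmax(px, 0), 1))
}

#' Deterministic test-time transform
#'
#' The inference pipeline: resize to the target size, histogram
#' normalization, then gamma contrast adjustment. A pure function of the
#' input — no randomness, no hidden state.
#'
#' @param image an \code{image_record} or pixel matrix in [0, 1].
#' @param config a \code{preprocess_config}.
#' @return model-ready pixel matrix (or \code{image_record}) of size
#'   \code{target_size x target_size} with values in [0, 1].
#' @export
test_transform <- function(image, config = preprocess_config()) {
  out <- resize_image(image, config$target_size)
  out <- if (config$equalize == "histogram") normalize_histogram(out)
         else normalize_minmax(out)
  g <- if (config$invert_gamma) 1 / config$gamma else config$gamma
  adjust_gamma(out, g)
}
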