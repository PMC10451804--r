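ANNOTATOR_LEVELS <- c("bilateral", "left_lung", "right_lung", "absent",
                      "equivocal")

#' Phantom generator configuration
#'
#' Parameters of the synthetic chest-radiograph phantom: a body ellipse,
#' two darker lung fields, optional bright opacity blobs confined to one
#' or both lungs, bright line/rectangle occluders emulating support
#' devices, additive Gaussian noise, and a degradation control that
#' collapses contrast and occludes lung area the way an uninterpretable
#' bedside film does.
#'
#' @param image_size side length in pixels (>= 32).
#' @param opacity_mode one of \code{"absent"}, \code{"left"},
#'   \code{"right"}, \code{"bilateral"}.
#' @param opacity_intensity blob amplitude as a fraction of dynamic range.
#' @param opacity_count_per_lung blobs drawn per designated lung.
#' @param occluder_count bright device artifacts (lines/rectangles).
#' @param degradation_level 0 (clean) to 1 (uninterpretable); at or above
#'   \code{equivocal_threshold} the intended truth label becomes
#'   \code{"equivocal"}.
#' @param noise_sd standard deviation of additive Gaussian noise.
#' @param equivocal_threshold degradation level from which an image is
#'   considered unreadable.
#' @param seed integer seed; phantoms are bit-reproducible given the seed.
#' @return an object of class \code{phantom_config}.
#' @export
phantom_config <- function(image_size = 64L,
                           opacity_mode = c("absent", "left", "right",
                                            "bilateral"),
                           opacity_intensity = 0.35,
                           opacity_count_per_lung = 2L,
                           occluder_count = 1L,
                           degradation_level = 0,
                           noise_sd = 0.02,
                           equivocal_threshold = 0.7,
                           seed = 1L) {
  opacity_mode <- match.arg(opacity_mode)
  image_size <- as.integer(image_size)
  if (is.na(image_size) || image_size < 32L)
    stop("image_size must be an integer >= 32")
  stopifnot(opacity_intensity >= 0, opacity_intensity <= 1,
            opacity_count_per_lung >= 0, occluder_count >= 0,
            degradation_level >= 0, degradation_level <= 1,
            noise_sd >= 0)
  structure(list(image_size = image_size, opacity_mode = opacity_mode,
                 opacity_intensity = opacity_intensity,
                 opacity_count_per_lung = as.integer(opacity_count_per_lung),
                 occluder_count = as.integer(occluder_count),
                 degradation_level = degradation_level,
                 noise_sd = noise_sd,
                 equivocal_threshold = equivocal_threshold,
                 seed = as.integer(seed)),
            class = "phantom_config")
}

#' Image record
#'
#' A grayscale intensity grid in [0, 1] with patient and image identifiers.
#'
#' @param pixels numeric matrix with values in [0, 1].
#' @param patient_id,image_id identifier strings.
#' @return an object of class \code{image_record}.
#' @export
image_record <- function(pixels, patient_id = "p0", image_id = "i0") {
  if (!is.matrix(pixels) || length(pixels) == 0L)
    stop("pixels must be a non-empty matrix")
  if (anyNA(pixels) || min(pixels) < 0 || max(pixels) > 1)
    stop("pixel values must lie in [0, 1]")
  structure(list(pixels = pixels,
                 patient_id = as.character(patient_id),
                 image_id = as.character(image_id)),
            class = "image_record")
}

# Accept either a bare matrix or an image_record.
as_pixels <- function(image) {
  if (inherits(image, "image_record")) image$pixels
  else if (is.matrix(image)) image
  else stop("expected an image_record or a numeric matrix")
}

# Elliptical mask on an n x n unit grid.
.ellipse_mask <- function(n, cx, cy, rx, ry) {
  u <- (seq_len(n) - 0.5) / n
  X <- matrix(u, n, n, byrow = TRUE)  # columns index x
  Y <- matrix(u, n, n)                # rows index y
  ((X - cx) / rx)^2 + ((Y - cy) / ry)^2 <= 1
}

#' Generate one synthetic chest phantom
#'
#' Renders the phantom described in \code{\link{phantom_config}} and
#' returns the image, the intended annotator-level truth label, and the
#' two lung-field masks. Opacity blobs are Gaussian bumps strictly
#' confined to the designated lung masks, so for any fixed seed a
#' bilateral phantom is pointwise at least as bright inside each lung as
#' its opacity-free counterpart.
#'
#' @param config a \code{phantom_config}.
#' @param patient_id,image_id identifiers stored in the record.
#' @return a list with elements \code{image} (an \code{image_record}),
#'   \code{truth} (annotator-level label string), \code{left_mask},
#'   \code{right_mask} (logical matrices), and \code{config}.
#' @export
generate_phantom <- function(config, patient_id = "p0", image_id = "i0") {
  if (!inherits(config, "phantom_config")) stop("config must be a phantom_config")
  n <- config$image_size

  # Deterministic layout; separate RNG streams per stage so that phantoms
  # differing only in opacity_mode share body, occluders and noise.
  base <- matrix(0.05, n, n)
  body <- .ellipse_mask(n, 0.50, 0.52, 0.42, 0.46)
  base[body] <- 0.45
  left_mask <- .ellipse_mask(n, 0.32, 0.45, 0.16, 0.26) & body
  right_mask <- .ellipse_mask(n, 0.68, 0.45, 0.16, 0.26) & body
  base[left_mask | right_mask] <- 0.20

  u <- (seq_len(n) - 0.5) / n
  X <- matrix(u, n, n, byrow = TRUE)
  Y <- matrix(u, n, n)

  # Opacity blobs (their own stream so absent/bilateral pairs match
  # elsewhere).
  lungs <- switch(config$opacity_mode,
                  absent = character(0),
                  left = "left", right = "right",
                  bilateral = c("left", "right"))
  if (length(lungs) > 0 && config$opacity_count_per_lung > 0) {
    set.seed(config$seed + 9973L)
    for (side in lungs) {
      mask <- if (side == "left") left_mask else right_mask
      idx <- which(mask)
      for (b in seq_len(config$opacity_count_per_lung)) {
        ctr <- idx[sample.int(length(idx), 1L)]
        cy <- ((ctr - 1L) %% n + 0.5) / n
        cx <- ((ctr - 1L) %/% n + 0.5) / n
        sigma <- stats::runif(1L, 0.05, 0.09)
        blob <- config$opacity_intensity *
          exp(-(((X - cx)^2 + (Y - cy)^2)) / (2 * sigma^2))
        blob[!mask] <- 0
        base <- base + blob
      }
    }
  }

  # Occluding devices: bright thin lines or small rectangles.
  if (config$occluder_count > 0) {
    set.seed(config$seed + 7919L)
    for (k in seq_len(config$occluder_count)) {
      if (stats::runif(1L) < 0.5) {
        # line from a random edge point across the body
        x0 <- stats::runif(1L); y0 <- stats::runif(1L)
        ang <- stats::runif(1L, 0, pi)
        tt <- seq(-1, 1, length.out = 2L * n)
        px <- pmin(pmax(round((x0 + tt * cos(ang)) * n), 1L), n)
        py <- pmin(pmax(round((y0 + tt * sin(ang)) * n), 1L), n)
        base[cbind(py, px)] <- 0.92
      } else {
        rw <- max(2L, round(n * 0.05)); rh <- max(2L, round(n * 0.03))
        r0 <- sample.int(n - rh, 1L); c0 <- sample.int(n - rw, 1L)
        base[r0:(r0 + rh), c0:(c0 + rw)] <- 0.90
      }
    }
  }

  # Degradation: contrast collapse toward mid-gray plus a gray occluding
  # band over the lungs, scaled by degradation_level.
  d <- config$degradation_level
  if (d > 0) {
    set.seed(config$seed + 4409L)
    base <- base * (1 - 0.8 * d) + 0.5 * 0.8 * d
    band_h <- round(n * 0.45 * d)
    if (band_h >= 1) {
      r0 <- sample.int(max(n - band_h, 1L), 1L)
      rows <- r0:min(r0 + band_h, n)
      base[rows, ] <- base[rows, ] * (1 - 0.9 * d) + 0.55 * 0.9 * d
    }
  }

  if (config$noise_sd > 0) {
    set.seed(config$seed + 1021L)
    base <- base + matrix(stats::rnorm(n * n, 0, config$noise_sd), n, n)
  }
  base <- pmin(pmax(base, 0), 1)

  truth <- if (d >= config$equivocal_threshold) "equivocal"
  else switch(config$opacity_mode,
              absent = "absent", left = "left_lung",
              right = "right_lung", bilateral = "bilateral")

  list(image = image_record(base, patient_id, image_id),
       truth = truth, left_mask = left_mask, right_mask = right_mask,
       config = config)
}

# Default confusion kernel: which labels an annotator may mistakenly
# report for a given truth. Uniform over the set.
.confusion_kernel <- list(
  bilateral  = c("left_lung", "right_lung", "equivocal"),
  left_lung  = c("bilateral", "absent", "equivocal"),
  right_lung = c("bilateral", "absent", "equivocal"),
  absent     = c("left_lung", "right_lung", "equivocal"),
  equivocal  = c("bilateral", "left_lung", "right_lung", "absent"))

#' Simulate a three-annotator panel
#'
#' Each of three blinded annotators independently reports the truth with
#' probability \code{1 - difficulty}; otherwise a label drawn uniformly
#' from a plausibility-restricted confusion kernel (e.g. a bilateral image
#' may be misread as left-, right-sided or equivocal, never as cleanly
#' absent).
#'
#' @param truth annotator-level truth label.
#' @param difficulty per-annotator error probability in [0, 1].
#' @param seed integer seed.
#' @return character vector of three labels (class \code{annotator_panel}).
#' @export
simulate_annotators <- function(truth, difficulty = 0.1, seed = 1L) {
  if (!truth %in% ANNOTATOR_LEVELS) stop("unknown truth label: ", truth)
  if (!is.numeric(difficulty) || difficulty < 0 || difficulty > 1)
    stop("difficulty must lie in [0, 1]")
  set.seed(as.integer(seed))
  panel <- vapply(1:3, function(a) {
    if (stats::runif(1L) < difficulty) {
      pool <- .confusion_kernel[[truth]]
      pool[sample.int(length(pool), 1L)]
    } else truth
  }, character(1))
  structure(panel, class = "annotator_panel")
}

#' Adjudicate a three-annotator panel
#'
#' Resolves three annotator labels into the three-class ground truth:
#' \enumerate{
#'   \item if at least two annotators gave the identical label, that label
#'     is the ground truth (bilateral maps to \code{"present"};
#'     left/right/absent map to \code{"absent"} since unilateral opacities
#'     are not bilateral; equivocal stays \code{"equivocal"});
#'   \item otherwise, if all three labels assert opacities are present
#'     (some of bilateral/left/right), the image is \code{"present"};
#'   \item otherwise the three-way disagreement is \code{"equivocal"}.
#' }
#'
#' @param panel character vector of exactly three annotator labels.
#' @return one of \code{"absent"}, \code{"present"}, \code{"equivocal"}.
#' @export
adjudicate <- function(panel) {
  panel <- as.character(panel)
  if (length(panel) != 3L) stop("panel must contain exactly three labels")
  if (!all(panel %in% ANNOTATOR_LEVELS))
    stop("unknown annotator label(s): ",
         paste(setdiff(panel, ANNOTATOR_LEVELS), collapse = ", "))
  counts <- table(panel)
  if (max(counts) >= 2L) {
    maj <- names(counts)[which.max(counts)]
    return(switch(maj,
                  bilateral = "present",
                  left_lung = "absent",
                  right_lung = "absent",
                  absent = "absent",
                  equivocal = "equivocal"))
  }
  if (all(panel %in% c("bilateral", "left_lung", "right_lung")))
    return("present")
  "equivocal"
}

#' Generate a labeled synthetic dataset
#'
#' Draws adjudicated-class targets from a class mix (defaults to the
#' long-tailed prevalence of a septic ICU cohort: 54\% present, 23\%
#' absent, 23\% equivocal), renders one phantom per image, simulates a
#' three-annotator panel per image and adjudicates it. Present images are
#' bilateral phantoms; absent images are drawn from clean, left- or
#' right-sided phantoms; equivocal images are heavily degraded phantoms.
#'
#' @param n_patients number of patients (> 0).
#' @param images_per_patient integer range \code{c(min, max)}.
#' @param class_mix nonnegative weights over (present, absent, equivocal);
#'   normalized internally.
#' @param difficulty annotator error probability.
#' @param image_size phantom side length in pixels.
#' @param seed integer seed; the dataset is reproducible bit-exactly.
#' @param noise_sd,opacity_intensity passed to \code{\link{phantom_config}}.
#' @param occluder_range integer range \code{c(min, max)} of occluding
#'   devices per image; \code{c(0, 0)} renders clean films.
#' @param unilateral_in_absent include unilateral-opacity phantoms in the
#'   absent class (the clinically realistic default); \code{FALSE} makes
#'   the negative class opacity-free, for easy recovery-style datasets.
#' @param normal_degradation,equivocal_degradation uniform ranges from
#'   which the degradation level is drawn for readable and equivocal
#'   images. Image quality is a continuum: the readable range reaches
#'   close to the equivocal threshold so borderline films are genuinely
#'   ambiguous, and equivocal films sit just past it — degraded enough
#'   that no reading is certain, but with any opacities still partially
#'   visible, as on bedside ICU radiographs.
#' @param equivocal_mode_mix named weights over the underlying opacity
#'   modes of equivocal films. Defaults favour opacity-bearing films: an
#'   equivocal read typically means suspected opacities whose extent or
#'   bilaterality cannot be confirmed, not pristine lungs behind a poor
#'   film.
#' @return a list with \code{manifest} (data.frame: patient_id, image_id,
#'   annotator1..3, truth, adjudicated_label), \code{images} (named list of
#'   pixel matrices), and \code{masks} (per-image lung masks).
#' @export
generate_dataset <- function(n_patients = 50L,
                             images_per_patient = c(1L, 3L),
                             class_mix = c(present = 0.54, absent = 0.23,
                                           equivocal = 0.23),
                             difficulty = 0.1,
                             image_size = 64L,
                             seed = 1L,
                             noise_sd = 0.02,
                             opacity_intensity = 0.35,
                             occluder_range = c(0L, 2L),
                             unilateral_in_absent = TRUE,
                             normal_degradation = c(0, 0.6),
                             equivocal_degradation = c(0.7, 0.8),
                             equivocal_mode_mix = c(bilateral = 0.5,
                                                    left = 0.2, right = 0.2,
                                                    absent = 0.1)) {
  n_patients <- as.integer(n_patients)
  if (is.na(n_patients) || n_patients <= 0L) stop("n_patients must be > 0")
  if (any(class_mix < 0) || sum(class_mix) <= 0)
    stop("class_mix must be nonnegative with positive sum")
  mix <- class_mix / sum(class_mix)
  set.seed(as.integer(seed))
  rows <- list(); images <- list(); masks <- list()
  img_counter <- 0L
  for (p in seq_len(n_patients)) {
    n_img <- images_per_patient[1] +
      sample.int(images_per_patient[2] - images_per_patient[1] + 1L, 1L) - 1L
    for (j in seq_len(n_img)) {
      img_counter <- img_counter + 1L
      cls <- sample(c("present", "absent", "equivocal"), 1L, prob = mix)
      mode <- switch(cls,
                     present = "bilateral",
                     absent = if (unilateral_in_absent)
                       sample(c("absent", "left", "right"), 1L,
                              prob = c(0.5, 0.25, 0.25)) else "absent",
                     equivocal = sample(c("bilateral", "left", "right",
                                          "absent"), 1L,
                                        prob = equivocal_mode_mix[
                                          c("bilateral", "left", "right",
                                            "absent")]))
      degr <- if (cls == "equivocal")
        stats::runif(1L, equivocal_degradation[1], equivocal_degradation[2])
      else stats::runif(1L, normal_degradation[1], normal_degradation[2])
      img_seed <- sample.int(2^30, 1L)
      cfg <- phantom_config(image_size = image_size, opacity_mode = mode,
                            opacity_intensity = opacity_intensity,
                            occluder_count = sample(
                              occluder_range[1]:occluder_range[2], 1L),
                            degradation_level = degr,
                            noise_sd = noise_sd, seed = img_seed)
      pid <- sprintf("patient_%04d", p)
      iid <- sprintf("image_%05d", img_counter)
      ph <- generate_phantom(cfg, patient_id = pid, image_id = iid)
      # The class mix describes *adjudicated* prevalences (what a labeled
      # cohort reports), so the panel is drawn from the annotator error
      # model conditioned on adjudicating to the intended class; a
      # unanimous panel is the (rare) fallback.
      panel <- simulate_annotators(ph$truth, difficulty,
                                   seed = sample.int(2^30, 1L))
      tries <- 1L
      while (adjudicate(panel) != cls && tries < 20L) {
        panel <- simulate_annotators(ph$truth, difficulty,
                                     seed = sample.int(2^30, 1L))
        tries <- tries + 1L
      }
      if (adjudicate(panel) != cls)
        panel <- structure(rep(ph$truth, 3L), class = "annotator_panel")
      rows[[img_counter]] <- data.frame(
        patient_id = pid, image_id = iid,
        annotator1 = panel[1], annotator2 = panel[2], annotator3 = panel[3],
        truth = ph$truth, adjudicated_label = adjudicate(panel),
        stringsAsFactors = FALSE)
      images[[iid]] <- ph$image$pixels
      masks[[iid]] <- list(left = ph$left_mask, right = ph$right_mask)
    }
  }
  list(manifest = do.call(rbind, rows), images = images, masks = masks)
}

#' Write a dataset to disk
#'
#' Writes 8-bit grayscale PNGs, a CSV manifest (with an image_path
#' column), and a JSON sidecar echoing the generator parameters.
#'
#' @param dataset result of \code{\link{generate_dataset}}.
#' @param dir output directory (created if needed).
#' @param params generator parameters to echo into the sidecar.
#' @return the manifest data.frame (invisibly), with image paths.
#' @export
write_dataset <- function(dataset, dir, params = list()) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  img_dir <- file.path(dir, "images")
  dir.create(img_dir, showWarnings = FALSE)
  man <- dataset$manifest
  man$image_path <- file.path("images", paste0(man$image_id, ".png"))
  for (iid in names(dataset$images)) {
    png::writePNG(dataset$images[[iid]],
                  file.path(img_dir, paste0(iid, ".png")))
  }
  utils::write.csv(man, file.path(dir, "manifest.csv"), row.names = FALSE)
  jsonlite::write_json(params, file.path(dir, "generator_params.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(man)
}

#' Read a dataset written by \code{write_dataset}
#'
#' @param dir dataset directory containing \code{manifest.csv}.
#' @return a list with \code{manifest} and \code{images}.
#' @export
read_dataset <- function(dir) {
  man <- utils::read.csv(file.path(dir, "manifest.csv"),
                         stringsAsFactors = FALSE)
  images <- lapply(seq_len(nrow(man)), function(i) {
    px <- png::readPNG(file.path(dir, man$image_path[i]))
    if (length(dim(px)) == 3L) px <- px[, , 1L]
    px
  })
  names(images) <- man$image_id
  list(manifest = man, images = images)
}
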