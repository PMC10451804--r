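# End-to-end experiment orchestration: generate phantoms, split by
# patient, train the configured scheme(s), evaluate, calibrate, render a
# saliency example, and assemble a comparison report.

#' Experiment configuration
#'
#' Bundles every stage's options with a single global seed that
#' propagates deterministically to data generation, splitting, training,
#' bootstrap and saliency sampling.
#'
#' @param n_patients,images_per_patient,class_mix,difficulty,noise_sd
#'   synthetic dataset options (see \code{\link{generate_dataset}}).
#' @param image_size phantom and model input side length (multiple of
#'   16).
#' @param schemes character vector of training schemes to run.
#' @param losses named list mapping scheme name to a list of
#'   \code{\link{loss_config}}s, or a single list applied to every
#'   scheme.
#' @param epochs,learning_rate,batch_size,augment training options
#'   (from-scratch small_cnn default learning rate 1e-3).
#' @param train_fraction patient-level split fraction.
#' @param bootstrap_B,bootstrap_level evaluation options.
#' @param n_bins calibration bins.
#' @param saliency_examples number of test images to render maps for.
#' @param out_dir output directory, or \code{NULL} for in-memory only.
#' @param seed global integer seed.
#' @return an object of class \code{experiment_config}.
#' @export
experiment_config <- function(n_patients = 120L,
                              images_per_patient = c(1L, 3L),
                              class_mix = c(present = 0.54, absent = 0.23,
                                            equivocal = 0.23),
                              difficulty = 0.1,
                              noise_sd = 0.02,
                              image_size = 64L,
                              schemes = c("three_class", "two_class"),
                              losses = list(
                                three_class = loss_config("uncertainty_ce"),
                                two_class = loss_config("cross_entropy")),
                              epochs = 8L,
                              learning_rate = 1e-3,
                              batch_size = 32L,
                              augment = TRUE,
                              train_fraction = 0.7,
                              bootstrap_B = 200L,
                              bootstrap_level = 0.95,
                              n_bins = 10L,
                              saliency_examples = 2L,
                              out_dir = NULL,
                              seed = 1L) {
  structure(as.list(environment()), class = "experiment_config")
}

# Losses applicable to a scheme (uncertainty targets need 3 classes).
.losses_for_scheme <- function(config, scheme) {
  ls <- config$losses
  if (!is.null(names(ls)) && scheme %in% names(ls)) ls <- ls[[scheme]]
  if (inherits(ls, "loss_config")) ls <- list(ls)
  Filter(function(l) !(l$kind == "uncertainty_ce" && scheme != "three_class"),
         ls)
}

#' Run a full experiment
#'
#' Generates a synthetic dataset, applies the deterministic test
#' transform at the model input size, splits by patient, then for every
#' scheme x loss combination trains a small CNN, evaluates the present
#' class with bootstrap CIs, computes calibration bins and MCE, and
#' renders Grad-CAM and occlusion maps for a few test images. When
#' \code{out_dir} is set, writes a metrics JSON, per-run history and
#' reliability CSVs, and saliency PNGs, all stamped with the seed and a
#' config hash.
#'
#' @param config an \code{\link{experiment_config}}.
#' @param verbose print progress.
#' @return an experiment report: list with \code{runs} (per scheme/loss:
#'   eval report, calibration, history), \code{comparison} (the
#'   \code{\link{compare_schemes}} table), \code{split} sizes and
#'   \code{seed}.
#' @export
run_experiment <- function(config = experiment_config(), verbose = FALSE) {
  stage <- function(what, expr) {
    tryCatch(expr, error = function(e)
      stop("experiment stage [", what, "] failed: ", conditionMessage(e),
           call. = FALSE))
  }
  ds <- stage("generate", generate_dataset(
    n_patients = config$n_patients,
    images_per_patient = config$images_per_patient,
    class_mix = config$class_mix, difficulty = config$difficulty,
    image_size = config$image_size, seed = config$seed,
    noise_sd = config$noise_sd))
  pp <- preprocess_config(target_size = config$image_size)
  imgs <- stage("preprocess", lapply(ds$images, function(m)
    suppressWarnings(test_transform(m, pp))))
  sp <- stage("split", split_patients(ds$manifest,
                                      train_fraction = config$train_fraction,
                                      seed = config$seed + 1L))
  runs <- list()
  for (scheme in config$schemes) {
    tr_man <- prepare_labels(sp$train, scheme)
    te_man <- prepare_labels(sp$test, scheme)
    n_classes <- if (scheme == "three_class") 3L else 2L
    for (lc in .losses_for_scheme(config, scheme)) {
      run_id <- paste(scheme, lc$kind, sep = ".")
      if (verbose) message("training ", run_id)
      tc <- train_config(scheme = scheme, loss = lc,
                         epochs = config$epochs,
                         learning_rate = config$learning_rate,
                         batch_size = config$batch_size,
                         augment = config$augment,
                         augment_config = pp,
                         seed = config$seed + 7L)
      model <- build_model("small_cnn", n_classes = n_classes,
                           input_size = config$image_size,
                           seed = config$seed + 13L)
      fit <- stage(paste0("train:", run_id),
                   train_classifier(model, imgs[tr_man$image_id],
                                    tr_man$class_index, tc))
      probs <- stage(paste0("predict:", run_id),
                     predict_classifier(fit$model, imgs[te_man$image_id]))
      report <- stage(paste0("evaluate:", run_id), suppressWarnings(
        evaluate_classifier(truth_labels = te_man$adjudicated_label,
                            probs = probs, B = config$bootstrap_B,
                            level = config$bootstrap_level,
                            seed = config$seed + 17L)))
      bins <- stage(paste0("calibrate:", run_id),
                    bin_confidences(probs, truth = te_man$class_index,
                                    n_bins = config$n_bins))
      runs[[run_id]] <- list(scheme = scheme, loss = lc$kind,
                             model = fit$model, history = fit$history,
                             report = report, bins = bins,
                             mce = suppressWarnings(mce(bins)),
                             test_ids = te_man$image_id)
    }
  }
  # saliency examples from the last run's test set
  saliency <- list()
  if (config$saliency_examples > 0L && length(runs) > 0L) {
    last <- runs[[length(runs)]]
    set.seed(config$seed + 23L)
    ids <- last$test_ids[sample.int(length(last$test_ids),
                                    min(config$saliency_examples,
                                        length(last$test_ids)))]
    saliency <- stage("explain", lapply(ids, function(iid) {
      list(image_id = iid,
           grad_cam = grad_cam(last$model, imgs[[iid]], target_class = 2L),
           occlusion = occlusion_map(last$model, imgs[[iid]],
                                     target_class = 2L))
    }))
  }
  # runs under the disregard-equivocal scheme see a reduced test set and
  # cannot be compared head-to-head; keep the majority split group
  sig <- vapply(runs, function(r) paste(sort(r$test_ids), collapse = ","),
                character(1))
  main_sig <- names(sort(table(sig), decreasing = TRUE))[1]
  if (any(sig != main_sig))
    warning("excluding ", sum(sig != main_sig),
            " run(s) evaluated on a different test split from the comparison")
  comparison <- compare_schemes(runs[sig == main_sig])
  result <- list(runs = runs, comparison = comparison,
                 split = list(n_train = nrow(sp$train),
                              n_test = nrow(sp$test)),
                 seed = config$seed)
  if (!is.null(config$out_dir)) .write_report(result, config, saliency)
  result$saliency <- saliency
  result
}

# Serialize the report bundle under config$out_dir.
.write_report <- function(result, config, saliency) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  cfg_plain <- config; class(cfg_plain) <- NULL
  cfg_plain <- cfg_plain[!vapply(cfg_plain, is.function, logical(1))]
  cfg_plain$losses <- lapply(config$losses, function(l) unclass(l))
  hash <- sprintf("%08x", sum(utf8ToInt(paste(
    deparse(cfg_plain), collapse = "")) * 31L %% 2147483647L))
  metrics <- lapply(result$runs, function(r)
    list(scheme = r$scheme, loss = r$loss, mce = r$mce,
         metrics = stats::setNames(as.list(r$report$point),
                                   r$report$metric)))
  jsonlite::write_json(list(schema_version = 1L, seed = result$seed,
                            config_hash = hash, runs = metrics),
                       file.path(config$out_dir, "metrics.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  utils::write.csv(result$comparison,
                   file.path(config$out_dir, "comparison.csv"),
                   row.names = FALSE)
  for (id in names(result$runs)) {
    r <- result$runs[[id]]
    utils::write.csv(r$history,
                     file.path(config$out_dir, paste0("history_", id, ".csv")),
                     row.names = FALSE)
    utils::write.csv(reliability_table(r$bins),
                     file.path(config$out_dir,
                               paste0("reliability_", id, ".csv")),
                     row.names = FALSE)
  }
  for (s in saliency) {
    export_saliency(s$grad_cam,
                    png_path = file.path(config$out_dir,
                                         paste0("gradcam_", s$image_id,
                                                ".png")))
    export_saliency(s$occlusion,
                    png_path = file.path(config$out_dir,
                                         paste0("occlusion_", s$image_id,
                                                ".png")))
  }
  invisible(NULL)
}

#' Scheme comparison table
#'
#' One row per scheme x loss with the eight diagnostic metrics plus MCE,
#' ordered deterministically by scheme then loss.
#'
#' @param runs the \code{runs} element of a \code{\link{run_experiment}}
#'   result (or the result itself).
#' @return data.frame comparison table.
#' @export
compare_schemes <- function(runs) {
  if (!is.null(runs$runs)) runs <- runs$runs
  if (length(runs) < 1L) stop("no runs to compare")
  ids <- vapply(runs, function(r) paste(r$scheme, r$loss), character(1))
  test_sets <- lapply(runs, function(r) r$test_ids)
  if (length(unique(vapply(test_sets, function(x)
    paste(sort(x), collapse = ","), character(1)))) > 1L)
    stop("runs were evaluated on different test splits")
  rows <- lapply(runs, function(r) {
    pts <- stats::setNames(r$report$point, r$report$metric)
    data.frame(scheme = r$scheme, loss = r$loss,
               t(pts), mce = r$mce, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$scheme, out$loss), , drop = FALSE]
  rownames(out) <- NULL
  out
}
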