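#' Published benchmark operating points
#'
#' Sensitivity/specificity operating points (with their printed balanced
#' accuracies) reported for bilateral-opacity classifiers trained under
#' each scheme/loss combination on a clinical ICU cohort. Useful as
#' worked examples for the diagnostic-metric formulas: balanced accuracy
#' recomputed from each row's sensitivity and specificity matches the
#' printed cell to within rounding.
#'
#' @return data.frame with experiment, loss, sensitivity, specificity
#'   and the printed balanced accuracy.
#' @export
reference_operating_points <- function() {
  utils::read.csv(system.file("extdata", "reference_operating_points.csv",
                              package = "opaxr"),
                  stringsAsFactors = FALSE)
}
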