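# Shared fixtures, generated in code at test time.

# Independent rule-by-rule adjudication oracle: counts label multiplicities
# explicitly and applies the three rules by direct case analysis, written
# without reference to the package implementation.
oracle_adjudicate <- function(panel) {
  to_class <- c(bilateral = "present", left_lung = "absent",
                right_lung = "absent", absent = "absent",
                equivocal = "equivocal")
  for (lab in unique(panel)) {
    if (sum(panel == lab) >= 2) return(unname(to_class[lab]))
  }
  opacity_asserting <- c("bilateral", "left_lung", "right_lung")
  if (sum(panel %in% opacity_asserting) == 3) return("present")
  "equivocal"
}

annotator_levels <- c("bilateral", "left_lung", "right_lung", "absent",
                      "equivocal")

# All 125 ordered annotator panels.
all_panels <- function() {
  expand.grid(a1 = annotator_levels, a2 = annotator_levels,
              a3 = annotator_levels, stringsAsFactors = FALSE)
}

# Enumeration oracle: recompute the diagnostic metrics from first
# principles for a 2x2 table, independently of the package formulas.
oracle_metrics <- function(tp, fp, tn, fn) {
  div <- function(a, b) if (b == 0) NA_real_ else a / b
  sens <- div(tp, tp + fn); spec <- div(tn, tn + fp)
  prec <- div(tp, tp + fp)
  list(precision = prec, sensitivity = sens, specificity = spec,
       balanced_accuracy = if (is.na(sens) || is.na(spec)) NA_real_
                           else mean(c(sens, spec)),
       dor = if (is.na(sens) || is.na(spec)) NA_real_
             else if ((1 - sens) * (1 - spec) == 0) Inf
             else (sens * spec) / ((1 - sens) * (1 - spec)),
       f_score = if (is.na(prec) || is.na(sens) || prec + sens == 0)
                   NA_real_
                 else 2 * prec * sens / (prec + sens))
}

# A tiny trained-free classifier whose forward pass is still exercised.
tiny_model <- function(n_classes = 3L, seed = 1L) {
  build_model("small_cnn", n_classes = n_classes, input_size = 32L,
              seed = seed)
}

# A small easy dataset (clean films, exact annotators) shared by
# training-path tests.
easy_dataset <- function(n_patients = 40L, seed = 11L) {
  generate_dataset(n_patients = n_patients, images_per_patient = c(1L, 2L),
                   difficulty = 0, seed = seed, occluder_range = c(0L, 0L),
                   unilateral_in_absent = FALSE,
                   normal_degradation = c(0, 0.15))
}
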