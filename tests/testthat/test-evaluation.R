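test_that("binarization isolates the present class", {
  probs <- rbind(c(0.2, 0.3, 0.5),
                 c(0.1, 0.8, 0.1),
                 c(0.6, 0.3, 0.1))
  bz <- binarize_present(c("equivocal", "present", "absent"), probs)
  expect_identical(bz$truth, c(0L, 1L, 0L))
  expect_identical(bz$pred, c(0L, 1L, 0L))   # argmax equivocal -> negative
  expect_equal(bz$score, c(0.3, 0.8, 0.3), tolerance = 1e-12)
  expect_error(binarize_present(character(0), probs[0, , drop = FALSE]),
               "empty")
})

test_that("confusion counts cover the canonical cases", {
  cc <- confusion_counts(c(1, 1, 0, 0), c(1, 0, 0, 1))
  expect_identical(cc, list(TP = 1L, FP = 1L, TN = 1L, FN = 1L))
  same <- confusion_counts(c(1, 0, 1), c(1, 0, 1))
  expect_identical(same$FP + same$FN, 0L)
  opp <- confusion_counts(c(1, 0), c(0, 1))
  expect_identical(opp$TP + opp$TN, 0L)
})

test_that("diagnostic metrics match the enumeration oracle on all small tables", {
  tables <- expand.grid(tp = 0:12, fp = 0:12, tn = 0:12, fn = 0:12)
  tables <- tables[rowSums(tables) <= 12 & rowSums(tables) > 0, ]
  metrics <- c("precision", "sensitivity", "specificity",
               "balanced_accuracy", "dor", "f_score")
  na_mismatches <- 0L; max_err <- 0
  for (i in seq_len(nrow(tables))) {
    tb <- tables[i, ]
    got <- suppressWarnings(diagnostic_metrics(
      list(TP = tb$tp, FP = tb$fp, TN = tb$tn, FN = tb$fn)))
    want <- oracle_metrics(tb$tp, tb$fp, tb$tn, tb$fn)
    for (nm in metrics) {
      if (is.na(got[[nm]]) != is.na(want[[nm]]))
        na_mismatches <- na_mismatches + 1L
      else if (!is.na(want[[nm]]) && is.finite(want[[nm]]))
        max_err <- max(max_err, abs(got[[nm]] - want[[nm]]))
      else if (!is.na(want[[nm]]) && !identical(got[[nm]], want[[nm]]))
        na_mismatches <- na_mismatches + 1L
    }
  }
  expect_identical(na_mismatches, 0L)
  expect_lt(max_err, 1e-12)
})

test_that("balanced accuracy reproduces published operating points", {
  ref <- reference_operating_points()
  for (i in seq_len(nrow(ref))) {
    expect_lt(abs(balanced_accuracy(ref$sensitivity[i], ref$specificity[i]) -
                    ref$balanced_accuracy[i]), 0.005)
  }
  # the two-class cross-entropy row in full precision
  expect_equal(balanced_accuracy(0.724, 0.809), 0.7665, tolerance = 1e-12)
})

test_that("degenerate operating points behave as documented", {
  expect_equal(suppressWarnings(diagnostic_metrics(
    list(TP = 3L, FP = 1L, TN = 0L, FN = 0L)))$precision, 0.75)
  # uninformative test has DOR 1
  m <- diagnostic_metrics(list(TP = 5L, FP = 5L, TN = 5L, FN = 5L))
  expect_equal(m$dor, 1, tolerance = 1e-12)
  expect_equal(m$balanced_accuracy, 0.5, tolerance = 1e-12)
  # perfect classifier: DOR infinite, not NA
  perfect <- diagnostic_metrics(list(TP = 4L, FP = 0L, TN = 4L, FN = 0L))
  expect_identical(perfect$dor, Inf)
  # Haldane correction yields a finite DOR
  corrected <- diagnostic_metrics(list(TP = 4L, FP = 0L, TN = 4L, FN = 0L),
                                  dor_correction = TRUE)
  expect_true(is.finite(corrected$dor))
  w <- capture_warnings(
    diagnostic_metrics(list(TP = 0L, FP = 0L, TN = 5L, FN = 0L)))
  expect_true(all(grepl("undefined", w)) && length(w) >= 1L)
})

test_that("AUROC equals positive-negative pair counting", {
  expect_equal(auroc(c(0, 0, 1, 1), c(0.1, 0.4, 0.35, 0.8)), 0.75,
               tolerance = 1e-12)
  expect_equal(auroc(c(0, 0, 1, 1), c(0.1, 0.2, 0.8, 0.9)), 1)
  expect_equal(auroc(c(0, 1, 0, 1), rep(0.5, 4)), 0.5)
  expect_warning(expect_true(is.na(auroc(c(1, 1), c(0.2, 0.3)))), "single")
  # random data vs brute-force pair counting with half ties
  set.seed(51)
  for (rep in 1:20) {
    n <- 40
    truth <- rbinom(n, 1, 0.4)
    if (length(unique(truth)) < 2) next
    scores <- round(runif(n), 2)   # induce ties
    pos <- scores[truth == 1]; neg <- scores[truth == 0]
    pairs <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
    expect_equal(auroc(truth, scores), mean(pairs), tolerance = 1e-12)
  }
})

test_that("AUROC is invariant under strictly monotone score transforms", {
  set.seed(52)
  truth <- rbinom(60, 1, 0.5)
  scores <- runif(60)
  base <- auroc(truth, scores)
  expect_equal(auroc(truth, scores^3), base, tolerance = 1e-12)
  expect_equal(auroc(truth, plogis(5 * scores - 2)), base, tolerance = 1e-12)
  expect_equal(auroc(truth, rank(scores)), base, tolerance = 1e-12)
})

test_that("AUROC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(53)
  truth <- rbinom(100, 1, 0.5)
  scores <- runif(100)
  ref <- as.numeric(pROC::auc(pROC::roc(truth, scores, quiet = TRUE,
                                        direction = "<")))
  expect_equal(auroc(truth, scores), ref, tolerance = 1e-9)
})

test_that("AUPRC follows the step-wise average-precision rule", {
  expect_equal(auprc(c(0, 0, 1), c(0.1, 0.2, 0.9)), 1)
  expect_equal(auprc(c(1, 0, 0, 0), c(0.9, 0.5, 0.4, 0.1)), 1)
  expect_warning(expect_true(is.na(auprc(c(0, 0), c(0.5, 0.2)))),
                 "no positive")
  # brute force over distinct thresholds
  set.seed(54)
  for (rep in 1:20) {
    n <- 30
    truth <- rbinom(n, 1, 0.5)
    if (sum(truth) == 0) next
    scores <- round(runif(n), 2)
    ths <- sort(unique(scores), decreasing = TRUE)
    rec_prev <- 0; ap <- 0
    for (th in ths) {
      tp <- sum(truth == 1 & scores >= th)
      fp <- sum(truth == 0 & scores >= th)
      prec <- tp / (tp + fp); rec <- tp / sum(truth)
      ap <- ap + (rec - rec_prev) * prec
      rec_prev <- rec
    }
    expect_equal(auprc(truth, scores), ap, tolerance = 1e-12)
  }
  # random scores at large n approach the prevalence
  set.seed(55)
  truth <- rbinom(10000, 1, 0.3)
  expect_lt(abs(auprc(truth, runif(10000)) - 0.3), 0.03)
})

test_that("bootstrap intervals are seeded, ordered and honest about NAs", {
  truth <- rep(c(1, 0), each = 20)
  scores <- c(runif(20, 0.5, 1), runif(20, 0, 0.5))
  ci <- bootstrap_ci(auroc, truth, scores, B = 200, seed = 7)
  ci2 <- bootstrap_ci(auroc, truth, scores, B = 200, seed = 7)
  expect_identical(ci, ci2)
  expect_lte(ci$low, ci$point)
  expect_gte(ci$high, ci$point)
  # constant metric: zero-width interval
  const <- bootstrap_ci(function(t, s) 0.42, truth, scores, B = 50, seed = 1)
  expect_identical(c(const$low, const$high), c(0.42, 0.42))
  # fuzzed ordering invariant
  set.seed(56)
  for (i in 1:10) {
    t <- rbinom(30, 1, 0.5); s <- runif(30)
    if (length(unique(t)) < 2) next
    ci <- bootstrap_ci(auroc, t, s, B = 100, seed = i)
    expect_true(ci$low <= ci$point && ci$point <= ci$high)
  }
})

test_that("bootstrap coverage of a Bernoulli mean is near nominal", {
  mean_metric <- function(truth, scores) mean(scores)
  set.seed(57)
  covered <- vapply(1:500, function(r) {
    x <- rbinom(200, 1, 0.7)
    ci <- bootstrap_ci(mean_metric, x, x, B = 200, seed = r)
    ci$low <= 0.7 && 0.7 <= ci$high
  }, logical(1))
  expect_lt(abs(mean(covered) - 0.95), 0.025)
})

test_that("full evaluation reports all eight present-class metrics", {
  # a synthetic perfect classifier via precomputed probabilities
  truth <- c("present", "present", "absent", "equivocal", "absent")
  probs <- rbind(c(0.1, 0.8, 0.1), c(0.05, 0.9, 0.05),
                 c(0.8, 0.1, 0.1), c(0.2, 0.1, 0.7), c(0.7, 0.2, 0.1))
  rep1 <- suppressWarnings(
    evaluate_classifier(truth_labels = truth, probs = probs, B = 100,
                        seed = 3))
  expect_setequal(rep1$metric,
                  c("precision", "sensitivity", "specificity",
                    "balanced_accuracy", "dor", "f_score", "auroc", "auprc"))
  pts <- setNames(rep1$point, rep1$metric)
  expect_equal(unname(pts[c("precision", "sensitivity", "specificity")]),
               c(1, 1, 1))
  expect_identical(unname(pts["dor"]), Inf)
  # row-order invariance
  o <- c(4, 2, 5, 1, 3)
  rep2 <- suppressWarnings(
    evaluate_classifier(truth_labels = truth[o], probs = probs[o, ],
                        B = 100, seed = 3))
  expect_equal(setNames(rep2$point, rep2$metric)[rep1$metric], pts,
               tolerance = 1e-9)
})
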