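test_that("model construction is seeded and validates its inputs", {
  m1 <- build_model("small_cnn", 3, 64, seed = 5)
  m2 <- build_model("small_cnn", 3, 64, seed = 5)
  expect_identical(m1$params, m2$params)
  m3 <- build_model("small_cnn", 3, 64, seed = 6)
  expect_false(identical(m1$params, m3$params))
  expect_error(build_model("densenet121", 3, 64), "backend")
  expect_error(build_model("small_cnn", 3, 64, pretrained = TRUE),
               "pretrained")
  expect_error(build_model("small_cnn", 4), "n_classes")
  expect_error(build_model("small_cnn", 3, input_size = 50), "multiple")
})

test_that("forward pass yields finite logits of the right width", {
  m <- tiny_model(3)
  zero <- matrix(0, 32, 32)
  p <- predict_classifier(m, zero)
  expect_identical(dim(p), c(1L, 3L))
  expect_true(all(is.finite(p)))
  expect_equal(sum(p), 1, tolerance = 1e-9)
  m2 <- tiny_model(2)
  expect_identical(ncol(predict_classifier(m2, zero)), 2L)
})

test_that("prediction preserves batch order and duplicates", {
  m <- tiny_model(3)
  set.seed(31)
  imgs <- lapply(1:5, function(i) matrix(runif(32 * 32), 32, 32))
  p <- predict_classifier(m, imgs)
  expect_equal(p[2, ], predict_classifier(m, imgs[[2]])[1, ],
               tolerance = 1e-12)
  pdup <- predict_classifier(m, list(imgs[[1]], imgs[[1]]))
  expect_equal(pdup[1, ], pdup[2, ], tolerance = 1e-12)
  perm <- c(3, 1, 5, 2, 4)
  expect_equal(predict_classifier(m, imgs[perm]), p[perm, ],
               tolerance = 1e-12)
  expect_error(predict_classifier(m, matrix(0, 16, 16)), "32")
})

test_that("compiled and reference convolution engines agree exactly", {
  set.seed(32)
  x <- array(runif(24 * 24 * 2 * 3), c(24, 24, 2, 3))
  w <- array(rnorm(3 * 3 * 2 * 5), c(3, 3, 2, 5))
  b <- rnorm(5)
  fc <- opaxr:::conv_forward(x, w, b, engine = "cpp")
  fr <- opaxr:::conv_forward(x, w, b, engine = "r")
  expect_equal(fc$out, fr$out, tolerance = 1e-12)
  dy <- array(rnorm(length(fc$out)), dim(fc$out))
  bc <- opaxr:::conv_backward(dy, w, fc)
  br <- opaxr:::conv_backward(dy, w, fr)
  expect_equal(bc$dx, br$dx, tolerance = 1e-12)
  expect_equal(bc$dw, br$dw, tolerance = 1e-12)
  expect_equal(bc$db, br$db, tolerance = 1e-10)
})

test_that("network gradients match finite differences through all layers", {
  set.seed(33)
  m <- tiny_model(3)
  x <- array(runif(32 * 32 * 1 * 2), c(32, 32, 1, 2))
  lc <- loss_config("uncertainty_ce")
  targets <- make_targets(c(2, 3), lc)
  fw <- opaxr:::cnn_forward(m, x)
  probs <- softmax(fw$logits)
  dl <- opaxr:::loss_grad_logits(targets, probs, lc)
  bk <- opaxr:::cnn_backward(m, fw, dl)
  eps <- 1e-5
  for (nm in names(m$params)) {
    p <- m$params[[nm]]
    for (i in sample(length(p), min(4, length(p)))) {
      m2 <- m; m2$params[[nm]][i] <- p[i] + eps
      L1 <- batch_loss(targets,
                       softmax(opaxr:::cnn_forward(m2, x, FALSE)$logits), lc)
      m2$params[[nm]][i] <- p[i] - eps
      L2 <- batch_loss(targets,
                       softmax(opaxr:::cnn_forward(m2, x, FALSE)$logits), lc)
      expect_equal(bk$grads[[nm]][i], (L1 - L2) / (2 * eps),
                   tolerance = 1e-4)
    }
  }
})

test_that("class-balanced weights follow n / (K * n_c)", {
  expect_equal(class_balanced_weights(c(10, 30, 60)),
               c(10 / 3, 10 / 9, 100 / 180), tolerance = 1e-4)
  expect_equal(class_balanced_weights(c(5, 5, 5)), c(1, 1, 1))
  # a septic-ICU-sized cohort: 54% / 23% / 23% of 7825
  w <- class_balanced_weights(c(4227, 1788, 1810))
  expect_equal(w, c(0.6171, 1.4588, 1.4411), tolerance = 1e-4)
  expect_equal(sum(w * c(4227, 1788, 1810)), 7825, tolerance = 1e-9)
  expect_error(class_balanced_weights(c(0, 5)), "zero")
})

test_that("the weighted sampler equalizes expected class frequencies", {
  labels <- rep(c("a", "b", "c"), times = c(100, 10, 10))
  idx <- make_sampler(labels, n = 10000, seed = 3)
  freq <- table(labels[idx]) / 10000
  expect_true(all(abs(freq - 1 / 3) < 0.02))
  # chi-square goodness of fit against uniform
  expect_gt(chisq.test(table(labels[idx]))$p.value, 0.01)
  # degenerate single-class data
  expect_true(all(labels[make_sampler(rep("a", 7), n = 50, seed = 1)] == "a"))
  # seeded determinism
  expect_identical(make_sampler(labels, n = 100, seed = 9),
                   make_sampler(labels, n = 100, seed = 9))
})

test_that("patient-level splits never leak and k-folds partition", {
  man <- data.frame(patient_id = rep(sprintf("p%02d", 1:10), each = 3),
                    image_id = sprintf("i%03d", 1:30),
                    stringsAsFactors = FALSE)
  sp <- split_patients(man, 0.7, seed = 4)
  expect_identical(length(unique(sp$train$patient_id)), 7L)
  expect_identical(length(unique(sp$test$patient_id)), 3L)
  expect_length(intersect(sp$train$patient_id, sp$test$patient_id), 0L)
  # exhaustive leakage check over many seeds and fractions
  for (seed in 1:20) for (fr in c(0.3, 0.5, 0.8)) {
    s <- split_patients(man, fr, seed = seed)
    expect_length(intersect(s$train$patient_id, s$test$patient_id), 0L)
    expect_identical(nrow(s$train) + nrow(s$test), nrow(man))
  }
  man100 <- data.frame(patient_id = sprintf("p%03d", rep(1:100, each = 2)),
                       stringsAsFactors = FALSE)
  folds <- split_patients(man100, k_folds = 10, seed = 5)
  expect_length(folds, 10L)
  test_pats <- lapply(folds, function(f) unique(f$test$patient_id))
  expect_true(all(lengths(test_pats) == 10L))
  expect_setequal(unlist(test_pats), unique(man100$patient_id))
  for (f in folds)
    expect_length(intersect(f$train$patient_id, f$test$patient_id), 0L)
  expect_error(split_patients(man, k_folds = 11), "fewer patients")
})

test_that("scheme label preparation maps equivocal per the scheme", {
  man <- data.frame(adjudicated_label = c("present", "absent", "equivocal"),
                    image_id = c("a", "b", "c"), stringsAsFactors = FALSE)
  three <- prepare_labels(man, "three_class")
  expect_identical(three$class_index, c(2L, 1L, 3L))
  two <- prepare_labels(man, "two_class")
  expect_identical(two$class_index, c(2L, 1L, 1L))   # equivocal -> controls
  de <- prepare_labels(man, "two_class_disregard_equivocal")
  expect_identical(de$image_id, c("a", "b"))          # equivocal dropped
  expect_error(prepare_labels(
    data.frame(adjudicated_label = "maybe"), "two_class"), "unknown")
})

test_that("training runs, records history, and is seed-deterministic", {
  ds <- easy_dataset(n_patients = 8L, seed = 21L)
  pp <- preprocess_config(target_size = 32)
  imgs <- lapply(ds$images, function(m) suppressWarnings(test_transform(m, pp)))
  man <- prepare_labels(ds$manifest, "three_class")
  tc <- train_config("three_class", loss_config("uncertainty_ce"),
                     epochs = 1L, learning_rate = 1e-3, batch_size = 4L,
                     augment = FALSE, seed = 2L)
  m <- build_model("small_cnn", 3, 32, seed = 3L)
  fit1 <- train_classifier(m, imgs[man$image_id], man$class_index, tc)
  expect_identical(nrow(fit1$history), 1L)
  expect_true(is.finite(fit1$history$mean_loss))
  fit2 <- train_classifier(m, imgs[man$image_id], man$class_index, tc)
  expect_identical(fit1$model$params, fit2$model$params)
  expect_identical(fit1$history, fit2$history)
  expect_error(train_config("two_class", loss_config("uncertainty_ce")),
               "three_class")
})

test_that("training loss decreases on separable synthetic data", {
  ds <- easy_dataset(n_patients = 30L, seed = 41L)
  pp <- preprocess_config(target_size = 32)
  imgs <- lapply(ds$images, function(m) suppressWarnings(test_transform(m, pp)))
  man <- prepare_labels(ds$manifest, "three_class")
  wins <- 0L
  for (seed in 1:5) {
    tc <- train_config("three_class", loss_config("cross_entropy"),
                       epochs = 5L, learning_rate = 1e-3, augment = FALSE,
                       seed = seed)
    m <- build_model("small_cnn", 3, 32, seed = seed + 50L)
    fit <- train_classifier(m, imgs[man$image_id], man$class_index, tc)
    if (fit$history$mean_loss[5] < fit$history$mean_loss[1]) wins <- wins + 1L
  }
  expect_gte(wins, 4L)
})

test_that("classifier checkpoints round-trip through JSON", {
  m <- tiny_model(3, seed = 77)
  path <- withr::local_tempfile(fileext = ".json")
  save_classifier(m, path)
  back <- load_classifier(path)
  expect_equal(back$params, m$params, tolerance = 1e-12)
  expect_identical(back$n_classes, m$n_classes)
  set.seed(1)
  img <- matrix(runif(32 * 32), 32, 32)
  expect_equal(predict_classifier(back, img), predict_classifier(m, img),
               tolerance = 1e-10)
})
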