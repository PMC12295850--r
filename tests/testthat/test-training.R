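test_that("the default fine-tune protocol carries the reference recipe", {
  p <- default_finetune_protocol()
  expect_equal(p$optimizer, "sgdm")
  expect_equal(p$momentum, 0.9)
  expect_equal(p$epochs, 30L)
  expect_equal(p$lr, 0.01)
  expect_equal(p$batch_size, 128L)
  expect_equal(p$l2, 1e-4)
  expect_true(p$shuffle)
  expect_equal(p$loss, "cross-entropy")
  # pre-training stage is configuration only
  pp <- pretrain_protocol()
  expect_equal(pp$optimizer, "adamw")
  expect_equal(pp$epochs, 90L)
  expect_equal(pp$lr, 1e-3)
  expect_equal(pp$weight_decay, 1e-4)
  expect_false(pp$executed_here)
})

test_that("a zero learning rate leaves parameters untouched", {
  ds <- generate_dataset(3, classes = c("cyst", "normal"), side = 32, seed = 81)
  m <- tiny_model(num_classes = 2, seed = 82)
  tr <- suppressWarnings(
    train_model(m, ds, NULL, finetune_protocol(epochs = 2, lr = 0,
                                               batch_size = 8), seed = 83))
  expect_identical(tr$model$params, m$params)
  expect_equal(nrow(tr$history), 2L)
})

test_that("training is seed-reproducible and history tracks every iteration", {
  ds <- generate_dataset(6, classes = c("cyst", "normal"), side = 32, seed = 84)
  m <- tiny_model(num_classes = 2, seed = 85)
  proto <- finetune_protocol(epochs = 3, lr = 0.005, batch_size = 4)
  t1 <- train_model(m, ds, ds, proto, seed = 86)
  t2 <- train_model(m, ds, ds, proto, seed = 86)
  expect_identical(t1$model$params, t2$model$params)
  expect_identical(t1$history, t2$history)
  expect_equal(nrow(t1$history), 3L * ceiling(12 / 4))
  # validation is evaluated once per epoch
  expect_equal(sum(!is.na(t1$history$val_acc)), 3L)
  # returned parameters are the final-iteration state: training longer
  # from the same seed gives a different endpoint (no best-epoch restore)
  t3 <- train_model(m, ds, ds, finetune_protocol(epochs = 4, lr = 0.005,
                                                 batch_size = 4), seed = 86)
  expect_false(identical(t3$model$params, t1$model$params))
})

test_that("stronger L2 yields smaller final weight norms", {
  ds <- generate_dataset(5, classes = c("cyst", "normal"), side = 32, seed = 87)
  m <- tiny_model(num_classes = 2, seed = 88)
  norm_of <- function(mod) {
    w <- mod$params[grepl("\\.w$", names(mod$params))]
    sqrt(sum(vapply(w, function(p) sum(p^2), numeric(1))))
  }
  run <- function(l2) train_model(m, ds, NULL,
                                  finetune_protocol(epochs = 3, lr = 0.01,
                                                    batch_size = 10, l2 = l2),
                                  seed = 89)$model
  expect_lt(norm_of(run(0.1)), norm_of(run(0)))
})

test_that("oversized batches fall back to one batch with a warning", {
  ds <- generate_dataset(2, classes = c("cyst", "normal"), side = 32, seed = 90)
  m <- tiny_model(num_classes = 2, seed = 91)
  expect_warning(tr <- train_model(m, ds, NULL,
                                   finetune_protocol(epochs = 1, lr = 1e-3,
                                                     batch_size = 64),
                                   seed = 92),
                 "batch size")
  expect_equal(nrow(tr$history), 1L)
})

test_that("class mismatches between model and data are rejected", {
  ds <- generate_dataset(2, classes = c("cyst", "normal", "stone"), side = 32,
                         seed = 93)
  m <- tiny_model(num_classes = 2, seed = 94)
  expect_error(train_model(m, ds), "classes")
})

test_that("an untrained model is an uninformative prior", {
  m <- tiny_model(num_classes = 3, seed = 95, input_size = 64,
                  stage_channels = c(8, 16, 32, 64))
  ds <- generate_dataset(34, classes = c("benign", "malignant", "normal"),
                         side = 64, seed = 96)
  m$classes <- ds$classes
  preds <- kn_predict(m, ds)
  probs <- as.matrix(preds[, paste0("p_", ds$classes)])
  expect_lt(mean(apply(probs, 1, max)), 0.6)
  expect_equal(rowSums(probs), rep(1, nrow(probs)), tolerance = 1e-8)
})

test_that("prediction is deterministic and duplicates agree", {
  ex <- phantom_experiment()
  test <- ex$split$test
  dup <- image_set(test$images[c(1, 1)], test$labels[c(1, 1)],
                   classes = test$classes, sources = c("a", "b"))
  pr <- kn_predict(ex$model, dup)
  expect_equal(as.numeric(pr[1, -(1:3)]), as.numeric(pr[2, -(1:3)]))
  pr2 <- kn_predict(ex$model, dup)
  expect_identical(pr, pr2)
  # probabilities sum to one and the argmax names the predicted class
  probs <- as.matrix(pr[, paste0("p_", test$classes)])
  expect_equal(rowSums(probs), c(1, 1), tolerance = 1e-8)
  expect_equal(pr$predicted[1], test$classes[which.max(probs[1, ])])
})

test_that("a perfect-prediction stub gives a diagonal confusion matrix", {
  truth <- rep(c("benign", "malignant", "normal"), times = c(4, 3, 5))
  cm <- confusion_matrix(truth, truth, sort(unique(truth)))
  expect_equal(sum(cm) - sum(diag(cm)), 0L)
  expect_equal(diag(cm), c(benign = 4L, malignant = 3L, normal = 5L))
})

test_that("deep features have the documented dimensionality", {
  ex <- phantom_experiment()
  sub <- set_subset(ex$split$test, 1:4)
  fp <- extract_features(ex$model, sub, tap = "pooled")
  expect_equal(ncol(fp), 64L + 1L)   # final stage width + label column
  expect_equal(nrow(fp), 4L)
  fl <- extract_features(ex$model, sub, tap = "logits")
  expect_equal(ncol(fl), 3L + 1L)
  expect_identical(fp, extract_features(ex$model, sub, tap = "pooled"))
  expect_error(extract_features(ex$model, sub, tap = "gap"), "arg")
  # the reference configuration pools a 768-dimensional vector
  expect_equal(ncol(build_model(kn_config(num_classes = 3), 1)$params$head.w),
               768L)
})

test_that("cross-entropy decreases across epoch averages on a separable task", {
  ds <- generate_dataset(25, classes = c("cyst", "normal"), side = 64, seed = 97)
  m <- tiny_model(num_classes = 2, seed = 98, input_size = 64,
                  stage_channels = c(8, 16, 32, 64))
  tr <- train_model(m, ds, NULL, finetune_protocol(epochs = 4, lr = 0.002,
                                                   batch_size = 10), seed = 99)
  ep_mean <- tapply(tr$history$train_loss, tr$history$epoch, mean)
  expect_true(all(diff(ep_mean) < 0))
})
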