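test_that("feature extraction is deterministic, shape-checked and sensitive", {
  fx <- small_fx()
  zero <- array(0, dim = c(64, 64, 3))
  expect_equal(extract_features(fx, zero), rep(0, 64))
  img <- array(runif(64 * 64 * 3), dim = c(64, 64, 3))
  expect_identical(extract_features(fx, img), extract_features(fx, img))
  img2 <- img
  img2[1, 1, 1] <- 1 - img2[1, 1, 1]
  expect_false(all(extract_features(fx, img) == extract_features(fx, img2)))
  expect_error(extract_features(fx, array(0, dim = c(16, 16, 3))), "64 x 64")

  custom <- custom_feature_extractor(function(im) c(mean(im), 1), output_dim = 2)
  expect_equal(extract_features(custom, img)[2], 1)
})

test_that("inference-mode prediction is the deterministic sigmoid head", {
  # zero weights -> sigmoid(0) = 0.5 exactly
  z <- classifier_head(8, 8, init = "zero")
  expect_equal(predict_head(z, rep(1, 8))$probability, 0.5)

  # probability is monotone in the output-layer bias
  h <- classifier_head(8, 8, seed = 3)
  h$trained <- TRUE
  x <- rnorm(8)
  probs <- vapply(c(-2, 0, 2), function(b) {
    h$weights$b2 <- b
    predict_head(h, x)$probability
  }, numeric(1))
  expect_true(all(diff(probs) > 0))

  # untrained heads refuse to predict; dropout plays no role at inference
  expect_error(predict_head(classifier_head(8, 8), rep(0, 8)), "untrained")
  p1 <- predict_head(z, rnorm(8) * 0)
  p2 <- predict_head(z, rnorm(8) * 0)
  expect_identical(p1, p2)
})

test_that("training converges on separable data, is seeded, and rejects bad input", {
  withr::with_seed(123, {
    X <- matrix(rnorm(600 * 10), 600, 10)
    s <- X[, 1] + 0.5 * X[, 2]
    X <- X[abs(s) > 0.4, ][1:400, ] # separable with a margin
    y <- as.numeric((X[, 1] + 0.5 * X[, 2]) > 0)
    n <- 400
  })
  cfg <- train_config(epochs = 10, seed = 42, learning_rate = 0.01)
  h <- train_head(classifier_head(10, 16, seed = 1), X, y, cfg)
  expect_equal(nrow(h$history), 10)
  expect_gte(h$history$val_acc[10], 0.95)

  # independent oracle: logistic regression separates the same data
  glm_acc <- withr::with_seed(42, {
    fit <- suppressWarnings(stats::glm(y ~ X, family = stats::binomial()))
    mean((stats::fitted(fit) >= 0.5) == (y == 1))
  })
  expect_gte(glm_acc, 0.95)

  # identical seed reproduces identical weights and history
  h2 <- train_head(classifier_head(10, 16, seed = 1), X, y, cfg)
  expect_identical(h$weights, h2$weights)
  expect_identical(h$history, h2$history)

  # permuted labels stay at chance level
  yperm <- withr::with_seed(9, sample(y))
  hp <- train_head(classifier_head(10, 16, seed = 1), X, yperm, cfg)
  expect_gte(hp$history$val_acc[10], 0.35)
  expect_lte(hp$history$val_acc[10], 0.65)

  expect_error(train_head(classifier_head(10), X, rep(1, n), cfg), "single class")
  expect_error(train_config(epochs = 0), "epochs")
})

test_that("evaluation builds truth-by-prediction confusion counts", {
  z <- classifier_head(4, 4, init = "zero")
  X <- matrix(rnorm(40), 10, 4)

  # threshold 0 predicts everything true
  z$decision_threshold <- 0
  cm <- evaluate_head(z, X, rep(c(TRUE, FALSE), 5))
  expect_equal(c(cm$a, cm$b, cm$c, cm$d), c(5, 0, 5, 0))

  # threshold 1 predicts everything false
  z$decision_threshold <- 1
  cm2 <- evaluate_head(z, X, rep(TRUE, 10))
  expect_equal(c(cm2$a, cm2$b, cm2$c, cm2$d), c(0, 10, 0, 0))

  expect_equal(cm_total <- cm$a + cm$b + cm$c + cm$d, 10)
  expect_error(evaluate_head(z, X[0, , drop = FALSE], logical(0)), "empty")
})

test_that("tidy, glance and the weight bundle round-trip describe a fit", {
  X <- matrix(rnorm(200), 50, 4)
  y <- as.numeric(X[, 1] > 0)
  h <- train_head(classifier_head(4, 6, seed = 2), X, y, train_config(epochs = 3, seed = 2))

  td <- tidy(h)
  expect_named(td, c("epoch", "train_loss", "val_loss", "val_acc"))
  expect_equal(nrow(td), 3)
  g <- glance(h)
  expect_true(g$trained)
  expect_equal(g$epochs, 3L)
  expect_equal(g$final_val_acc, td$val_acc[3])

  path <- withr::local_tempfile(fileext = ".json")
  write_head(h, path)
  h2 <- read_head(path)
  expect_equal(h2$weights$W1, h$weights$W1, tolerance = 1e-12)
  expect_equal(
    predict_head(h2, X[1:5, ])$probability,
    predict_head(h, X[1:5, ])$probability,
    tolerance = 1e-12
  )

  p <- autoplot(h)
  expect_s3_class(p, "ggplot")
})

test_that("region models separate the synthetic PPE colours at small scale", {
  fit <- train_region_models(
    n_per_class = 16, seed = 7, fx = small_fx(),
    epochs = 10, cfg = small_cfg()
  )
  expect_true(all(fit$evaluation$val_acc >= 0.95))
  expect_setequal(fit$evaluation$item, c("mask", "gloves", "gown"))
  # evaluate on its own training pool: counts sum to pool size
  ds <- fit$manifests$mask
  expect_equal(nrow(ds), 32)
})
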