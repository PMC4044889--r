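test_that("hidden layer size follows the between-layers rule of thumb", {
  expect_identical(hidden_layer_size(5, 2), 3L)
  expect_identical(hidden_layer_size(2, 2), 2L)
  expect_identical(hidden_layer_size(10, 2), 6L)
  expect_error(hidden_layer_size(1, 2), class = "pf_validation_error")
})

test_that("forward pass matches closed-form hand computation", {
  # all-zero weights: every output is sigmoid(0) = 0.5
  z <- manual_model(matrix(0, 3, 5), rep(0, 3), matrix(0, 2, 3), rep(0, 2))
  expect_equal(unname(forward(z, rep(1, 5))), matrix(0.5, 1, 2))

  # hand-set 2-1-2 network with unit weights on input (0, 0)
  m <- manual_model(matrix(1, 1, 2), 0, matrix(1, 2, 1), c(0, 0))
  sig <- function(x) 1 / (1 + exp(-x))
  expect_equal(unname(forward(m, c(0, 0))),
               matrix(sig(sig(0)), 1, 2), tolerance = 1e-12)

  # outputs strictly inside (0, 1) for any finite input
  r <- random_model(4, 3, seed = 2)
  withr::local_seed(2)
  for (i in 1:20) {
    out <- forward(r, rnorm(4, sd = 50))
    expect_true(all(out > 0 & out < 1))
  }
  expect_error(forward(r, rep(0, 5)), class = "pf_shape_error")
})

test_that("predict_score is the output difference with ties predicting control", {
  m <- random_model(3, 2, seed = 4)
  out <- forward(m, c(0.1, -0.2, 0.5))
  expect_equal(predict_score(m, c(0.1, -0.2, 0.5)),
               unname(out[, 1] - out[, 2]))
  # zero-weight model scores exactly 0 -> control by the tie rule
  z <- manual_model(matrix(0, 2, 2), rep(0, 2), matrix(0, 2, 2), rep(0, 2))
  cm <- confusion_from_scores(predict_score(z, matrix(rnorm(10), 5, 2)),
                              c("cancer", "cancer", "control", "control",
                                "cancer"))
  expect_identical(cm$tp + cm$fp, 0L) # nothing predicted cancer

  # thresholding at 0 equals argmax of the two outputs
  withr::local_seed(6)
  for (i in 1:10) {
    r <- random_model(4, 3, seed = i)
    x <- matrix(rnorm(40), 10, 4)
    labels <- rep(c("cancer", "control"), 5)
    s <- predict_score(r, x)
    out <- forward(r, x)
    argmax_cancer <- out[, "cancer"] > out[, "healthy"]
    expect_identical(s > 0, argmax_cancer)
  }
})

test_that("backprop gradient matches central finite differences", {
  withr::local_seed(12)
  for (n_input in c(2, 5, 8)) {
    model <- random_model(n_input, hidden_layer_size(max(n_input, 2)),
                          seed = n_input)
    x <- matrix(rnorm(6 * n_input), 6, n_input)
    labels <- rep(c("cancer", "control"), 3)
    g <- ffnn_gradient(model, x, labels)
    h <- 1e-5
    for (fld in c("W1", "b1", "W2", "b2")) {
      for (i in seq_along(model[[fld]])) {
        up <- model; up[[fld]][i] <- up[[fld]][i] + h
        dn <- model; dn[[fld]][i] <- dn[[fld]][i] - h
        fd <- (ffnn_sse(up, x, labels) - ffnn_sse(dn, x, labels)) / (2 * h)
        expect_lt(abs(fd - g[[fld]][i]) / max(1e-6, abs(fd)), 1e-6)
      }
    }
  }
})

test_that("training learns separable data and honors degenerate configs", {
  d <- separable_data(n_per_class = 40, p = 5, seed = 3)
  model <- train_ffnn(d$x, d$labels, config = training_config(seed = 3))
  acc <- mean((predict_score(model, d$x) > 0) == (d$labels == "cancer"))
  expect_gte(acc, 0.95)
  expect_equal(model$final_sse, ffnn_sse(model, d$x, d$labels),
               tolerance = 1e-10)

  # zero learning rate leaves the initial weights untouched
  frozen <- train_ffnn(d$x, d$labels,
                       config = training_config(learning_rate = 0, seed = 3,
                                                max_epochs = 50))
  init <- panelforge:::with_seed(3, panelforge:::init_weights(
    network_architecture(5), training_config()))
  expect_identical(frozen$W1, init$W1)
  expect_identical(frozen$b2, init$b2)

  expect_error(train_ffnn(d$x[d$labels == "cancer", ],
                          d$labels[d$labels == "cancer"]),
               class = "pf_validation_error")
})

test_that("training is deterministic and loss non-increasing at small rates", {
  d <- separable_data(n_per_class = 10, p = 3, seed = 5)
  cfg <- training_config(learning_rate = 1e-3, max_epochs = 100, seed = 11)
  m1 <- train_ffnn(d$x, d$labels, config = cfg)
  m2 <- train_ffnn(d$x, d$labels, config = cfg)
  expect_identical(m1$W1, m2$W1)
  expect_identical(m1$W2, m2$W2)
  expect_identical(m1$sse_log, m2$sse_log)
  expect_true(all(diff(m1$sse_log) <= 1e-9))
})

test_that("early stopping halts training once the loss stops improving", {
  d <- separable_data(n_per_class = 10, p = 3, seed = 5)
  # frozen weights never improve: patience kicks in immediately
  m <- train_ffnn(d$x, d$labels,
                  config = training_config(learning_rate = 0,
                                           max_epochs = 5000, seed = 1,
                                           early_stop_patience = 3))
  expect_lte(m$epochs_run, 5)
  # patience 0 disables early stopping entirely
  m2 <- train_ffnn(d$x, d$labels,
                   config = training_config(learning_rate = 0,
                                            max_epochs = 20, seed = 1))
  expect_identical(m2$epochs_run, 20L)
})

test_that("cross-validation selects an epoch budget on a proper partition", {
  d <- separable_data(n_per_class = 10, p = 4, gap = 6, seed = 7)
  cv <- cross_validate(d$x, d$labels, config = training_config(seed = 7),
                       k = 10) # k equal to class size
  expect_equal(cv$mean_cv_auc, 1.0)
  expect_identical(sort(unique(cv$fold)), 1:10)
  expect_identical(tabulate(cv$fold), rep(2L, 10)) # one per class per fold
  expect_true(cv$epoch_budget %in% cv$eval_epochs)

  expect_error(cross_validate(d$x, d$labels, k = 11),
               class = "pf_validation_error")
})

test_that("permuted labels give chance-level CV AUC", {
  d <- separable_data(n_per_class = 20, p = 5, gap = 0, seed = 13) # pure noise
  aucs <- vapply(1:10, function(s) {
    labels <- panelforge:::with_seed(100 + s, sample(d$labels))
    cross_validate(d$x, labels,
                   config = training_config(seed = s, max_epochs = 100),
                   k = 5)$mean_cv_auc
  }, numeric(1))
  expect_gte(mean(aucs), 0.35)
  expect_lte(mean(aucs), 0.65)
})

test_that("models serialize and round-trip through the text format", {
  d <- separable_data(n_per_class = 10, p = 3, seed = 9)
  m <- train_ffnn(d$x, d$labels,
                  config = training_config(seed = 9, max_epochs = 50))
  path <- withr::local_tempfile()
  write_ffnn_model(m, path)
  back <- read_ffnn_model(path)
  expect_equal(back$W1, m$W1)
  expect_equal(back$b1, m$b1)
  expect_equal(back$W2, m$W2)
  expect_equal(back$b2, m$b2)
  expect_equal(back$center, m$center)
  x <- matrix(rnorm(9), 3, 3)
  expect_equal(predict_score(back, x), predict_score(m, x))
})
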