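# From-scratch feed-forward neural network: one hidden layer, logistic
# sigmoid activations, two-variable output encoding (cancer = (1,0),
# healthy = (0,1)), trained by full-batch backpropagation gradient descent
# on the total sum of squared errors. The inner training loop is compiled
# (src/ffnn.cpp); the exhaustive panel search trains hundreds of thousands
# of these small networks.

#' Rule-of-thumb hidden layer size
#'
#' The hidden layer is sized between the input and output layers:
#' `floor((n_input + n_output) / 2)`, clamped to at least `n_output`. For a
#' five-marker panel with two output nodes this gives 3 hidden nodes.
#'
#' @param n_input number of input nodes (panel size).
#' @param n_output number of output nodes (2 for two-variable encoding).
#' @return integer hidden-layer size.
#' @export
hidden_layer_size <- function(n_input, n_output = 2L) {
  if (n_output < 1 || n_input < n_output)
    pf_stop("pf_validation_error", "need n_input >= n_output >= 1")
  as.integer(max(n_output, (n_input + n_output) %/% 2))
}

#' Network architecture
#'
#' @param n_input number of input nodes.
#' @param n_hidden hidden-layer size; defaults to [hidden_layer_size()].
#' @param activation only `"sigmoid"` is supported.
#' @return list of class `network_architecture`; `n_output` is fixed at 2
#'   for the two-variable encoding.
#' @export
network_architecture <- function(n_input,
                                 n_hidden = hidden_layer_size(n_input, 2L),
                                 activation = "sigmoid") {
  activation <- match.arg(activation, "sigmoid")
  if (n_input < 1 || n_hidden < 1)
    pf_stop("pf_validation_error", "layer sizes must be positive")
  structure(list(n_input = as.integer(n_input),
                 n_hidden = as.integer(n_hidden), n_output = 2L,
                 activation = activation),
            class = "network_architecture")
}

#' Training configuration
#'
#' @param learning_rate step size of full-batch gradient descent on total
#'   SSE (0 is allowed and leaves the initial weights untouched).
#' @param max_epochs maximum number of epochs.
#' @param weight_init_scale initial weights drawn from
#'   Uniform(-w, w) with w = `weight_init_scale / sqrt(fan_in)`.
#' @param seed integer seed; training is bit-deterministic given it.
#' @param early_stop_patience stop after this many epochs without SSE
#'   improvement (0 disables early stopping).
#' @param input_standardization standardize inputs to zero mean / unit
#'   variance on training statistics (stored for reuse at prediction time).
#' @return list of class `training_config`.
#' @export
training_config <- function(learning_rate = 0.05, max_epochs = 300L,
                            weight_init_scale = 1.0, seed = 1L,
                            early_stop_patience = 0L,
                            input_standardization = TRUE) {
  if (learning_rate < 0 || max_epochs < 1 || weight_init_scale <= 0 ||
      early_stop_patience < 0)
    pf_stop("pf_validation_error", "invalid training configuration")
  structure(list(learning_rate = learning_rate,
                 max_epochs = as.integer(max_epochs),
                 weight_init_scale = weight_init_scale,
                 seed = as.integer(seed),
                 early_stop_patience = as.integer(early_stop_patience),
                 input_standardization = isTRUE(input_standardization)),
            class = "training_config")
}

#' Encode labels as two-variable targets: cancer = (1,0), healthy = (0,1)
#' @noRd
encode_labels <- function(labels) {
  labels <- as.character(labels)
  bad <- setdiff(unique(labels), c("cancer", "control"))
  if (length(bad))
    pf_stop("pf_validation_error", "unknown class label: %s", bad[1])
  cbind(cancer = as.numeric(labels == "cancer"),
        healthy = as.numeric(labels == "control"))
}

init_weights <- function(arch, config) {
  w1 <- config$weight_init_scale / sqrt(arch$n_input)
  w2 <- config$weight_init_scale / sqrt(arch$n_hidden)
  list(W1 = matrix(runif(arch$n_hidden * arch$n_input, -w1, w1),
                   arch$n_hidden, arch$n_input),
       b1 = runif(arch$n_hidden, -w1, w1),
       W2 = matrix(runif(arch$n_output * arch$n_hidden, -w2, w2),
                   arch$n_output, arch$n_hidden),
       b2 = runif(arch$n_output, -w2, w2))
}

new_ffnn_model <- function(arch, weights, center, scale, config,
                           epochs_run = 0L, sse_log = numeric(0),
                           final_sse = NA_real_) {
  structure(list(architecture = arch, W1 = weights$W1, b1 = weights$b1,
                 W2 = weights$W2, b2 = weights$b2, center = center,
                 scale = scale, config = config, epochs_run = epochs_run,
                 sse_log = sse_log, final_sse = final_sse),
            class = "ffnn_model")
}

#' @export
print.ffnn_model <- function(x, ...) {
  a <- x$architecture
  cat(sprintf("<ffnn_model> %d-%d-%d sigmoid, %d epochs, final SSE %.4g\n",
              a$n_input, a$n_hidden, a$n_output, x$epochs_run, x$final_sse))
  invisible(x)
}

standardize_features <- function(x, center, scale) {
  x <- as.matrix(x)
  sweep(sweep(x, 2, center, "-"), 2, scale, "/")
}

model_inputs <- function(model, features) {
  if (is.null(dim(features)))
    features <- matrix(features, nrow = 1)
  features <- as.matrix(features)
  if (ncol(features) != model$architecture$n_input)
    pf_stop("pf_shape_error", "expected %d features, got %d",
            model$architecture$n_input, ncol(features))
  if (!is.null(model$center))
    features <- standardize_features(features, model$center, model$scale)
  features
}

#' Forward pass
#'
#' Propagates a feature vector through the network:
#' `sigmoid(W2 %*% sigmoid(W1 %*% x + b1) + b2)`. If the model stores
#' training standardization statistics they are applied first.
#'
#' @param model an `ffnn_model`.
#' @param features numeric vector of length `n_input` (or a matrix with one
#'   row per example).
#' @return numeric matrix with columns `cancer`, `healthy`, each in (0, 1).
#' @export
forward <- function(model, features) {
  x <- model_inputs(model, features)
  out <- ffnn_forward_cpp(x, model$W1, model$b1, model$W2, model$b2)
  colnames(out) <- c("cancer", "healthy")
  out
}

#' Classification score
#'
#' `cancer_score - healthy_score` in (-1, 1); predicted class is cancer iff
#' the score is strictly positive (ties predict control). Thresholding this
#' score at 0 is equivalent to taking the larger output node.
#'
#' @inheritParams forward
#' @return numeric vector of scores, one per example.
#' @export
predict_score <- function(model, features) {
  out <- forward(model, features)
  unname(out[, "cancer"] - out[, "healthy"])
}

#' Train the network by backpropagation
#'
#' Full-batch gradient descent on total SSE
#' `sum over examples and output nodes of (target - output)^2`, with labels
#' encoded cancer = (1,0), healthy = (0,1). Deterministic given
#' `config$seed` (weight initialization is the only random element).
#'
#' @param x numeric matrix, one row per example, `n_input` columns.
#' @param labels `"cancer"`/`"control"` per row; both classes required.
#' @param arch a [network_architecture()]; defaults to the rule-of-thumb
#'   hidden size for `ncol(x)` inputs.
#' @param config a [training_config()].
#' @param epochs optional override of `config$max_epochs` (used to retrain
#'   with a cross-validated epoch budget).
#' @return an `ffnn_model` with the training log (`sse_log`, one entry per
#'   epoch) and `final_sse`, the SSE of the returned weights on the
#'   training data.
#' @export
train_ffnn <- function(x, labels, arch = NULL, config = training_config(),
                       epochs = NULL) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  y <- encode_labels(labels)
  if (length(unique(as.character(labels))) < 2)
    pf_stop("pf_validation_error", "training data contains a single class")
  if (is.null(arch)) arch <- network_architecture(ncol(x))
  if (ncol(x) != arch$n_input)
    pf_stop("pf_shape_error", "expected %d features, got %d",
            arch$n_input, ncol(x))
  center <- scale <- NULL
  if (config$input_standardization) {
    center <- colMeans(x)
    scale <- apply(x, 2, sd)
    scale[!is.finite(scale) | scale == 0] <- 1
    x <- standardize_features(x, center, scale)
  }
  weights <- with_seed(config$seed, init_weights(arch, config))
  max_epochs <- as.integer(epochs %||% config$max_epochs)
  fit <- ffnn_train_cpp(x, y, weights$W1, weights$b1, weights$W2, weights$b2,
                        config$learning_rate, max_epochs,
                        matrix(numeric(0), 0, ncol(x)),
                        matrix(numeric(0), 0, 2L), 0L,
                        config$early_stop_patience, 1e-12)
  if (fit$nan_epoch > 0)
    pf_stop("pf_divergence_error", "training loss became NaN at epoch %d",
            fit$nan_epoch)
  sse_log <- as.numeric(fit$sse_log)
  new_ffnn_model(arch, fit, center, scale, config,
                 epochs_run = fit$epochs_run, sse_log = sse_log,
                 final_sse = if (length(sse_log)) sse_log[length(sse_log)]
                 else NA_real_)
}

#' Analytic backpropagation gradient of the total SSE
#'
#' Exposed for verification against finite differences; this is the exact
#' gradient the training loop descends.
#'
#' @param model an `ffnn_model` (weights are taken as-is; standardization
#'   statistics are ignored — pass pre-standardized `x`).
#' @param x example matrix, `labels` their classes.
#' @inheritParams train_ffnn
#' @return list with gradient components `W1`, `b1`, `W2`, `b2` and the
#'   `sse` at the evaluation point.
#' @export
ffnn_gradient <- function(model, x, labels) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  ffnn_grad_cpp(x, encode_labels(labels), model$W1, model$b1, model$W2,
                model$b2)
}

#' Stratified fold assignment
#' @noRd
stratified_folds <- function(labels, k, seed) {
  labels <- as.character(labels)
  fold <- integer(length(labels))
  with_seed(seed, {
    for (cl in unique(labels)) {
      idx <- which(labels == cl)
      if (length(idx) < k)
        pf_stop("pf_validation_error",
                "class %s has %d examples, fewer than k = %d folds",
                cl, length(idx), k)
      fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
    }
  })
  fold
}

#' Stratified k-fold cross-validation with epoch-budget selection
#'
#' For each fold the network is trained on the remaining folds while the
#' held-out fold's AUC is recorded every `eval_every` epochs; the selected
#' epoch budget is the evaluation epoch maximizing the mean held-fold AUC.
#' AUC plateaus are common once the classes separate, so exact AUC ties are
#' broken by the smaller mean held-fold SSE (better-calibrated outputs),
#' then by the smaller epoch. This is the early-stopping surrogate used
#' by the panel search: the final network is retrained on the full training
#' set for the selected number of epochs.
#'
#' @inheritParams train_ffnn
#' @param k number of folds (default 5).
#' @param eval_every record held-fold AUC every this many epochs.
#' @return list of class `cv_summary`: `epoch_budget`, `mean_cv_auc` (at
#'   the selected budget), `fold_auc` (per fold at the budget), `fold_sse`
#'   (final training SSE per fold), `eval_epochs`, `mean_auc_by_epoch`.
#' @export
cross_validate <- function(x, labels, arch = NULL,
                           config = training_config(), k = 5L,
                           eval_every = 5L) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  labels <- as.character(labels)
  if (k < 2) pf_stop("pf_validation_error", "k must be at least 2")
  if (is.null(arch)) arch <- network_architecture(ncol(x))
  fold <- stratified_folds(labels, k, seed_hash(config$seed, "cv_folds"))
  auc_rows <- NULL
  hold_sse_rows <- NULL
  fold_sse <- numeric(k)
  eval_epochs <- NULL
  for (f in seq_len(k)) {
    tr <- fold != f
    xt <- x[tr, , drop = FALSE]
    xh <- x[!tr, , drop = FALSE]
    yh <- labels[!tr]
    center <- scale <- NULL
    if (config$input_standardization) {
      center <- colMeans(xt)
      scale <- apply(xt, 2, sd)
      scale[!is.finite(scale) | scale == 0] <- 1
      xt <- standardize_features(xt, center, scale)
      xh <- standardize_features(xh, center, scale)
    }
    weights <- with_seed(seed_hash(config$seed, c("cv_init", f)),
                         init_weights(arch, config))
    fit <- ffnn_train_cpp(xt, encode_labels(labels[tr]), weights$W1,
                          weights$b1, weights$W2, weights$b2,
                          config$learning_rate, config$max_epochs, xh,
                          encode_labels(yh), as.integer(eval_every), 0L,
                          1e-12)
    if (fit$nan_epoch > 0)
      pf_stop("pf_divergence_error", "fold %d diverged at epoch %d", f,
              fit$nan_epoch)
    aucs <- apply(fit$hold_scores, 1, auc_rank, labels = yh)
    auc_rows <- rbind(auc_rows, aucs)
    hold_sse_rows <- rbind(hold_sse_rows, as.numeric(fit$hold_sse))
    eval_epochs <- fit$eval_epochs
    fold_sse[f] <- fit$sse_log[length(fit$sse_log)]
  }
  mean_auc <- colMeans(auc_rows)
  mean_hold_sse <- colMeans(hold_sse_rows)
  # max AUC; ties -> min held-out SSE; ties -> smallest epoch
  at_max <- which(mean_auc == max(mean_auc))
  best <- at_max[which.min(mean_hold_sse[at_max])]
  structure(list(epoch_budget = as.integer(eval_epochs[best]),
                 mean_cv_auc = mean_auc[best],
                 fold_auc = as.numeric(auc_rows[, best]),
                 fold_sse = fold_sse,
                 eval_epochs = as.integer(eval_epochs),
                 mean_auc_by_epoch = as.numeric(mean_auc),
                 mean_hold_sse_by_epoch = as.numeric(mean_hold_sse), k = k,
                 fold = fold),
            class = "cv_summary")
}

#' Serialize a trained model to a structured text file
#' @param model an `ffnn_model`.
#' @param path output path.
#' @export
write_ffnn_model <- function(model, path) {
  a <- model$architecture
  lines <- c("# panelforge ffnn v1",
             sprintf("arch\t%d\t%d\t%d", a$n_input, a$n_hidden, a$n_output),
             sprintf("epochs_run\t%d", model$epochs_run),
             sprintf("final_sse\t%.17g", model$final_sse),
             sprintf("W1\t%s", paste(sprintf("%.17g", model$W1), collapse = "\t")),
             sprintf("b1\t%s", paste(sprintf("%.17g", model$b1), collapse = "\t")),
             sprintf("W2\t%s", paste(sprintf("%.17g", model$W2), collapse = "\t")),
             sprintf("b2\t%s", paste(sprintf("%.17g", model$b2), collapse = "\t")))
  if (!is.null(model$center)) {
    lines <- c(lines,
               sprintf("center\t%s", paste(sprintf("%.17g", model$center), collapse = "\t")),
               sprintf("scale\t%s", paste(sprintf("%.17g", model$scale), collapse = "\t")))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a model written by [write_ffnn_model()]
#' @param path model file path.
#' @return an `ffnn_model` (without training log).
#' @export
read_ffnn_model <- function(path) {
  lines <- readLines(path)
  fields <- strsplit(lines[-1], "\t", fixed = TRUE)
  names(fields) <- vapply(fields, `[`, character(1), 1L)
  num <- function(k) as.numeric(fields[[k]][-1])
  dims <- as.integer(fields[["arch"]][-1])
  arch <- network_architecture(dims[1], dims[2])
  weights <- list(W1 = matrix(num("W1"), dims[2], dims[1]),
                  b1 = num("b1"),
                  W2 = matrix(num("W2"), dims[3], dims[2]),
                  b2 = num("b2"))
  center <- if ("center" %in% names(fields)) num("center") else NULL
  scale <- if ("scale" %in% names(fields)) num("scale") else NULL
  new_ffnn_model(arch, weights, center, scale, NULL,
                 epochs_run = as.integer(num("epochs_run")),
                 final_sse = num("final_sse"))
}
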