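# Exhaustive wrapper feature selection: enumerate every N-marker panel from
# the screened candidates, train an FFNN per panel on the training study,
# and select C* = argmax over panels of validation-study AUC. The testing
# study is touched exactly once, to assess C*.

#' Enumerate all N-marker panels
#'
#' All `choose(length(candidates), N)` combinations, in lexicographic order
#' of candidate indices (candidates are conventionally ordered by screen
#' p-value, which fixes the enumeration deterministically).
#'
#' @param candidates ordered character vector of candidate protein ids.
#' @param N panel size.
#' @return character matrix, one row per panel, `N` columns.
#' @export
enumerate_panels <- function(candidates, N) {
  N <- as.integer(N)
  if (N < 1 || N > length(candidates))
    pf_stop("pf_validation_error",
            "panel size %d outside [1, %d]", N, length(candidates))
  idx <- combn(length(candidates), N)
  matrix(candidates[idx], ncol = N, byrow = TRUE)
}

#' Per-sample classifier features for a panel
#'
#' Classification operates at the biological-sample level: each sample's
#' feature vector is the mean across its replicate injections of each panel
#' protein's intensity.
#'
#' @param matrix an [intensity_matrix()].
#' @param design the matching [study_design()].
#' @param panel character vector of panel protein ids.
#' @return list with `x` (samples x panel matrix), `labels`
#'   (cancer/control per sample), `sample_ids`.
#' @export
panel_features <- function(matrix, design, panel) {
  missing_prot <- setdiff(panel, protein_ids(matrix))
  if (length(missing_prot))
    pf_stop("pf_evaluation_error", "protein %s absent from data",
            missing_prot[1])
  design <- as.data.frame(design)
  check_design_matches(matrix, design)
  design <- design[design$injection_id %in% injection_ids(matrix), ]
  v <- unclass(matrix)[panel, design$injection_id, drop = FALSE]
  samples <- unique(design$sample_id)
  x <- vapply(samples, function(s) {
    rowMeans(v[, design$sample_id == s, drop = FALSE], na.rm = TRUE)
  }, numeric(length(panel)))
  x <- t(matrix(x, nrow = length(panel)))
  colnames(x) <- panel
  labels <- design$group[match(samples, design$sample_id)]
  list(x = x, labels = labels, sample_ids = samples)
}

panel_seed <- function(seed, panel) seed_hash(seed, c("panel", panel))

#' Evaluate one panel under the three-way split
#'
#' 5-fold cross-validation on the training study selects an epoch budget;
#' the final network is retrained on the full training study with that
#' budget, and its ROC AUC on the validation study is the panel's selection
#' statistic. The per-panel RNG seed is derived deterministically from the
#' global seed and the panel's protein ids, so results are independent of
#' evaluation order.
#'
#' @param panel character vector of protein ids.
#' @param train,validation lists with elements `matrix` and `design` for
#'   the training and validation studies.
#' @param config a [training_config()]; its `seed` acts as the global seed.
#' @param k cross-validation folds.
#' @param eval_every epoch granularity of the CV budget search.
#' @return list of class `panel_candidate`: `panel`, `training_sse`,
#'   `cv_summary`, `cv_mean_auc`, `validation_auc`, `training_accuracy`,
#'   `validation_accuracy`, `model`.
#' @export
evaluate_panel <- function(panel, train, validation,
                           config = training_config(), k = 5L,
                           eval_every = 5L) {
  ftrain <- panel_features(train$matrix, train$design, panel)
  fval <- panel_features(validation$matrix, validation$design, panel)
  cfg <- config
  cfg$seed <- panel_seed(config$seed, panel)
  arch <- network_architecture(length(panel))
  cv <- cross_validate(ftrain$x, ftrain$labels, arch, cfg, k = k,
                       eval_every = eval_every)
  model <- train_ffnn(ftrain$x, ftrain$labels, arch, cfg,
                      epochs = cv$epoch_budget)
  strain <- predict_score(model, ftrain$x)
  sval <- predict_score(model, fval$x)
  structure(list(panel = panel,
                 training_sse = model$final_sse,
                 cv_summary = cv,
                 cv_mean_auc = cv$mean_cv_auc,
                 validation_auc = auc_scores(sval, fval$labels),
                 training_accuracy = unname(
                   confusion_metrics(confusion_from_scores(
                     strain, ftrain$labels))["accuracy"]) / 100,
                 validation_accuracy = unname(
                   confusion_metrics(confusion_from_scores(
                     sval, fval$labels))["accuracy"]) / 100,
                 model = model),
            class = "panel_candidate")
}

#' @export
print.panel_candidate <- function(x, ...) {
  cat(sprintf("<panel_candidate> [%s] validation AUC %.4f, training SSE %.4g\n",
              panel_string(x$panel), x$validation_auc, x$training_sse))
  invisible(x)
}

rank_candidates <- function(candidates) {
  keys <- vapply(candidates, function(p) panel_string(p$panel), character(1))
  ord <- order(-vapply(candidates, `[[`, numeric(1), "validation_auc"),
               vapply(candidates, `[[`, numeric(1), "training_sse"),
               keys)
  candidates <- candidates[ord]
  for (i in seq_along(candidates)) candidates[[i]]$rank <- i
  candidates
}

#' Select the optimal panel C*
#'
#' The candidate with maximal validation AUC; ties broken by lower training
#' SSE, then lexicographic panel ids. Order of the input list is
#' irrelevant.
#'
#' @param candidates list of `panel_candidate` objects.
#' @return the winning `panel_candidate`, with `rank = 1` and the full
#'   ranking in attribute `"ranking"`.
#' @export
select_optimal <- function(candidates) {
  if (!length(candidates))
    pf_stop("pf_validation_error", "no panel candidates to select from")
  ranked <- rank_candidates(candidates)
  cstar <- ranked[[1]]
  attr(cstar, "ranking") <- ranked
  cstar
}

#' Assess the selected panel on the held-out testing study
#'
#' Called exactly once per search, only on C*. Errors if any testing
#' injection id also appears in the training or validation study (leakage).
#'
#' @param cstar the selected `panel_candidate`.
#' @param model the trained `ffnn_model` for C* (defaults to the one stored
#'   on the candidate).
#' @param test list with `matrix` and `design` for the testing study.
#' @param train,validation optional same-shaped lists, used for the
#'   leakage check and to fill the per-split confusion matrices of the
#'   final report.
#' @return list with `confusion` (per split) and `metrics` (sensitivity,
#'   specificity, precision, accuracy as percentages, plus `auc`).
#' @export
assess_on_test <- function(cstar, model = cstar$model, test,
                           train = NULL, validation = NULL) {
  for (other in list(train, validation)) {
    if (is.null(other)) next
    overlap <- intersect(injection_ids(test$matrix),
                         injection_ids(other$matrix))
    if (length(overlap))
      pf_stop("pf_leakage_error",
              "injection %s appears in the testing study and in a %s study",
              overlap[1], "training/validation")
  }
  splits <- list(testing = test)
  if (!is.null(train)) splits$training <- train
  if (!is.null(validation)) splits$validation <- validation
  confusion <- list()
  metrics <- list()
  for (nm in names(splits)) {
    f <- panel_features(splits[[nm]]$matrix, splits[[nm]]$design, cstar$panel)
    s <- predict_score(model, f$x)
    cm <- confusion_from_scores(s, f$labels)
    met <- confusion_metrics(cm)
    confusion[[nm]] <- cm
    metrics[[nm]] <- c(as.list(met), auc = auc_scores(s, f$labels))
  }
  ord <- intersect(c("training", "validation", "testing"), names(splits))
  list(confusion = confusion[ord], metrics = metrics[ord])
}

#' Exhaustive panel search under the three-way split
#'
#' Enumerates every N-panel from the candidate pool, evaluates each with
#' [evaluate_panel()], selects C* by validation AUC, and (unless
#' `assess = FALSE`) assesses C* once on the testing study.
#'
#' @param candidates ordered candidate protein ids (screen p-value order).
#' @param train,validation,test per-study lists with `matrix` and `design`.
#' @param N panel size (default 5).
#' @param config a [training_config()].
#' @param pool_cap keep only the first `pool_cap` candidates (the screen's
#'   best); `Inf` disables the cap. `choose(32, 5)` is a long-running mode —
#'   the default cap keeps desk-scale runs in minutes.
#' @param assess run [assess_on_test()] on C*.
#' @param progress_every log every this many panels to stderr (0 = silent).
#' @inheritParams evaluate_panel
#' @return list of class `search_result`: `ranking` (list of ranked
#'   `panel_candidate`s), `cstar` (with `test_metrics` when assessed),
#'   `config` echo.
#' @export
search_panels <- function(candidates, train, validation, test = NULL, N = 5L,
                          config = training_config(), pool_cap = 10L,
                          assess = !is.null(test), k = 5L, eval_every = 5L,
                          progress_every = 0L) {
  pool <- head(candidates, pool_cap)
  panels <- enumerate_panels(pool, N)
  evaluated <- vector("list", nrow(panels))
  for (i in seq_len(nrow(panels))) {
    evaluated[[i]] <- evaluate_panel(panels[i, ], train, validation,
                                     config = config, k = k,
                                     eval_every = eval_every)
    if (progress_every > 0 && i %% progress_every == 0)
      message(sprintf("evaluated %d / %d panels", i, nrow(panels)))
  }
  cstar <- select_optimal(evaluated)
  ranking <- attr(cstar, "ranking")
  attr(cstar, "ranking") <- NULL
  if (assess) {
    if (is.null(test))
      pf_stop("pf_validation_error", "assess = TRUE requires test data")
    cstar$test_metrics <- assess_on_test(cstar, cstar$model, test,
                                         train = train,
                                         validation = validation)
  }
  ranking[[1]] <- cstar
  structure(list(ranking = ranking, cstar = cstar,
                 config = list(N = N, pool_cap = pool_cap,
                               pool_size = length(pool),
                               n_panels = nrow(panels),
                               seed = config$seed,
                               learning_rate = config$learning_rate,
                               max_epochs = config$max_epochs)),
            class = "search_result")
}

#' @export
print.search_result <- function(x, ...) {
  cat(sprintf("<search_result> %d panels evaluated (N = %s)\n",
              length(x$ranking), x$config$N))
  if (!is.null(x$cstar)) {
    cat(sprintf("  C* = [%s], validation AUC %.4f\n",
                panel_string(x$cstar$panel), x$cstar$validation_auc))
    tm <- x$cstar$test_metrics
    if (!is.null(tm) && !is.null(tm$metrics$testing))
      cat(sprintf("  test: accuracy %.2f%%, AUC %.4f\n",
                  tm$metrics$testing$accuracy, tm$metrics$testing$auc))
  }
  invisible(x)
}
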