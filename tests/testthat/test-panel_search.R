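test_that("panel enumeration is exhaustive, ordered, duplicate-free", {
  ids5 <- sprintf("p%d", 1:5)
  expect_identical(nrow(enumerate_panels(ids5, 5)), 1L)

  ids6 <- sprintf("p%d", 1:6)
  panels <- enumerate_panels(ids6, 3)
  expect_identical(nrow(panels), 20L)
  keys <- apply(panels, 1, paste, collapse = ";")
  expect_identical(anyDuplicated(keys), 0L)
  expect_false(is.unsorted(keys)) # lexicographic in candidate order (p1<p2<...)
  expect_identical(panels[1, ], c("p1", "p2", "p3"))
  expect_identical(panels[20, ], c("p4", "p5", "p6"))

  expect_error(enumerate_panels(ids5, 6), class = "pf_validation_error")
})

test_that("panel features are per-sample replicate means", {
  st <- simulate_study(simulation_config(n_proteins = 4, n_informative = 2,
                                         n_cancer = 3, n_control = 3,
                                         n_replicates = 2, seed = 4))
  f <- panel_features(st$matrix, st$design, c("P0002", "P0001"))
  expect_identical(dim(f$x), c(6L, 2L))
  s1 <- f$sample_ids[1]
  cols <- st$design$injection_id[st$design$sample_id == s1]
  expect_equal(unname(f$x[1, "P0002"]),
               mean(unclass(st$matrix)["P0002", cols]))
  expect_error(panel_features(st$matrix, st$design, "P9999"),
               class = "pf_evaluation_error")
})

test_that("evaluate_panel is deterministic and separates informative panels", {
  st <- quick_three_studies(seed = 8)
  panel <- st$truth$informative_protein_ids
  train <- st$A
  val <- st$C
  p1 <- evaluate_panel(panel, train, val, config = training_config(seed = 8))
  p2 <- evaluate_panel(panel, train, val, config = training_config(seed = 8))
  expect_identical(p1$model$W1, p2$model$W1)
  expect_identical(p1$validation_auc, p2$validation_auc)
  expect_identical(p1$training_sse, p2$training_sse)
  expect_gte(p1$validation_auc, 0.9)
})

test_that("pure-noise panels score near chance on validation", {
  aucs <- vapply(1:5, function(s) {
    st <- quick_three_studies(seed = 200 + s, effect = 0, n_informative = 0,
                              n_proteins = 10, n_cancer = 15, n_control = 15)
    evaluate_panel(protein_ids(st$A$matrix)[1:5], st$A, st$C,
                   config = training_config(seed = s,
                                            max_epochs = 150))$validation_auc
  }, numeric(1))
  expect_gte(mean(aucs), 0.3)
  expect_lte(mean(aucs), 0.7)
})

mock_candidate <- function(panel, vauc, sse) {
  structure(list(panel = panel, training_sse = sse, cv_summary = NULL,
                 cv_mean_auc = vauc, validation_auc = vauc,
                 training_accuracy = NA_real_,
                 validation_accuracy = NA_real_, model = NULL),
            class = "panel_candidate")
}

test_that("select_optimal maximizes validation AUC with deterministic ties", {
  single <- mock_candidate(c("a", "b"), 0.8, 0.1)
  expect_identical(select_optimal(list(single))$panel, c("a", "b"))

  cands <- list(mock_candidate(c("x", "y"), 0.8, 0.01),
                mock_candidate(c("a", "b"), 0.9, 0.05),
                mock_candidate(c("c", "d"), 0.9, 0.02))
  best <- select_optimal(cands)
  expect_identical(best$panel, c("c", "d")) # AUC tie broken by lower SSE

  # order invariance
  shuffled <- select_optimal(cands[c(3, 1, 2)])
  expect_identical(shuffled$panel, best$panel)
  expect_identical(
    vapply(attr(shuffled, "ranking"), function(p) paste(p$panel, collapse = ";"),
           character(1)),
    vapply(attr(best, "ranking"), function(p) paste(p$panel, collapse = ";"),
           character(1)))

  # exact tie on AUC and SSE: lexicographic panel ids
  tie <- select_optimal(list(mock_candidate(c("z", "w"), 0.9, 0.1),
                             mock_candidate(c("a", "b"), 0.9, 0.1)))
  expect_identical(tie$panel, c("a", "b"))

  expect_error(select_optimal(list()), class = "pf_validation_error")
})

test_that("assess_on_test reports the one-shot confusion and catches leakage", {
  st <- quick_three_studies(seed = 14)
  panel <- st$truth$informative_protein_ids
  pc <- evaluate_panel(panel, st$A, st$C, config = training_config(seed = 14))
  tm <- assess_on_test(pc, pc$model, st$B, train = st$A, validation = st$C)
  expect_named(tm$metrics, c("training", "validation", "testing"))
  expect_gte(tm$metrics$testing$accuracy, 90)
  expect_gte(tm$metrics$testing$auc, 0.9)
  cmt <- tm$confusion$testing
  expect_identical(cmt$tp + cmt$fp + cmt$fn + cmt$tn,
                   length(unique(st$B$design$sample_id)))

  # constant-score model predicts all-control: accuracy = control fraction
  zero <- manual_model(matrix(0, 3, 5), rep(0, 3), matrix(0, 2, 3), rep(0, 2))
  tm0 <- assess_on_test(pc, zero, st$B)
  expect_equal(tm0$metrics$testing$accuracy,
               100 * mean(unique(st$B$design[c("sample_id", "group")])$group
                          == "control"))

  # shared injection id between test and train studies
  leaky <- st$B
  colnames(leaky$matrix)[1] <- injection_ids(st$A$matrix)[1]
  leaky$design$injection_id[1] <- injection_ids(st$A$matrix)[1]
  expect_error(assess_on_test(pc, pc$model, leaky, train = st$A),
               class = "pf_leakage_error")
})

test_that("search evaluates exactly choose(pool, N) panels and is replayable without test data", {
  st <- quick_three_studies(seed = 20, n_proteins = 12, n_informative = 3)
  cands <- screen_candidates(st$A$matrix, st$A$design, alpha = 1)$protein_ids
  res <- search_panels(cands, st$A, st$C, test = st$B, N = 3,
                       config = training_config(seed = 20), pool_cap = 6)
  expect_identical(length(res$ranking), 20L) # choose(6, 3)
  keys <- vapply(res$ranking, function(p) paste(p$panel, collapse = ";"),
                 character(1))
  expect_identical(anyDuplicated(keys), 0L)
  # ranked by descending validation AUC
  vaucs <- vapply(res$ranking, `[[`, numeric(1), "validation_auc")
  expect_false(is.unsorted(rev(vaucs)))
  # test metrics only on C*
  has_test <- vapply(res$ranking, function(p) !is.null(p$test_metrics),
                     logical(1))
  expect_identical(which(has_test), 1L)

  # anti-leakage: identical C* when the testing study is withheld
  res2 <- search_panels(cands, st$A, st$C, test = NULL, N = 3,
                        config = training_config(seed = 20), pool_cap = 6,
                        assess = FALSE)
  expect_identical(res2$cstar$panel, res$cstar$panel)
  expect_identical(res2$cstar$validation_auc, res$cstar$validation_auc)
})
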