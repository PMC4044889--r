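test_that("common_proteins intersects in first-matrix order", {
  mk <- function(ids) intensity_matrix(
    matrix(0, length(ids), 2,
           dimnames = list(ids, c("i1", "i2"))))
  expect_identical(common_proteins(list(mk(c("a", "b")), mk(c("a", "b")))),
                   c("a", "b"))
  expect_identical(common_proteins(list(mk(c("a", "b")), mk(c("c", "d")))),
                   character(0))
  expect_identical(common_proteins(list(mk(c("a", "b", "c")),
                                        mk(c("b", "c", "d")),
                                        mk(c("c", "b")))),
                   c("b", "c"))
  expect_error(common_proteins(list(mk("a"))), class = "pf_validation_error")
})

test_that("no-signal data gives F = 0, p = 1", {
  d <- make_design(n_per_group = 3, r = 2)
  fit <- fit_protein_anova(rep(5, nrow(d)), d)
  expect_identical(fit$f_statistic, 0)
  expect_identical(fit$p_value, 1)
})

test_that("nested ANOVA matches the reference mixed-model fitter", {
  d <- make_design(n_per_group = 3, r = 2)
  withr::local_seed(31)
  for (i in 1:5) {
    y <- rnorm(nrow(d))
    fit <- fit_protein_anova(setNames(y, d$injection_id), d)
    df <- data.frame(y = y, group = d$group, sample = d$sample_id)
    strata <- summary(stats::aov(y ~ group + Error(sample), data = df))
    ref <- strata[["Error: sample"]][[1]]
    expect_equal(fit$f_statistic, ref["group", "F value"], tolerance = 1e-9)
    expect_equal(fit$p_value, ref["group", "Pr(>F)"], tolerance = 1e-9)
    expect_equal(fit$df_num, 1)
    expect_equal(fit$df_den, 4)
    # variance components from the reference expected mean squares:
    # E[MS_samp] = sigma_w^2 + r sigma2^2 on the injection scale
    mse <- summary(stats::aov(y ~ sample, df))[[1]]["Residuals", "Mean Sq"]
    ms_samp <- ref["Residuals", "Mean Sq"] # injection-scale sample MS
    expect_equal(fit$var_residual, mse, tolerance = 1e-9)
    expect_equal(fit$var_sample, max(0, (ms_samp - mse) / 2),
                 tolerance = 1e-9)
  }
})

test_that("a strongly differential simulated protein is overwhelmingly significant", {
  base <- simulation_config()
  cfg <- simulation_config(n_proteins = 1, n_informative = 1,
                           effect_size = 5 * sigma_total(base),
                           n_cancer = 40, n_control = 40, seed = 17)
  st <- simulate_study(cfg)
  fit <- fit_protein_anova(unclass(st$matrix)[1, ], st$design)
  expect_lt(fit$p_value, 1e-6)
})

test_that("F is invariant to location shifts and positive scaling", {
  d <- make_design(n_per_group = 4, r = 2)
  withr::local_seed(5)
  y <- rnorm(nrow(d))
  f0 <- fit_protein_anova(y, d)$f_statistic
  expect_equal(fit_protein_anova(y + 100, d)$f_statistic, f0,
               tolerance = 1e-10)
  expect_equal(fit_protein_anova(y * 7.5, d)$f_statistic, f0,
               tolerance = 1e-10)
})

test_that("degrees-of-freedom guards fire", {
  d <- make_design(n_per_group = 1, r = 2)
  expect_error(fit_protein_anova(rnorm(nrow(d)), d), class = "pf_df_error")
  # single group
  d2 <- as.data.frame(make_design(n_per_group = 2, r = 2))
  d2$group <- "cancer"
  expect_error(fit_protein_anova(rnorm(nrow(d2)), study_design(d2)),
               class = "pf_df_error")
})

test_that("screen retains planted markers and orders by ascending p", {
  base <- simulation_config()
  effect <- 2 * sigma_total(base)
  hits <- 0L
  for (seed in 1:10) {
    cfg <- simulation_config(n_proteins = 205, n_informative = 5,
                             effect_size = effect, n_cancer = 40,
                             n_control = 40, seed = seed)
    st <- simulate_study(cfg)
    cs <- screen_candidates(st$matrix, st$design, alpha = 0.01)
    if (all(st$truth$informative_protein_ids %in% cs$protein_ids))
      hits <- hits + 1L
    expect_false(is.unsorted(cs$results$p_value))
    expect_true(all(cs$results$p_value[
      cs$results$protein_id %in% cs$protein_ids] < 0.01))
  }
  expect_identical(hits, 10L)
})

test_that("alpha = 0 yields an empty candidate set", {
  st <- simulate_study(simulation_config(n_proteins = 10, n_cancer = 4,
                                         n_control = 4, seed = 2))
  cs <- screen_candidates(st$matrix, st$design, alpha = 0)
  expect_identical(cs$protein_ids, character(0))
})

test_that("variance-component estimates have small relative bias", {
  cfg <- simulation_config(n_proteins = 500, n_informative = 0,
                           effect_size = 0, sigma_sample = 1,
                           sigma_replicate = 0.5, sigma_error = 0.5,
                           n_cancer = 40, n_control = 40, n_replicates = 2,
                           seed = 19)
  st <- simulate_study(cfg)
  cs <- screen_candidates(st$matrix, st$design, alpha = 1)
  # true sigma2^2 = 1, true pooled within-sample variance = 0.5
  expect_lt(abs(mean(cs$results$var_sample) - 1) / 1, 0.1)
  expect_lt(abs(mean(cs$results$var_residual) - 0.5) / 0.5, 0.1)
})

test_that("unfittable proteins are skipped with a warning", {
  d <- make_design(n_per_group = 2, r = 2)
  v <- matrix(rnorm(2 * nrow(d)), 2, nrow(d),
              dimnames = list(c("ok", "bad"), d$injection_id))
  v["bad", d$group == "cancer"] <- NA # loses one whole group
  m <- intensity_matrix(v)
  expect_warning(cs <- screen_candidates(m, d, alpha = 1), "bad")
  expect_identical(cs$results$protein_id, "ok")
})
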