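# Per-protein mixed-model ANOVA screening.
#
# Model: y_ijk = mu + T_j + S_k + I_i + e_ijk with samples S_k nested in
# groups. With one measurement per protein per injection the replicate
# effect I_i and the residual e_ijk are confounded, so the fitter estimates
# their pooled variance; the F-test for the group effect uses
# sample-within-group as the denominator stratum, which is the only
# estimable, correct test at this data granularity. On balanced data this F
# equals the classical nested ANOVA F = MS(group) / MS(sample within group).

#' Intersect protein sets across studies
#'
#' @param matrices list of two or more [intensity_matrix()] objects.
#' @return character vector: protein ids present in every matrix, in the
#'   first matrix's row order.
#' @export
common_proteins <- function(matrices) {
  if (length(matrices) < 2)
    pf_stop("pf_validation_error", "need at least two matrices")
  ids <- protein_ids(matrices[[1]])
  for (m in matrices[-1]) ids <- ids[ids %in% protein_ids(m)]
  ids
}

#' Fit the per-protein nested ANOVA
#'
#' Tests the fixed cancer/control group effect against between-sample
#' variation. The test is computed on per-sample replicate means:
#' F = MS(between groups) / MS(samples within groups) with degrees of
#' freedom (g - 1, N_samples - g) — identical to the balanced two-level
#' nested ANOVA F for the group effect. Variance components are estimated
#' by method of moments from expected mean squares: `var_sample` estimates
#' the between-sample variance sigma2^2 and `var_residual` the pooled
#' replicate-plus-residual variance sigma1^2 + sigma^2 (both truncated at
#' zero; `var_residual` is `NA` when every sample has a single replicate).
#'
#' @param values numeric vector of one protein's measurements, named by or
#'   aligned with `design$injection_id`; `NA` entries are dropped.
#' @param design a [study_design()] covering the injections.
#' @param denominator `"sample"` (default) tests the group effect against
#'   sample-within-group variation; `"residual"` is the naive injection-level
#'   one-way ANOVA that ignores the nesting (anticonservative under real
#'   sample-to-sample variation; provided for comparison only).
#' @return list of class `anova_result`: `f_statistic`, `p_value`, `df_num`,
#'   `df_den`, `var_sample`, `var_residual`, `group_means`, `mean_diff`
#'   (cancer minus control), `degenerate` flag.
#' @export
fit_protein_anova <- function(values, design,
                              denominator = c("sample", "residual")) {
  denominator <- match.arg(denominator)
  design <- as.data.frame(design)
  if (!is.null(names(values)))
    values <- values[design$injection_id]
  if (length(values) != nrow(design))
    pf_stop("pf_validation_error",
            "values length %d does not match %d injections",
            length(values), nrow(design))
  keep <- !is.na(values)
  y <- as.numeric(values[keep])
  grp <- design$group[keep]
  samp <- design$sample_id[keep]

  groups <- sort(unique(grp))
  if (length(groups) < 2)
    pf_stop("pf_df_error", "need at least two groups with data")
  sample_mean <- tapply(y, samp, mean)
  sample_group <- tapply(grp, samp, `[`, 1L)
  n_per_group <- table(sample_group)
  if (any(n_per_group < 2))
    pf_stop("pf_df_error", "group %s has fewer than two samples",
            names(n_per_group)[which(n_per_group < 2)[1]])

  g <- length(groups)
  ns <- length(sample_mean)
  group_means <- tapply(sample_mean, sample_group, mean)
  grand <- mean(sample_mean)
  ss_between <- sum(as.numeric(n_per_group) *
                      (group_means[names(n_per_group)] - grand)^2)
  ss_within <- sum((sample_mean - group_means[sample_group])^2)
  ms_between <- ss_between / (g - 1)
  ms_within <- ss_within / (ns - g)

  # pooled replicate + residual variance from within-sample scatter
  reps <- table(samp)
  df_err <- sum(as.numeric(reps) - 1)
  if (df_err > 0) {
    ss_err <- sum((y - sample_mean[samp])^2)
    var_residual <- ss_err / df_err
  } else var_residual <- NA_real_
  r_bar <- mean(as.numeric(reps))
  var_sample <- if (is.na(var_residual)) NA_real_ else
    max(0, ms_within - var_residual / r_bar)

  if (denominator == "residual") {
    inj_group_means <- tapply(y, grp, mean)
    grand_y <- mean(y)
    n_g <- table(grp)
    ssb <- sum(as.numeric(n_g) * (inj_group_means[names(n_g)] - grand_y)^2)
    ssw <- sum((y - inj_group_means[grp])^2)
    df_num <- g - 1
    df_den <- length(y) - g
    ms_between <- ssb / df_num
    ms_within <- ssw / df_den
  } else {
    df_num <- g - 1
    df_den <- ns - g
  }

  degenerate <- FALSE
  if (ms_within <= 0) {
    if (ms_between <= 0) {
      f <- 0
      p <- 1
    } else {
      f <- Inf
      p <- 0
      degenerate <- TRUE
    }
  } else {
    f <- ms_between / ms_within
    p <- pf(f, df_num, df_den, lower.tail = FALSE)
  }
  gm <- as.numeric(group_means)
  names(gm) <- names(group_means)
  mean_diff <- if (all(c("cancer", "control") %in% names(gm)))
    gm[["cancer"]] - gm[["control"]] else NA_real_
  structure(list(f_statistic = f, p_value = p, df_num = df_num,
                 df_den = df_den, var_sample = var_sample,
                 var_residual = var_residual, group_means = gm,
                 mean_diff = mean_diff, degenerate = degenerate),
            class = "anova_result")
}

#' Screen candidate marker proteins on the training study
#'
#' Applies [fit_protein_anova()] to every protein and keeps those with raw
#' (unadjusted) p-value below `alpha`, ordered by ascending p-value; ties
#' are broken by descending absolute cancer-minus-control mean difference,
#' then protein id. Proteins whose fit fails (e.g. too few samples with
#' data) are skipped with a warning.
#'
#' @param matrix an [intensity_matrix()] restricted to the training study.
#' @param design the matching [study_design()].
#' @param alpha raw p-value threshold (the canonical screen uses 0.01).
#' @param denominator passed to [fit_protein_anova()].
#' @return list of class `candidate_set`: `protein_ids` (ordered retained
#'   ids), `alpha`, and `results` (data.frame of per-protein statistics for
#'   all proteins that could be fit).
#' @export
screen_candidates <- function(matrix, design, alpha = 0.01,
                              denominator = "sample") {
  check_design_matches(matrix, design)
  design <- as.data.frame(design)
  design <- design[design$injection_id %in% injection_ids(matrix), ]
  v <- unclass(matrix)[, design$injection_id, drop = FALSE]
  prot <- rownames(v)
  rows <- vector("list", length(prot))
  for (i in seq_along(prot)) {
    fit <- tryCatch(fit_protein_anova(v[i, ], design, denominator),
                    pf_df_error = function(e) e,
                    pf_validation_error = function(e) e)
    if (inherits(fit, "condition")) {
      warning(sprintf("skipping protein %s: %s", prot[i],
                      conditionMessage(fit)), call. = FALSE)
      next
    }
    rows[[i]] <- data.frame(protein_id = prot[i],
                            f_statistic = fit$f_statistic,
                            p_value = fit$p_value,
                            df_num = fit$df_num, df_den = fit$df_den,
                            var_sample = fit$var_sample,
                            var_residual = fit$var_residual,
                            mean_diff = fit$mean_diff,
                            stringsAsFactors = FALSE)
  }
  results <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(results))
    results <- data.frame(protein_id = character(0),
                          f_statistic = numeric(0), p_value = numeric(0),
                          df_num = numeric(0), df_den = numeric(0),
                          var_sample = numeric(0), var_residual = numeric(0),
                          mean_diff = numeric(0))
  ord <- order(results$p_value, -abs(results$mean_diff), results$protein_id)
  results <- results[ord, , drop = FALSE]
  rownames(results) <- NULL
  keep <- results$protein_id[results$p_value < alpha]
  structure(list(protein_ids = keep, alpha = alpha, results = results),
            class = "candidate_set")
}

#' @export
print.candidate_set <- function(x, ...) {
  cat(sprintf("<candidate_set> %d of %d proteins with p < %g\n",
              length(x$protein_ids), nrow(x$results), x$alpha))
  invisible(x)
}
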