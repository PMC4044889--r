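# Simulator for case/control plasma-proteomics studies under the per-protein
# nested mixed model
#
#   y_ijk = mu + T_j + S_k + I_i + e_ijk
#
# with fixed group effect T_j (a log2-scale shift applied to the cancer
# group for informative proteins), random sample effect S_k ~ N(0, sigma2^2),
# random replicate-injection effect I_i ~ N(0, sigma1^2), and residual
# e_ijk ~ N(0, sigma^2), all independent, drawn per protein.

#' Simulation configuration
#'
#' Defaults emulate one arm of a plasma LC-MS/MS case/control study: 40
#' cancer vs 40 control samples, 2 replicate injections each, 246 proteins
#' of which a handful carry a 2 log2-unit cancer shift. Variance defaults
#' (sample 1.0, replicate 0.25, residual 0.25 on the variance scale) are
#' package choices, not literature values.
#'
#' @param n_proteins number of proteins per study.
#' @param n_informative number of planted differential proteins.
#' @param effect_size log2-units shift added to the cancer group for
#'   informative proteins (the fixed effect).
#' @param baseline_mu grand mean log2 intensity.
#' @param sigma_sample,sigma_replicate,sigma_error standard deviations of
#'   the random sample effect, replicate-injection effect and residual.
#' @param n_cancer,n_control samples per group.
#' @param n_replicates replicate injections per sample.
#' @param seed integer master seed; all draws are deterministic given it.
#' @param effect_sizes optional per-protein override: named numeric vector
#'   of length `n_informative` (names become the informative protein ids'
#'   effects in planting order).
#' @return list of class `simulation_config`.
#' @export
simulation_config <- function(n_proteins = 246, n_informative = 5,
                              effect_size = 2.0, baseline_mu = 20,
                              sigma_sample = 1.0, sigma_replicate = 0.5,
                              sigma_error = 0.5, n_cancer = 40,
                              n_control = 40, n_replicates = 2, seed = 1,
                              effect_sizes = NULL) {
  cfg <- list(n_proteins = as.integer(n_proteins),
              n_informative = as.integer(n_informative),
              effect_size = effect_size, baseline_mu = baseline_mu,
              sigma_sample = sigma_sample, sigma_replicate = sigma_replicate,
              sigma_error = sigma_error, n_cancer = as.integer(n_cancer),
              n_control = as.integer(n_control),
              n_replicates = as.integer(n_replicates),
              seed = as.integer(seed), effect_sizes = effect_sizes)
  if (cfg$n_proteins < 1 || cfg$n_cancer < 1 || cfg$n_control < 1 ||
      cfg$n_replicates < 1)
    pf_stop("pf_config_error", "counts must be positive")
  if (cfg$n_informative < 0 || cfg$n_informative > cfg$n_proteins)
    pf_stop("pf_config_error",
            "n_informative must lie in [0, n_proteins]")
  if (cfg$sigma_sample < 0 || cfg$sigma_replicate < 0 || cfg$sigma_error < 0)
    pf_stop("pf_config_error", "sigmas must be nonnegative")
  if (!is.null(effect_sizes) && length(effect_sizes) != cfg$n_informative)
    pf_stop("pf_config_error",
            "effect_sizes must have length n_informative")
  class(cfg) <- "simulation_config"
  cfg
}

#' Total per-observation standard deviation implied by a config
#'
#' sqrt(sigma_sample^2 + sigma_replicate^2 + sigma_error^2); the natural
#' unit for expressing planted effect sizes.
#' @param config a [simulation_config()].
#' @export
sigma_total <- function(config) {
  sqrt(config$sigma_sample^2 + config$sigma_replicate^2 +
         config$sigma_error^2)
}

sim_ids <- function(config, study_label) {
  n_samp <- config$n_cancer + config$n_control
  group <- rep(c("cancer", "control"), c(config$n_cancer, config$n_control))
  sample_id <- sprintf("%s_%s_%02d", study_label, group,
                       c(seq_len(config$n_cancer), seq_len(config$n_control)))
  data.frame(
    injection_id = sprintf("%s_r%d", rep(sample_id, each = config$n_replicates),
                           rep(seq_len(config$n_replicates), n_samp)),
    sample_id = rep(sample_id, each = config$n_replicates),
    group = rep(group, each = config$n_replicates),
    study = study_label,
    replicate = rep(seq_len(config$n_replicates), n_samp),
    stringsAsFactors = FALSE)
}

draw_study_values <- function(config, design, protein_ids_vec, truth) {
  p <- length(protein_ids_vec)
  n_inj <- nrow(design)
  samples <- unique(design$sample_id)
  # per-protein random sample effects, expanded to injections
  S <- matrix(rnorm(p * length(samples), 0, config$sigma_sample),
              p, length(samples))
  vals <- config$baseline_mu +
    S[, match(design$sample_id, samples), drop = FALSE] +
    matrix(rnorm(p * n_inj, 0, config$sigma_replicate), p, n_inj) +
    matrix(rnorm(p * n_inj, 0, config$sigma_error), p, n_inj)
  inform <- match(truth$informative_protein_ids, protein_ids_vec)
  inform <- inform[!is.na(inform)]
  if (length(inform)) {
    cancer_cols <- design$group == "cancer"
    vals[inform, cancer_cols] <- vals[inform, cancer_cols] +
      truth$effect_sizes[match(protein_ids_vec[inform],
                               truth$informative_protein_ids)]
  }
  intensity_matrix(vals, protein_ids = protein_ids_vec,
                   injection_ids = design$injection_id)
}

make_truth <- function(config, informative_ids) {
  effects <- if (is.null(config$effect_sizes))
    rep(config$effect_size, config$n_informative)
  else as.numeric(config$effect_sizes)
  list(informative_protein_ids = informative_ids,
       effect_sizes = setNames(effects, informative_ids))
}

#' Simulate one case/control study
#'
#' Draws a proteins-by-injections log2 intensity matrix under the nested
#' mixed model, together with its study design and the ground truth of
#' planted differential proteins. Fully deterministic given
#' `(config$seed, study_label)`.
#'
#' @param config a [simulation_config()].
#' @param study_label study label, conventionally `"A"`, `"B"` or `"C"`.
#' @return list with elements `matrix` ([intensity_matrix()]), `design`
#'   ([study_design()]), `truth` (informative ids and effect sizes).
#' @export
simulate_study <- function(config, study_label = "A") {
  stopifnot(inherits(config, "simulation_config"))
  prot <- sprintf("P%04d", seq_len(config$n_proteins))
  truth <- make_truth(config, head(prot, config$n_informative))
  design <- study_design(sim_ids(config, study_label))
  mat <- with_seed(seed_hash(config$seed, c("study", study_label)),
                   draw_study_values(config, design, prot, truth))
  list(matrix = mat, design = design, truth = truth)
}

#' Simulate a three-study train/validation/test scenario
#'
#' Studies A and B use the configured group sizes; study C uses half of
#' each (rounded up), mirroring the canonical 40/40, 40/40, 20/20 layout.
#' Each study measures `n_proteins` proteins of which a shared core of
#' `round(overlap_fraction * n_proteins)` is common to all three; the
#' remaining proteins are study-specific. Informative proteins always lie
#' in the core (so the cross-study intersection never discards signal).
#'
#' @inheritParams simulate_study
#' @param overlap_fraction fraction in (0, 1] of each study's proteins that
#'   form the shared core.
#' @return list with elements `A`, `B`, `C` (each as in
#'   [simulate_study()]) and `truth` shared across studies.
#' @export
simulate_three_studies <- function(config, overlap_fraction = 1.0) {
  stopifnot(inherits(config, "simulation_config"))
  if (overlap_fraction <= 0 || overlap_fraction > 1)
    pf_stop("pf_config_error", "overlap_fraction must be in (0, 1]")
  n_core <- round(config$n_proteins * overlap_fraction)
  if (n_core < config$n_informative)
    pf_stop("pf_config_error",
            "shared core (%d proteins) smaller than n_informative (%d)",
            n_core, config$n_informative)
  core <- sprintf("P%04d", seq_len(n_core))
  truth <- make_truth(config, head(core, config$n_informative))
  n_extra <- config$n_proteins - n_core
  out <- list()
  for (lab in c("A", "B", "C")) {
    cfg <- config
    if (lab == "C") {
      cfg$n_cancer <- as.integer(ceiling(config$n_cancer / 2))
      cfg$n_control <- as.integer(ceiling(config$n_control / 2))
    }
    prot <- c(core, if (n_extra > 0)
      sprintf("%s_X%04d", lab, seq_len(n_extra)))
    design <- study_design(sim_ids(cfg, lab))
    mat <- with_seed(seed_hash(config$seed, c("study", lab)),
                     draw_study_values(cfg, design, prot, truth))
    out[[lab]] <- list(matrix = mat, design = design)
  }
  out$truth <- truth
  out
}
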