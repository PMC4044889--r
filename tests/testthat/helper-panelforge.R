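# Shared fixtures and independent oracles.

# small deterministic intensity matrix with optional missing cells
make_matrix <- function(n_prot = 3, n_inj = 4, seed = 1, na_cells = 0) {
  withr::local_seed(seed)
  v <- matrix(round(rnorm(n_prot * n_inj, 20, 2), 4), n_prot, n_inj,
              dimnames = list(sprintf("prot%d", seq_len(n_prot)),
                              sprintf("inj%d", seq_len(n_inj))))
  if (na_cells > 0) v[sample(length(v), na_cells)] <- NA
  intensity_matrix(v)
}

# balanced design: n_samples per group, r replicates
make_design <- function(n_per_group = 2, r = 2, study = "A") {
  n <- 2 * n_per_group
  sample_id <- sprintf("%s_s%02d", study, seq_len(n))
  study_design(data.frame(
    injection_id = sprintf("%s_r%d", rep(sample_id, each = r),
                           rep(seq_len(r), n)),
    sample_id = rep(sample_id, each = r),
    group = rep(c("cancer", "control"), each = n_per_group * r),
    study = study,
    replicate = rep(seq_len(r), n)))
}

# brute-force Mann-Whitney AUC: correctly ordered pairs + half ties
pair_count_auc <- function(scores, labels) {
  pos <- scores[labels == "cancer"]
  neg <- scores[labels == "control"]
  total <- 0
  for (p in pos) for (q in neg)
    total <- total + (p > q) + 0.5 * (p == q)
  total / (length(pos) * length(neg))
}

# SSE of a model on a batch, via the exported forward pass only
ffnn_sse <- function(model, x, labels) {
  out <- forward(model, x)
  targets <- cbind(labels == "cancer", labels == "control")
  sum((targets - out)^2)
}

# hand-built model with explicit weights (no standardization)
manual_model <- function(W1, b1, W2, b2) {
  arch <- network_architecture(ncol(W1), nrow(W1))
  panelforge:::new_ffnn_model(arch, list(W1 = W1, b1 = b1, W2 = W2, b2 = b2),
                              NULL, NULL, training_config())
}

random_model <- function(n_input = 5, n_hidden = 3, seed = 1) {
  arch <- network_architecture(n_input, n_hidden)
  w <- panelforge:::with_seed(seed,
                              panelforge:::init_weights(arch, training_config()))
  panelforge:::new_ffnn_model(arch, w, NULL, NULL, training_config())
}

# clearly separable two-class feature matrix
separable_data <- function(n_per_class = 40, p = 5, gap = 4, seed = 1) {
  withr::local_seed(seed)
  x <- rbind(matrix(rnorm(n_per_class * p, gap), n_per_class, p),
             matrix(rnorm(n_per_class * p, 0), n_per_class, p))
  list(x = x, labels = rep(c("cancer", "control"), each = n_per_class))
}

# quick three-study simulation for search tests
quick_three_studies <- function(seed = 1, n_proteins = 30, effect = NULL,
                                n_informative = 5, n_cancer = 20,
                                n_control = 20) {
  base <- simulation_config()
  if (is.null(effect)) effect <- 2 * sigma_total(base)
  cfg <- simulation_config(n_proteins = n_proteins,
                           n_informative = n_informative,
                           effect_size = effect, n_cancer = n_cancer,
                           n_control = n_control, seed = seed)
  simulate_three_studies(cfg)
}
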