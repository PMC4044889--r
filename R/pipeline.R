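# End-to-end orchestration: simulate/load -> normalize -> intersect ->
# screen -> exhaustive panel search -> one-shot test assessment -> report.

#' Pipeline configuration
#'
#' Studies may come from disk (`studies` = list of
#' `list(matrix = path, metadata = path)`) or from the simulator
#' (`sim_config` plus `overlap_fraction`). Exactly one of the two sources
#' must be given.
#'
#' @param studies named list (`A`, `B`, `C`) of file-path pairs, or `NULL`.
#' @param sim_config a [simulation_config()], or `NULL`.
#' @param overlap_fraction passed to [simulate_three_studies()].
#' @param split role assignment: named character vector mapping roles
#'   `training`, `validation`, `testing` to study labels. Default is the
#'   canonical split: A trains, C validates, B tests.
#' @param N panel size.
#' @param alpha screening p-value threshold.
#' @param pool_cap candidate pool cap for the search.
#' @param training a [training_config()].
#' @param log2_input log2-transform matrices after reading (for linear-scale
#'   input files; simulated data is already on the log2 scale).
#' @param normalize quantile-normalize each study before intersection.
#' @param seed global seed (overrides `training$seed` and `sim_config$seed`).
#' @param out_dir if non-NULL, write the report and manifest there.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(studies = NULL, sim_config = NULL,
                            overlap_fraction = 1.0,
                            split = c(training = "A", validation = "C",
                                      testing = "B"),
                            N = 5L, alpha = 0.01, pool_cap = 10L,
                            training = training_config(),
                            log2_input = FALSE, normalize = TRUE,
                            seed = 1L, out_dir = NULL) {
  if (is.null(studies) == is.null(sim_config))
    pf_stop("pf_config_error",
            "provide exactly one of `studies` or `sim_config`")
  roles <- c("training", "validation", "testing")
  if (!setequal(names(split), roles) || anyDuplicated(split))
    pf_stop("pf_config_error",
            "split must map training/validation/testing to three distinct studies")
  if (!is.null(studies) && !setequal(names(studies), unname(split)))
    pf_stop("pf_config_error", "studies must be named %s",
            paste(sort(unname(split)), collapse = ", "))
  structure(list(studies = studies, sim_config = sim_config,
                 overlap_fraction = overlap_fraction, split = split[roles],
                 N = as.integer(N), alpha = alpha, pool_cap = pool_cap,
                 training = training, log2_input = isTRUE(log2_input),
                 normalize = isTRUE(normalize), seed = as.integer(seed),
                 out_dir = out_dir),
            class = "pipeline_config")
}

load_or_simulate_studies <- function(config) {
  if (!is.null(config$sim_config)) {
    sim <- config$sim_config
    sim$seed <- config$seed
    studies <- simulate_three_studies(sim, config$overlap_fraction)
    studies$truth <- NULL
    return(studies)
  }
  out <- list()
  for (lab in names(config$studies)) {
    paths <- config$studies[[lab]]
    m <- read_intensity_table(paths$matrix)
    d <- read_sample_metadata(paths$metadata)
    out[[lab]] <- list(matrix = m, design = d)
  }
  out
}

#' Run the full panel-discovery pipeline
#'
#' Stages, in order: load or simulate the three studies; optional log2
#' transform; per-study quantile normalization; protein intersection across
#' studies; ANOVA screening on the training study only; exhaustive panel
#' search scored on the validation study; single final assessment of C* on
#' the testing study; report and reproducibility manifest. The testing
#' study's values are only ever read by the final assessment stage.
#'
#' @param config a [pipeline_config()].
#' @param verbose log stage progress to stderr.
#' @return the `search_result`, with the stage log in attribute
#'   `"stage_log"`.
#' @export
run_pipeline <- function(config, verbose = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  t0 <- Sys.time()
  stage_log <- list()
  note <- function(stage, ...) {
    msg <- sprintf(...)
    stage_log[[stage]] <<- list(message = msg,
                                elapsed = as.numeric(Sys.time() - t0,
                                                     units = "secs"))
    if (verbose) message(sprintf("[%s] %s", stage, msg))
  }
  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      pf_stop("pf_pipeline_error", "stage '%s' failed: %s", stage,
              conditionMessage(e))
    })
  }

  studies <- run_stage("load", load_or_simulate_studies(config))
  note("load", "loaded studies %s", paste(names(studies), collapse = ","))

  if (config$log2_input)
    studies <- run_stage("log2", lapply(studies, function(s) {
      s$matrix <- log2_transform(s$matrix); s
    }))
  if (config$normalize) {
    studies <- run_stage("normalize", lapply(studies, function(s) {
      s$matrix <- quantile_normalize(s$matrix); s
    }))
    note("normalize", "quantile-normalized %d studies", length(studies))
  }

  shared <- run_stage("intersect",
                      common_proteins(lapply(studies, `[[`, "matrix")))
  if (!length(shared))
    pf_stop("pf_pipeline_error", "stage 'intersect' failed: no shared proteins")
  studies <- lapply(studies, function(s) {
    s$matrix <- intensity_matrix(unclass(s$matrix)[shared, , drop = FALSE])
    s
  })
  note("intersect", "%d proteins common to all studies", length(shared))

  split <- config$split
  train <- studies[[split[["training"]]]]
  validation <- studies[[split[["validation"]]]]
  test <- studies[[split[["testing"]]]]

  screen <- run_stage("screen",
                      screen_candidates(train$matrix, train$design,
                                        alpha = config$alpha))
  note("screen", "%d candidates at p < %g", length(screen$protein_ids),
       config$alpha)
  if (length(screen$protein_ids) < config$N)
    pf_stop("pf_pipeline_error",
            "stage 'screen' failed: %d candidates < panel size %d",
            length(screen$protein_ids), config$N)

  tcfg <- config$training
  tcfg$seed <- config$seed
  result <- run_stage("search",
                      search_panels(screen$protein_ids, train, validation,
                                    test = test, N = config$N, config = tcfg,
                                    pool_cap = config$pool_cap))
  note("search", "%d panels evaluated; C* = [%s]",
       length(result$ranking), panel_string(result$cstar$panel))

  result$config$alpha <- config$alpha
  result$config$split <- paste(sprintf("%s=%s", names(split), split),
                               collapse = ";")
  result$screen <- screen
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    write_report(result, file.path(config$out_dir, "report.txt"))
    manifest <- list(package = "panelforge",
                     version = as.character(utils::packageVersion("panelforge")),
                     seed = config$seed, N = config$N, alpha = config$alpha,
                     pool_cap = config$pool_cap,
                     split = as.list(config$split),
                     normalize = config$normalize,
                     log2_input = config$log2_input,
                     training = unclass(config$training),
                     sim_config = if (!is.null(config$sim_config))
                       unclass(config$sim_config),
                     overlap_fraction = config$overlap_fraction)
    jsonlite::write_json(manifest,
                         file.path(config$out_dir, "manifest.json"),
                         auto_unbox = TRUE, null = "null", digits = NA)
    note("report", "wrote report and manifest to %s", config$out_dir)
  }
  attr(result, "stage_log") <- stage_log
  result
}
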