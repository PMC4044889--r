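#' @noRd
pf_stop <- function(class, fmt, ...) {
  stop(structure(class = c(class, "panelforge_error", "error", "condition"),
                 list(message = sprintf(fmt, ...), call = sys.call(-1))))
}

#' Run code with a temporary RNG seed, restoring the caller's RNG state.
#' @noRd
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Deterministic 31-bit hash of a seed plus a character key.
#'
#' Used to derive independent sub-seeds (per study, per panel) from one
#' global seed so that parallel and serial execution agree. Arithmetic stays
#' below 2^53 so the double-precision modular reduction is exact.
#' @noRd
seed_hash <- function(seed, key) {
  m <- 2147483647
  h <- (as.double(seed) %% m + m) %% m
  for (ch in utf8ToInt(paste(key, collapse = "|"))) {
    h <- (h * 31 + ch) %% m
  }
  as.integer(h)
}

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a
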