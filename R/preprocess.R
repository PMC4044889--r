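# Preprocessing: log2 transformation and quantile normalization.
# Normalization is applied per study; studies measured at different times
# are never co-normalized.

#' Log2-transform an intensity matrix
#'
#' @param matrix an [intensity_matrix()] in linear intensity units; all
#'   non-missing values must be strictly positive.
#' @return an [intensity_matrix()] in log2 units; missing entries preserved.
#' @export
log2_transform <- function(matrix) {
  v <- unclass(matrix)
  bad <- which(!is.na(v) & v <= 0, arr.ind = TRUE)
  if (nrow(bad))
    pf_stop("pf_domain_error",
            "nonpositive intensity %g at protein %s, injection %s",
            v[bad[1, 1], bad[1, 2]], rownames(v)[bad[1, 1]],
            colnames(v)[bad[1, 2]])
  intensity_matrix(log2(v))
}

#' Quantile-normalize an intensity matrix across injections
#'
#' Forces every injection column to share one empirical distribution: the
#' value of rank r in each column is replaced by the mean, across columns,
#' of each column's rank-r value. Ties within a column receive the average
#' of their tied ranks' reference values. With complete data all columns
#' end up with the identical value multiset; missing entries are skipped
#' during ranking, left missing, and columns with fewer observations are
#' mapped onto the reference distribution by linear interpolation of
#' quantiles.
#'
#' @param matrix an [intensity_matrix()] with at least one column; no
#'   column may be entirely missing.
#' @return the normalized [intensity_matrix()].
#' @export
quantile_normalize <- function(matrix) {
  v <- unclass(matrix)
  n <- nrow(v)
  k <- ncol(v)
  if (k < 1) pf_stop("pf_domain_error", "matrix has no columns")
  n_obs <- colSums(!is.na(v))
  if (any(n_obs == 0))
    pf_stop("pf_domain_error", "column %s is entirely missing",
            colnames(v)[which(n_obs == 0)[1]])
  if (n == 1) return(matrix)
  # Reference distribution on an n-point grid: mean across columns of each
  # column's sorted values, shorter columns interpolated onto the grid.
  grid <- seq(0, 1, length.out = n)
  ref <- rowMeans(vapply(seq_len(k), function(j) {
    s <- sort(v[, j])
    if (length(s) == n) s
    else if (length(s) == 1) rep(s, n)
    else approx(seq(0, 1, length.out = length(s)), s, xout = grid)$y
  }, numeric(n)))
  out <- v
  for (j in seq_len(k)) {
    idx <- which(!is.na(v[, j]))
    m <- length(idx)
    refm <- if (m == n) ref
    else if (m == 1) mean(ref)
    else approx(grid, ref, xout = (seq_len(m) - 1) / (m - 1))$y
    vals <- v[idx, j]
    # each tied group receives the mean of its tied ranks' reference values
    rmin <- rank(vals, ties.method = "min")
    rmax <- rank(vals, ties.method = "max")
    cs <- cumsum(refm)
    out[idx, j] <- (cs[rmax] - c(0, cs)[rmin]) / (rmax - rmin + 1)
  }
  intensity_matrix(out)
}
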