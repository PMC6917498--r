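#' Ridge-regularized partial correlation matrix
#'
#' Estimates between-component direct connectivity for one subject from the
#' component time series via Tikhonov (ridge) regularization: the demeaned
#' sample covariance `C` (denominator `T - 1`) is optionally rescaled by the
#' root-mean-square of its diagonal (so `rho = 1` has comparable strength
#' across subjects with different signal scales), the regularized precision
#' `P = (C + rho I)^-1` is formed, and partial correlations are read off as
#' `r_ij = -p_ij / sqrt(p_ii p_jj)` with the diagonal set to 0.
#'
#' @param ts Numeric `T x K` matrix of component time series (columns are
#'   components; column names, if present, label the output).
#' @param rho Non-negative regularization strength (default 1, the study's
#'   setting).
#' @param normalize_covariance Rescale the covariance by the RMS of its
#'   diagonal before ridging (default `TRUE`). Disable for comparisons against
#'   the unregularized closed form.
#' @return Symmetric `K x K` partial-correlation matrix with zero diagonal.
#' @export
#' @examples
#' x <- matrix(rnorm(600), 150, 4)
#' r <- ridge_partial_cor(x, rho = 1)
#' max(abs(r)) <= 1
ridge_partial_cor <- function(ts, rho = 1, normalize_covariance = TRUE) {
  ts <- as.matrix(ts)
  if (!is.numeric(ts) || any(!is.finite(ts))) abort("time series must be finite numeric")
  tt <- nrow(ts)
  k <- ncol(ts)
  if (tt < k + 2) abort("need T >= K + 2 timepoints for estimability")
  check_number(rho, "rho", lower = 0)
  sds <- apply(ts, 2, sd)
  if (any(sds == 0)) abort("constant component time series (zero variance column)")

  xc <- sweep(ts, 2, colMeans(ts))
  cc <- crossprod(xc) / (tt - 1)
  if (normalize_covariance) cc <- cc / sqrt(mean(diag(cc)^2))
  p <- solve(cc + rho * diag(k))
  d <- sqrt(diag(p))
  r <- -p / outer(d, d)
  r <- (r + t(r)) / 2
  diag(r) <- 0
  dimnames(r) <- list(colnames(ts), colnames(ts))
  r
}

#' Fisher's variance-stabilizing z transformation
#'
#' `z = arctanh(r)`; strictly increasing and odd. Values with `|r| >= 1` are
#' rejected rather than clipped.
#'
#' @param r Numeric vector of correlations with `|r| < 1`.
#' @return Numeric vector of z statistics.
#' @export
#' @examples
#' fisher_z(0.5) # 0.5 * log(3)
fisher_z <- function(r) {
  if (any(!is.finite(r)) || any(abs(r) >= 1)) {
    abort("fisher_z requires finite correlations with |r| < 1")
  }
  atanh(r)
}

#' Extract the lower-triangle edge vector of a connectivity matrix
#'
#' Flattens a symmetric `K x K` matrix into the canonical per-subject edge
#' vector: lower-triangle entries in column-major order, i.e. (2,1), (3,1),
#' ..., (K,1), (3,2), ... The ordering is identical for every subject, so edge
#' vectors are directly comparable across the cohort.
#'
#' @param mat Symmetric numeric matrix (asymmetry beyond 1e-10 is an error).
#' @param subject_id Identifier attached to each row.
#' @param labels Component labels; defaults to `colnames(mat)`.
#' @return Tibble with columns `subject_id`, `comp_i`, `comp_j`, `edge`,
#'   `value` and `K (K - 1) / 2` rows.
#' @seealso [rebuild_edge_matrix()] for the inverse operation.
#' @export
extract_edges <- function(mat, subject_id = "S001", labels = colnames(mat)) {
  mat <- as.matrix(mat)
  if (nrow(mat) != ncol(mat)) abort("`mat` must be square")
  if (max(abs(mat - t(mat))) > 1e-10) abort("`mat` is asymmetric beyond 1e-10")
  if (is.null(labels)) labels <- paste0("C", seq_len(ncol(mat)))
  idx <- edge_index(labels)
  tibble(
    subject_id = subject_id,
    comp_i = idx$comp_i, comp_j = idx$comp_j, edge = idx$edge,
    value = mat[cbind(idx$row, idx$col)]
  )
}

#' Rebuild a symmetric matrix from an extracted edge vector
#'
#' @param edges Tibble from [extract_edges()] (one subject).
#' @param labels Component labels in matrix order.
#' @return Symmetric matrix with zero diagonal.
#' @export
rebuild_edge_matrix <- function(edges, labels = unique(c(edges$comp_j, edges$comp_i))) {
  k <- length(labels)
  m <- matrix(0, k, k, dimnames = list(labels, labels))
  i <- match(edges$comp_i, labels)
  j <- match(edges$comp_j, labels)
  if (any(is.na(i)) || any(is.na(j))) abort("edge components not found in `labels`")
  m[cbind(i, j)] <- edges$value
  m[cbind(j, i)] <- edges$value
  m
}

#' Per-subject Fisher-z edge vectors for a whole cohort
#'
#' Runs [ridge_partial_cor()] on every subject's component time series,
#' applies [fisher_z()] (unless `fisher = FALSE`), and stacks the canonical
#' lower-triangle edge vectors into one long tibble.
#'
#' @param timeseries Named list of `T x K` matrices (e.g. `cohort$timeseries`)
#'   or a `geo_cohort`.
#' @param rho,normalize_covariance Passed to [ridge_partial_cor()].
#' @param fisher Apply Fisher's transformation (default `TRUE`).
#' @return Long tibble: `subject_id`, `comp_i`, `comp_j`, `edge`, `value`.
#' @export
#' @examples
#' cohort <- generate_cohort(cohort_config(
#'   group_sizes = c("TD" = 3, "LD/DD" = 2), seed = 1
#' ))
#' edges <- compute_edges(cohort)
#' dplyr::count(edges, edge)
compute_edges <- function(timeseries, rho = 1, normalize_covariance = TRUE,
                          fisher = TRUE) {
  if (inherits(timeseries, "geo_cohort")) timeseries <- timeseries$timeseries
  if (is.null(names(timeseries))) abort("`timeseries` must be a named list")
  purrr::imap_dfr(timeseries, function(ts, id) {
    r <- ridge_partial_cor(ts, rho = rho, normalize_covariance = normalize_covariance)
    e <- extract_edges(r, subject_id = id)
    if (fisher) e$value <- fisher_z(e$value)
    e
  })
}
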