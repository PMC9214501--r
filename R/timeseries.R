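#' Multivariate neural time series
#'
#' Container for a nodes-by-time recording sampled at a uniform interval.
#' This is the universal input of every estimator in the package: rows are
#' recording sites (neurons, regions, independent components) and columns are
#' consecutive samples spaced \code{dt} seconds apart.  Non-uniform sampling
#' is not representable and therefore rejected by construction.
#'
#' @param values numeric matrix, \code{n_nodes x n_time}; all entries finite.
#' @param dt sampling interval in seconds, \code{> 0}.
#' @param node_ids optional character vector of unique node labels; defaults
#'   to \code{"n1", "n2", ...}.
#' @return An object of class \code{ddc_ts}: a list with elements
#'   \code{values}, \code{dt} and \code{node_ids}.
#' @examples
#' ts <- ddc_timeseries(matrix(rnorm(30), 3, 10), dt = 0.01)
#' dim(ts$values)
#' @export
ddc_timeseries <- function(values, dt, node_ids = NULL) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix (nodes x time)")
  if (!all(is.finite(values)))
    stop("`values` contains non-finite entries")
  if (!is.numeric(dt) || length(dt) != 1L || !is.finite(dt) || dt <= 0)
    stop("`dt` must be a single positive number (seconds)")
  if (ncol(values) < 3L)
    stop("at least 3 time samples are required (the derivative needs interior points)")
  n <- nrow(values)
  if (is.null(node_ids)) node_ids <- paste0("n", seq_len(n))
  node_ids <- as.character(node_ids)
  if (length(node_ids) != n) stop("`node_ids` must have one label per row")
  if (anyDuplicated(node_ids)) stop("`node_ids` must be unique")
  dimnames(values) <- NULL
  structure(list(values = values, dt = dt, node_ids = node_ids),
            class = "ddc_ts")
}

#' @export
print.ddc_ts <- function(x, ...) {
  cat(sprintf("<ddc_ts> %d nodes x %d samples, dt = %g s (%.6g s total)\n",
              nrow(x$values), ncol(x$values), x$dt,
              (ncol(x$values) - 1L) * x$dt))
  invisible(x)
}

#' @export
dim.ddc_ts <- function(x) dim(x$values)

.assert_ts <- function(ts) {
  if (!inherits(ts, "ddc_ts")) stop("expected a `ddc_ts` object")
  ts
}

#' Z-score each node of a time series
#'
#' Centers and scales every node to mean zero and unit standard deviation,
#' using the population convention (divisor \code{n_time}).  On z-scored data
#' the sample covariance and correlation matrices coincide, which is the
#' convention all estimators in the package rely on.
#'
#' @param ts a \code{\link{ddc_timeseries}} object.
#' @return A \code{ddc_ts} of identical shape and \code{dt}.
#' @export
zscore <- function(ts) {
  .assert_ts(ts)
  x <- ts$values
  m <- rowMeans(x)
  s <- sqrt(rowMeans((x - m)^2))
  bad <- which(s == 0 | !is.finite(s))
  if (length(bad))
    stop("zero-variance node(s): ", paste(ts$node_ids[bad], collapse = ", "))
  ddc_timeseries((x - m) / s, dt = ts$dt, node_ids = ts$node_ids)
}

#' Numerical time derivative
#'
#' Differentiates each node with either the symmetric difference quotient
#' \code{(x[t+1] - x[t-1]) / (2 dt)} (default, evaluated at interior samples)
#' or the forward quotient \code{(x[t+1] - x[t]) / dt}.  Endpoint samples are
#' dropped rather than padded, so the returned series is shorter than the
#' input; use \code{\link{trim_to_derivative}} to obtain the state samples
#' aligned with the derivative estimates.
#'
#' @param ts a \code{\link{ddc_timeseries}}.
#' @param method \code{"central"} (symmetric quotient, n_time - 2 samples) or
#'   \code{"forward"} (n_time - 1 samples).
#' @return A \code{ddc_ts} holding the derivative series.
#' @seealso \code{\link{trim_to_derivative}}
#' @export
numerical_derivative <- function(ts, method = c("central", "forward")) {
  .assert_ts(ts)
  method <- match.arg(method)
  x <- ts$values
  Tn <- ncol(x)
  if (Tn < 3L) stop("at least 3 samples are required for differentiation")
  d <- switch(method,
    central = (x[, 3:Tn, drop = FALSE] - x[, 1:(Tn - 2L), drop = FALSE]) / (2 * ts$dt),
    forward = (x[, 2:Tn, drop = FALSE] - x[, 1:(Tn - 1L), drop = FALSE]) / ts$dt)
  ddc_timeseries(d, dt = ts$dt, node_ids = ts$node_ids)
}

#' State samples aligned with a numerical derivative
#'
#' Returns the input series restricted to the samples at which
#' \code{\link{numerical_derivative}} evaluates its estimate, so that
#' cross-products between derivative and state use aligned time indices:
#' the interior samples for the central quotient and the left sample of each
#' step for the forward quotient.
#'
#' @inheritParams numerical_derivative
#' @return A \code{ddc_ts} with the same number of samples as the
#'   corresponding derivative series.
#' @export
trim_to_derivative <- function(ts, method = c("central", "forward")) {
  .assert_ts(ts)
  method <- match.arg(method)
  Tn <- ncol(ts$values)
  idx <- switch(method, central = 2:(Tn - 1L), forward = 1:(Tn - 1L))
  ddc_timeseries(ts$values[, idx, drop = FALSE], dt = ts$dt,
                 node_ids = ts$node_ids)
}

#' Time-averaged outer product
#'
#' Computes \code{(1/T) * sum_t a_t b_t'}, the time average of the outer
#' product of two (aligned) multivariate series.  Applied to a z-scored
#' series with itself this is the sample correlation matrix; applied to a
#' derivative series and the state it is the differential covariance.
#'
#' @param a,b \code{\link{ddc_timeseries}} objects with equal sample counts
#'   and aligned time indices.
#' @return A numeric matrix of shape \code{(n_a, n_b)}.
#' @export
time_average_outer <- function(a, b) {
  .assert_ts(a); .assert_ts(b)
  if (ncol(a$values) != ncol(b$values))
    stop("series lengths differ (", ncol(a$values), " vs ", ncol(b$values),
         "); align them before averaging")
  tcrossprod(a$values, b$values) / ncol(a$values)
}

# Derivative/state pair used by the derivative-based estimators; accepts a
# single series or a list of contiguous segments (cross-products are then
# pooled across segments, never across gaps).
.deriv_state <- function(ts, method, scale = TRUE, deriv_ts = NULL) {
  segs <- if (inherits(ts, "ddc_ts")) list(ts) else ts
  if (!length(segs) || !all(vapply(segs, inherits, TRUE, "ddc_ts")))
    stop("expected a `ddc_ts` or a list of `ddc_ts` segments")
  if (scale) segs <- lapply(segs, zscore)
  if (!is.null(deriv_ts)) {
    if (length(segs) != 1L)
      stop("an explicit derivative series can only accompany a single segment")
    d <- deriv_ts$values
    x <- segs[[1L]]$values
    if (ncol(d) != ncol(x))
      stop("explicit derivative must be aligned sample-for-sample with the state")
    return(list(d = d, x = x, node_ids = segs[[1L]]$node_ids))
  }
  dmats <- lapply(segs, function(s) numerical_derivative(s, method)$values)
  xmats <- lapply(segs, function(s) trim_to_derivative(s, method)$values)
  list(d = do.call(cbind, dmats), x = do.call(cbind, xmats),
       node_ids = segs[[1L]]$node_ids)
}
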