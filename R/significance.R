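#' Autoregressive bootstrap significance of estimated connections
#'
#' Surrogate-data test of the null hypothesis that the nodes are mutually
#' independent while each keeps its own temporal autocorrelation (and hence
#' power spectrum).  Per node, an AR(q) model is fitted by conditional
#' least squares, the order chosen by a forward BIC search that accepts a
#' higher order only while it lowers BIC by more than \code{bic_delta}.
#' Each surrogate dataset redraws every node independently from its own AR
#' model with resampled Gaussian innovations; the chosen estimator is run
#' on each surrogate, a Gaussian is fitted to the null values of every
#' edge, and the two-sided tail probability of the observed value is
#' reported.  Diagonal entries are set to 1.
#'
#' @param ts a \code{\link{ddc_timeseries}}.
#' @param estimator function mapping a \code{ddc_ts} to a square matrix or
#'   \code{\link{ddc_estimate}} (e.g. \code{ddc_linear}), or an estimator
#'   name from \code{"Cov"}, \code{"P"}, \code{"Dc"}, \code{"Dp"},
#'   \code{"DDC_L"}.
#' @param n_surrogates number of surrogate datasets (values below 50 give
#'   unstable Gaussian fits and trigger a warning).
#' @param seed optional RNG seed.
#' @param max_order largest AR order examined.
#' @param bic_delta BIC improvement required to accept a higher order.
#' @return An object of class \code{ddc_significance}: list with
#'   \code{p_values} (diagonal 1), \code{observed}, \code{null_mean},
#'   \code{null_sd}, \code{ar_orders}, \code{n_surrogates}.
#' @seealso \code{\link{binarize_by_significance}}
#' @export
ar_bootstrap_significance <- function(ts, estimator = ddc_linear,
                                      n_surrogates = 1000, seed = NULL,
                                      max_order = 10L, bic_delta = 2) {
  .assert_ts(ts)
  if (n_surrogates < 50L)
    warning("fewer than 50 surrogates: the Gaussian null fit will be unstable")
  if (!is.null(seed)) set.seed(seed)
  fn <- .resolve_estimator(estimator)
  n <- nrow(ts$values)
  Tn <- ncol(ts$values)
  fits <- lapply(seq_len(n), function(i)
    tryCatch(.fit_ar_bic(ts$values[i, ], max_order, bic_delta),
             error = function(e) stop("AR fit failed for node ",
                                      ts$node_ids[i], ": ",
                                      conditionMessage(e))))
  obs <- .mat_of(fn(ts))
  null_sum <- matrix(0, n, n)
  null_sq <- matrix(0, n, n)
  for (s in seq_len(n_surrogates)) {
    surro <- vapply(fits, function(f) .simulate_ar(f, Tn), numeric(Tn))
    est <- .mat_of(fn(ddc_timeseries(t(surro), dt = ts$dt,
                                     node_ids = ts$node_ids)))
    null_sum <- null_sum + est
    null_sq <- null_sq + est^2
  }
  mu <- null_sum / n_surrogates
  sd0 <- sqrt(pmax(null_sq / n_surrogates - mu^2, 0) *
                n_surrogates / (n_surrogates - 1))
  z <- (obs - mu) / sd0
  p <- 2 * stats::pnorm(-abs(z))
  p[sd0 == 0] <- 1
  diag(p) <- 1
  structure(list(p_values = p, observed = obs, null_mean = mu, null_sd = sd0,
                 ar_orders = vapply(fits, `[[`, 0L, "order"),
                 n_surrogates = n_surrogates, node_ids = ts$node_ids),
            class = "ddc_significance")
}

#' @export
print.ddc_significance <- function(x, ...) {
  cat(sprintf("<ddc_significance> %d nodes, %d surrogates; AR orders %s\n",
              nrow(x$p_values), x$n_surrogates,
              paste(range(x$ar_orders), collapse = "-")))
  invisible(x)
}

#' Binarize a significance result
#'
#' @param res a \code{\link{ar_bootstrap_significance}} result.
#' @param alpha significance level in \code{(0, 1)}.
#' @return 0/1 matrix with entry 1 where \code{p < alpha}; diagonal 0.
#'   Edge sets are nested across increasing \code{alpha}.
#' @export
binarize_by_significance <- function(res, alpha) {
  stopifnot(inherits(res, "ddc_significance"))
  if (alpha <= 0 || alpha >= 1) stop("`alpha` must be in (0, 1)")
  b <- (res$p_values < alpha) * 1
  diag(b) <- 0
  b
}

.resolve_estimator <- function(estimator) {
  if (is.function(estimator)) return(estimator)
  name <- match.arg(estimator, c("Cov", "P", "Dc", "Dp", "DDC_L",
                                 "DDC_ReLU", "L1reg", "L2reg"))
  switch(name,
         Cov = cov_estimator,
         P = precision_estimator,
         Dc = delta_c,
         Dp = delta_p,
         DDC_L = ddc_linear,
         DDC_ReLU = function(ts) ddc_nonlinear(ts, response_relu(0)),
         L1reg = function(ts) regularized_precision(ts, "L1", 0.1),
         L2reg = function(ts) regularized_precision(ts, "L2", 0.1))
}

# Forward BIC search over AR orders fitted by conditional least squares.
# Order 0 is the white-noise model.  BIC = n log(RSS/n) + (q+1) log(n) on
# the common conditioning sample.
.fit_ar_bic <- function(x, max_order, bic_delta) {
  Tn <- length(x)
  max_order <- min(max_order, Tn %/% 4L)
  mu <- mean(x)
  xc <- x - mu
  neff <- Tn - max_order
  y <- xc[(max_order + 1L):Tn]
  bic0 <- neff * log(sum(y^2) / neff) + log(neff)
  best <- list(order = 0L, coef = numeric(0), sd = sqrt(sum(y^2) / neff),
               mean = mu, bic = bic0)
  prev_bic <- bic0
  for (q in seq_len(max_order)) {
    X <- sapply(seq_len(q), function(l) xc[(max_order + 1L - l):(Tn - l)])
    X <- matrix(X, ncol = q)
    fit <- stats::lm.fit(X, y)
    rss <- sum(fit$residuals^2)
    bic <- neff * log(rss / neff) + (q + 1) * log(neff)
    if (bic < prev_bic - bic_delta) {
      best <- list(order = q, coef = unname(fit$coefficients),
                   sd = sqrt(rss / (neff - q)), mean = mu, bic = bic)
      prev_bic <- bic
    } else break
  }
  if (any(!is.finite(c(best$coef, best$sd))))
    stop("non-finite AR coefficients (degenerate series?)")
  best
}

# Simulate one surrogate of length Tn from a fitted AR model with fresh
# Gaussian innovations; a burn-in discards the influence of zero initials.
.simulate_ar <- function(fit, Tn) {
  burn <- 10L * max(1L, fit$order)
  innov <- stats::rnorm(Tn + burn, 0, fit$sd)
  x <- if (fit$order == 0L) innov
       else as.numeric(stats::filter(innov, fit$coef, method = "recursive"))
  if (any(!is.finite(x)))
    stop("AR surrogate diverged (non-stationary fitted coefficients)")
  fit$mean + x[(burn + 1L):(burn + Tn)]
}
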