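#' Connectivity estimate container
#'
#' Square matrix in which entry \code{(i, j)} encodes the estimated influence
#' of node \code{j} on node \code{i} (row = target, column = source), plus
#' the identity of the estimator that produced it and its parameters.
#'
#' @param matrix square numeric matrix.
#' @param estimator estimator name, one of \code{"Cov"}, \code{"P"},
#'   \code{"L1reg"}, \code{"L2reg"}, \code{"Dc"}, \code{"Dp"}, \code{"DDC_L"},
#'   \code{"DDC_R"}, \code{"DDC_ReLU"}, \code{"DDC_D"}, \code{"Cspk"}.
#' @param params named list of estimator parameters.
#' @param node_ids node labels.
#' @return An object of class \code{ddc_estimate}.
#' @export
new_ddc_estimate <- function(matrix, estimator, params = list(), node_ids = NULL) {
  if (!is.matrix(matrix) || nrow(matrix) != ncol(matrix))
    stop("estimate must be a square matrix")
  if (is.null(node_ids)) node_ids <- paste0("n", seq_len(nrow(matrix)))
  dimnames(matrix) <- NULL
  structure(list(matrix = matrix, estimator = as.character(estimator),
                 params = params, node_ids = as.character(node_ids)),
            class = "ddc_estimate")
}

#' @rdname new_ddc_estimate
#' @export
ddc_estimate <- new_ddc_estimate

#' @export
print.ddc_estimate <- function(x, ...) {
  cat(sprintf("<ddc_estimate> %s, %d x %d\n", x$estimator,
              nrow(x$matrix), ncol(x$matrix)))
  if (length(x$params))
    cat("  params:", paste(names(x$params), unlist(x$params), sep = "=",
                           collapse = ", "), "\n")
  invisible(x)
}

#' @export
as.matrix.ddc_estimate <- function(x, ...) {
  m <- x$matrix
  dimnames(m) <- list(x$node_ids, x$node_ids)
  m
}

.estimator_names <- c("Cov", "P", "L1reg", "L2reg", "Dc", "Dp",
                      "DDC_L", "DDC_R", "DDC_ReLU", "DDC_D", "Cspk")

#' Response functions for nonlinear DDC
#'
#' Elementwise, monotone nondecreasing transforms applied to the (z-scored)
#' state before the cross-product in \code{\link{ddc_nonlinear}}.  The
#' rectifier is parameterized as \code{max(x, theta)}, so a threshold below
#' the data minimum leaves the signal untouched and the estimator degrades
#' gracefully to the linear one; the centered sigmoid is
#' \code{1/(1 + exp(-alpha x)) - 1/2}.
#'
#' @param kind \code{"identity"}, \code{"relu"}, \code{"sigmoid"} or
#'   \code{"custom"}.
#' @param theta rectifier threshold (in z-score units).
#' @param alpha sigmoid slope.
#' @param fn for \code{kind = "custom"}, a vectorized monotone function.
#' @return An object of class \code{ddc_response}.
#' @export
response_function <- function(kind = c("identity", "relu", "sigmoid", "custom"),
                              theta = 0, alpha = 1, fn = NULL) {
  kind <- match.arg(kind)
  if (kind == "custom" && !is.function(fn))
    stop("`fn` must be supplied for a custom response function")
  structure(list(kind = kind, theta = theta, alpha = alpha, fn = fn),
            class = "ddc_response")
}

#' @rdname response_function
#' @export
response_identity <- function() response_function("identity")

#' @rdname response_function
#' @export
response_relu <- function(theta = 0) response_function("relu", theta = theta)

#' @rdname response_function
#' @export
response_sigmoid <- function(alpha = 1) response_function("sigmoid", alpha = alpha)

#' Apply a response function elementwise
#' @param R a \code{\link{response_function}}.
#' @param x numeric matrix or vector.
#' @export
apply_response <- function(R, x) {
  stopifnot(inherits(R, "ddc_response"))
  switch(R$kind,
         identity = x,
         relu = pmax(x, R$theta),
         sigmoid = 1 / (1 + exp(-R$alpha * x)) - 0.5,
         custom = R$fn(x))
}

# Guarded inverse.  Direct solve by default; the Moore-Penrose pseudoinverse
# is opt-in and never silent because the inverse of a rank-deficient matrix
# is not unique.
.safe_inverse <- function(M, pseudoinverse = FALSE, cond_cap = 1e12,
                          what = "matrix") {
  rc <- tryCatch(rcond(M), error = function(e) 0)
  if (!pseudoinverse && (!is.finite(rc) || rc < 1 / cond_cap))
    stop(what, " is (near) singular (reciprocal condition ", format(rc),
         "); set `pseudoinverse = TRUE` to use the Moore-Penrose ",
         "least-squares inverse")
  if (pseudoinverse && (!is.finite(rc) || rc < 1 / cond_cap))
    MASS::ginv(M)
  else
    solve(M)
}

#' Sample covariance estimator
#'
#' \code{Cov = <x, x>} on z-scored traces, i.e. the sample correlation
#' matrix.  Symmetric; cannot carry directional information, and a common
#' driver induces large spurious entries between unconnected targets.
#'
#' @param ts a \code{\link{ddc_timeseries}}.
#' @param scale z-score internally (default, and assumed by the diagonal
#'   contract).
#' @return A \code{\link{ddc_estimate}} with estimator \code{"Cov"}.
#' @export
cov_estimator <- function(ts, scale = TRUE) {
  .assert_ts(ts)
  z <- if (scale) zscore(ts) else ts
  C <- time_average_outer(z, z)
  C <- (C + t(C)) / 2
  new_ddc_estimate(C, "Cov", list(scale = scale), ts$node_ids)
}

#' Precision (partial covariance) estimator
#'
#' \code{P = Cov^-1}.  Off-diagonal zeros indicate conditional independence
#' given all remaining nodes, which explains away common-driver artifacts,
#' but the matrix remains symmetric and therefore undirected.
#'
#' @inheritParams cov_estimator
#' @param pseudoinverse use the Moore-Penrose pseudoinverse when the
#'   covariance is rank deficient (opt-in; see Details in
#'   \code{\link{ddc_linear}}).
#' @param cond_cap maximum tolerated condition number for a direct solve.
#' @return A \code{\link{ddc_estimate}} with estimator \code{"P"}.
#' @export
precision_estimator <- function(ts, scale = TRUE, pseudoinverse = FALSE,
                                cond_cap = 1e12) {
  C <- cov_estimator(ts, scale = scale)$matrix
  P <- .safe_inverse(C, pseudoinverse, cond_cap, "covariance matrix")
  P <- (P + t(P)) / 2
  new_ddc_estimate(P, "P", list(scale = scale, pseudoinverse = pseudoinverse),
                   ts$node_ids)
}

#' Differential covariance
#'
#' \code{Dc = <dx/dt, x>}: the time-averaged outer product of the numerical
#' derivative with the state, evaluated on aligned samples.  The derivative
#' defaults to the symmetric difference quotient.
#'
#' @inheritParams cov_estimator
#' @param deriv derivative scheme, \code{"central"} or \code{"forward"}.
#' @param deriv_ts optional explicit derivative series (e.g. the analytic
#'   right-hand side of a known model), aligned sample-for-sample with
#'   \code{ts}; overrides numerical differentiation.
#' @return A \code{\link{ddc_estimate}} with estimator \code{"Dc"}.
#' @export
delta_c <- function(ts, deriv = c("central", "forward"), scale = TRUE,
                    deriv_ts = NULL) {
  deriv <- match.arg(deriv)
  ds <- .deriv_state(ts, deriv, scale = scale, deriv_ts = deriv_ts)
  M <- tcrossprod(ds$d, ds$x) / ncol(ds$x)
  new_ddc_estimate(M, "Dc", list(deriv = deriv, scale = scale), ds$node_ids)
}

#' Partial differential covariance
#'
#' Elementwise for \code{i != j}:
#' \code{Dp[i,j] = Dc[i,j] - Cov[j,K] Cov[K,K]^-1 Dc[i,K]'} with \code{K}
#' the set of all nodes other than \code{i} and \code{j}; the diagonal is
#' copied from \code{Dc} (the elementwise definition leaves it open).
#'
#' @inheritParams delta_c
#' @return A \code{\link{ddc_estimate}} with estimator \code{"Dp"}.
#' @export
delta_p <- function(ts, deriv = c("central", "forward"), scale = TRUE,
                    deriv_ts = NULL) {
  deriv <- match.arg(deriv)
  dc <- delta_c(ts, deriv, scale = scale, deriv_ts = deriv_ts)$matrix
  C <- cov_estimator(ts, scale = scale)$matrix
  n <- nrow(C)
  out <- dc
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    K <- setdiff(seq_len(n), c(i, j))
    if (!length(K)) next            # 2-node system: Dp reduces to Dc
    CKK <- C[K, K, drop = FALSE]
    rc <- tryCatch(rcond(CKK), error = function(e) 0)
    if (!is.finite(rc) || rc < 1e-12)
      stop("conditioning covariance Cov[K,K] is singular for pair (",
           i, ",", j, ")")
    out[i, j] <- dc[i, j] -
      C[j, K, drop = FALSE] %*% solve(CKK, t(dc[i, K, drop = FALSE]))
  }
  new_ddc_estimate(out, "Dp", list(deriv = deriv, scale = scale),
                   if (inherits(ts, "ddc_ts")) ts$node_ids else ts[[1]]$node_ids)
}

#' Linear dynamical differential covariance
#'
#' \code{DDC_L = <dx/dt, x> <x, x>^-1}, the least-squares estimate of the
#' coupling matrix \code{W} of the assumed linear system \code{dx/dt = W x}:
#' it solves the normal equations of regressing each node's derivative on
#' all state nodes.  The derivative defaults to the forward difference
#' quotient, which pairs each Brownian increment with the state *before*
#' it so the noise term averages out (the Ito convention); the symmetric
#' quotient is available but on stochastic data it symmetrizes the
#' cross-covariance and degrades directed recovery (see the methods
#' vignette).
#'
#' @inheritParams delta_c
#' @param pseudoinverse opt-in Moore-Penrose inverse for rank-deficient
#'   state covariance.
#' @param cond_cap condition-number cap for the direct solve.
#' @return A \code{\link{ddc_estimate}} with estimator \code{"DDC_L"};
#'   entry \code{(i, j)} estimates the coupling j -> i.
#' @examples
#' g <- motif_graph("confounder")
#' ts <- simulate_linear(g, sigma = 1, duration = 50, seed = 1)
#' round(ddc_linear(ts)$matrix, 2)
#' @export
ddc_linear <- function(ts, deriv = c("forward", "central"), scale = TRUE,
                       deriv_ts = NULL, pseudoinverse = FALSE,
                       cond_cap = 1e12) {
  deriv <- match.arg(deriv)
  ds <- .deriv_state(ts, deriv, scale = scale, deriv_ts = deriv_ts)
  Tm <- ncol(ds$x)
  xc <- ds$x - rowMeans(ds$x)       # trimming can leave a residual mean
  dC <- tcrossprod(ds$d, xc) / Tm
  C <- tcrossprod(xc) / Tm
  W <- dC %*% .safe_inverse(C, pseudoinverse, cond_cap, "state covariance <x,x>")
  new_ddc_estimate(W, "DDC_L",
                   list(deriv = deriv, scale = scale,
                        pseudoinverse = pseudoinverse), ds$node_ids)
}

#' Nonlinear dynamical differential covariance
#'
#' \code{DDC_R = <dx/dt, x> <R(x), x>^-1} for an elementwise response
#' function \code{R}, the least-squares estimate of \code{W} under
#' \code{dx/dt = W R(x)}.  \code{R} is applied to the z-scored state and
#' \code{R(x)} is mean-centered over time before the outer product, so
#' constant offsets of the response (e.g. from a \code{max(x, theta)}
#' rectifier) do not leak into the cross-covariance.
#'
#' @inheritParams ddc_linear
#' @param R a \code{\link{response_function}}.
#' @return A \code{\link{ddc_estimate}} with estimator \code{"DDC_R"} (or
#'   \code{"DDC_ReLU"} for a rectifier response).
#' @export
ddc_nonlinear <- function(ts, R = response_relu(0),
                          deriv = c("forward", "central"), scale = TRUE,
                          deriv_ts = NULL, pseudoinverse = FALSE,
                          cond_cap = 1e12) {
  deriv <- match.arg(deriv)
  stopifnot(inherits(R, "ddc_response"))
  ds <- .deriv_state(ts, deriv, scale = scale, deriv_ts = deriv_ts)
  Tm <- ncol(ds$x)
  xc <- ds$x - rowMeans(ds$x)
  rx <- apply_response(R, ds$x)
  rx <- rx - rowMeans(rx)
  dC <- tcrossprod(ds$d, xc) / Tm
  CR <- tcrossprod(rx, xc) / Tm
  inv <- tryCatch(
    .safe_inverse(CR, pseudoinverse, cond_cap, "response cross-covariance <R(x),x>"),
    error = function(e) stop(conditionMessage(e),
      " (a heavily rectified response can make <R(x),x> rank deficient)",
      call. = FALSE))
  W <- dC %*% inv
  name <- if (R$kind == "relu") "DDC_ReLU" else "DDC_R"
  new_ddc_estimate(W, name,
                   list(deriv = deriv, scale = scale, response = R$kind,
                        theta = R$theta, alpha = R$alpha,
                        pseudoinverse = pseudoinverse), ds$node_ids)
}

#' Leaky (temporally filtered) nonlinear DDC
#'
#' For systems with an explicit decay term,
#' \code{tau dx/dt = -x + W R(x)}, the estimator
#' \code{DDC_D = (tau <dx/dt, x> + <x, x>) <R(x), x>^-1} removes the leak
#' contribution and estimates \code{W} directly.  With \code{tau -> 0} and
#' an identity response it tends to the identity matrix.
#'
#' @inheritParams ddc_nonlinear
#' @param tau membrane/decay time constant in seconds, \code{> 0}.
#' @return A \code{\link{ddc_estimate}} with estimator \code{"DDC_D"}.
#' @export
ddc_leaky <- function(ts, R = response_identity(), tau,
                      deriv = c("forward", "central"), scale = TRUE,
                      deriv_ts = NULL, pseudoinverse = FALSE,
                      cond_cap = 1e12) {
  deriv <- match.arg(deriv)
  if (!is.numeric(tau) || length(tau) != 1L || tau <= 0)
    stop("`tau` must be a single positive time constant (seconds)")
  stopifnot(inherits(R, "ddc_response"))
  ds <- .deriv_state(ts, deriv, scale = scale, deriv_ts = deriv_ts)
  Tm <- ncol(ds$x)
  xc <- ds$x - rowMeans(ds$x)
  rx <- apply_response(R, ds$x)
  rx <- rx - rowMeans(rx)
  dC <- tcrossprod(ds$d, xc) / Tm
  C <- tcrossprod(xc) / Tm
  CR <- tcrossprod(rx, xc) / Tm
  W <- (tau * dC + C) %*%
    .safe_inverse(CR, pseudoinverse, cond_cap, "response cross-covariance <R(x),x>")
  new_ddc_estimate(W, "DDC_D",
                   list(deriv = deriv, scale = scale, response = R$kind,
                        theta = R$theta, alpha = R$alpha, tau = tau),
                   ds$node_ids)
}

#' Rectifier threshold scan for DDC_ReLU
#'
#' Validation-time selection of the rectifier threshold: \code{DDC_ReLU} is
#' evaluated on a grid of thresholds placed at evenly spaced percentiles
#' (default 5th to 95th in 19 steps) of the pooled z-scored data, and the
#' threshold minimizing the normalized estimation error or maximizing the
#' ROC AUC against the known ground truth is returned.  Ties break toward
#' the smaller threshold (closer to the linear estimator).
#'
#' @inheritParams ddc_linear
#' @param truth a \code{\link{ddc_network}} ground-truth graph.
#' @param criterion \code{"error"} (normalized error after matrix
#'   normalization, lower triangle excluded diagonal) or \code{"auc"}.
#' @param probs percentile grid for candidate thresholds.
#' @return A list with \code{theta} (the selected threshold),
#'   \code{estimate} (the \code{ddc_estimate} at that threshold),
#'   \code{grid} and \code{score} vectors.
#' @export
relu_threshold_scan <- function(ts, truth, criterion = c("error", "auc"),
                                probs = seq(0.05, 0.95, length.out = 19),
                                deriv = c("forward", "central"),
                                scale = TRUE, pseudoinverse = FALSE) {
  criterion <- match.arg(criterion)
  deriv <- match.arg(deriv)
  if (is.null(truth))
    stop("criterion `", criterion, "` requires the ground-truth graph")
  stopifnot(inherits(truth, "ddc_network"))
  z <- if (scale) zscore(ts) else ts
  grid <- unname(stats::quantile(z$values, probs = probs))
  score <- numeric(length(grid))
  ests <- vector("list", length(grid))
  for (k in seq_along(grid)) {
    est <- ddc_nonlinear(z, response_relu(grid[k]), deriv = deriv,
                         scale = FALSE, pseudoinverse = pseudoinverse)
    ests[[k]] <- est
    score[k] <- if (criterion == "error") {
      error_bias_variance(list(est$matrix), truth$W)$error
    } else {
      roc_auc(est$matrix, truth$W != 0 & row(truth$W) != col(truth$W))$auc
    }
  }
  best <- if (criterion == "error") which(score == min(score))[1]
          else which(score == max(score))[1]
  list(theta = grid[best], estimate = ests[[best]], grid = grid,
       score = score, criterion = criterion)
}

#' Spike-train cross-correlogram connectivity
#'
#' Bins the spike trains at \code{dt}, mean-centers each binned train, and
#' integrates the cross-correlogram \code{g_ij(t)} over the window
#' \code{[-tau_window, 0]}:
#' \code{Cspk(i, j) = (1/tau_window) * integral of g_ij}, evaluated as a
#' Riemann sum on the \code{dt} grid.  Entry \code{(i, j)} is the influence
#' of j's past spiking on i.  Pairs in which either neuron fires below
#' \code{min_rate} are set to zero (their correlograms are too sparse to be
#' meaningful).
#'
#' @param spikes a \code{\link{ddc_spiketrains}}.
#' @param dt correlogram bin width in seconds (default 0.5 ms).
#' @param tau_window integration window in seconds (default 0.1 s).
#' @param min_rate minimum firing rate in Hz below which a neuron's pairs
#'   are zeroed.
#' @return A \code{\link{ddc_estimate}} with estimator \code{"Cspk"}.
#' @export
cspk <- function(spikes, dt = 5e-4, tau_window = 0.1, min_rate = 0.1) {
  stopifnot(inherits(spikes, "ddc_spikes"))
  if (tau_window <= 0) stop("`tau_window` must be positive")
  X <- bin_spikes(spikes, dt)
  n <- nrow(X); Tn <- ncol(X)
  L <- round(tau_window / dt)
  Xc <- X - rowMeans(X)
  # FFT cross-correlation over all pairs; zero-padding by > L avoids wrap-around
  np <- stats::nextn(Tn + L + 1L)
  Fx <- stats::mvfft(rbind(t(Xc), matrix(0, np - Tn, n)))
  M <- matrix(0, n, n)
  for (i in seq_len(n)) {
    cc <- Re(stats::mvfft(Fx * Conj(Fx[, i]), inverse = TRUE)) / np
    # cc[l+1, j] = sum_t x_j(t+l) x_i(t) = g_ji(-l dt) / dt: j's present against
    # i's past, i.e. the negative-lag branch that captures i -> j influence
    M[, i] <- colSums(cc[seq_len(L + 1L), , drop = FALSE]) * dt * dt / tau_window
  }
  rates <- firing_rates(spikes)
  low <- rates < min_rate
  M[low, ] <- 0
  M[, low] <- 0
  new_ddc_estimate(M, "Cspk",
                   list(dt = dt, tau_window = tau_window, min_rate = min_rate),
                   names(spikes$spike_times))
}
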