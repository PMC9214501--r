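.as_W <- function(g) {
  if (inherits(g, "ddc_network")) g$W
  else if (is.matrix(g)) g
  else stop("expected a `ddc_network` or a square matrix")
}

.as_graph <- function(g) {
  if (inherits(g, "ddc_network")) g else ddc_network(g)
}

.check_stable <- function(W) {
  ev <- max(Re(eigen(W, only.values = TRUE)$values))
  if (ev >= 0)
    warning("spectral abscissa of W is ", format(ev),
            " >= 0; the trajectory may not reach a stationary regime")
  invisible(ev)
}

#' Simulate a linear stochastic network
#'
#' Euler-Maruyama integration of \code{dx = W x dt + sigma D dbeta}: at
#' each step the state advances by \code{dt * W x} plus a Gaussian
#' increment \code{sqrt(dt) * sigma * D xi}, so the long-run covariance of
#' the trajectory solves the Lyapunov equation
#' \code{W P + P W' + sigma^2 D D' = 0}
#' (see \code{\link{lyapunov_steady_cov}}).  Observational noise of
#' standard deviation \code{sigma_obs} is added after integration.
#'
#' @param graph a \code{\link{ddc_network}} (or bare coupling matrix) whose
#'   \code{W} drives the dynamics; entry \code{(i, j)} couples j -> i.
#' @param sigma drive-noise standard deviation (diffusion amplitude).
#' @param sigma_obs observational-noise standard deviation.
#' @param D noise-structure matrix (default identity).
#' @param dt integration step in seconds.
#' @param duration simulated time in seconds.
#' @param seed optional RNG seed; the same seed reproduces the trajectory
#'   bit for bit.
#' @param x0 initial state (default zero).
#' @param keep_drive also record the per-step noise increments
#'   \code{dbeta/dt}; they are returned in the \code{"drive"} attribute as
#'   a \code{ddc_ts} aligned with the left sample of each step.
#' @return A \code{\link{ddc_timeseries}} with the ground-truth graph in
#'   the \code{"truth"} attribute.
#' @export
simulate_linear <- function(graph, sigma = 1, sigma_obs = 0, D = NULL,
                            dt = 0.01, duration = 1000, seed = NULL,
                            x0 = NULL, keep_drive = FALSE) {
  W <- .as_W(graph)
  n <- nrow(W)
  .check_stable(W)
  if (is.null(D)) D <- diag(n)
  if (is.null(x0)) x0 <- numeric(n)
  if (!is.null(seed)) set.seed(seed)
  n_steps <- round(duration / dt)
  res <- sim_linear_cpp(W, D, D, -1L, sigma, sigma_obs, dt, n_steps,
                        x0, keep_drive)
  ts <- ddc_timeseries(res$x, dt = dt)
  attr(ts, "truth") <- .as_graph(graph)
  if (keep_drive)
    attr(ts, "drive") <- ddc_timeseries(res$drive, dt = dt)
  ts
}

#' Simulate a two-state nonstationary linear network
#'
#' Identical coupling \code{W} throughout, but the noise structure switches
#' from \code{D1} to \code{D2} at \code{switch_time}; the second-order
#' statistics of the trajectory therefore change mid-recording while the
#' connectivity does not.  The default \code{D2} mixes noise across nodes
#' in a cyclic pattern.
#'
#' @inheritParams simulate_linear
#' @param switch_time time of the noise-structure switch in seconds.
#' @param D1,D2 noise-structure matrices before/after the switch.
#' @return A \code{\link{ddc_timeseries}} with \code{"truth"}, and the
#'   switch parameters in the \code{"states"} attribute.
#' @export
simulate_two_state <- function(graph = motif_graph("confounder"), sigma = 1,
                               dt = 0.01, duration = 1000, switch_time = 500,
                               D1 = NULL, D2 = NULL, seed = NULL, x0 = NULL) {
  if (switch_time >= duration) stop("`switch_time` must be before `duration`")
  W <- .as_W(graph)
  n <- nrow(W)
  .check_stable(W)
  if (is.null(D1)) D1 <- diag(n)
  if (is.null(D2)) {
    if (n != 3L) stop("supply `D2` explicitly for non-3-node graphs")
    D2 <- matrix(c(1, 0, 1,
                   1, 1, 0,
                   0, 1, 1), 3, 3, byrow = TRUE)
  }
  if (is.null(x0)) x0 <- numeric(n)
  if (!is.null(seed)) set.seed(seed)
  n_steps <- round(duration / dt)
  res <- sim_linear_cpp(W, D1, D2, as.integer(round(switch_time / dt)),
                        sigma, 0, dt, n_steps, x0, FALSE)
  ts <- ddc_timeseries(res$x, dt = dt)
  attr(ts, "truth") <- .as_graph(graph)
  attr(ts, "states") <- list(D1 = D1, D2 = D2, switch_time = switch_time)
  ts
}

#' Simulate a sigmoid-coupled nonlinear network
#'
#' Euler-Maruyama integration of \code{dx = W R(x) dt + sigma dbeta} with
#' the centered sigmoid \code{R(x) = 1/(1 + exp(-alpha x)) - 1/2} (odd, so
#' inhibitory coupling stays balanced around zero; \code{alpha} sets the
#' nonlinearity, with slope \code{alpha/4} at the origin).  Integrated at a
#' fine step and downsampled to \code{output_rate} before being returned;
#' estimation then operates on the downsampled signal.
#'
#' @inheritParams simulate_linear
#' @param alpha sigmoid slope.
#' @param output_rate output sampling rate in Hz.
#' @return A \code{\link{ddc_timeseries}} sampled at \code{output_rate},
#'   with \code{"truth"} attribute.
#' @export
simulate_sigmoid <- function(graph, alpha = 1, sigma = 1, dt = 1e-4,
                             duration = 1000, output_rate = 100,
                             seed = NULL, x0 = NULL) {
  if (alpha <= 0) stop("`alpha` must be positive")
  W <- .as_W(graph)
  n <- nrow(W)
  if (is.null(x0)) x0 <- numeric(n)
  if (!is.null(seed)) set.seed(seed)
  thin <- max(1L, as.integer(round(1 / (output_rate * dt))))
  n_steps <- round(duration / dt)
  x <- sim_sigmoid_cpp(W, alpha, sigma, dt, n_steps, thin, x0)
  ts <- ddc_timeseries(x, dt = dt * thin)
  attr(ts, "truth") <- .as_graph(graph)
  ts
}

#' Simulate the Rossler chaotic system
#'
#' Deterministic fixed-step Euler integration of the three-variable Rossler
#' equations \code{dx1 = -x2 - x3}, \code{dx2 = x1 + a x2},
#' \code{dx3 = b + x3 (x1 - c)} at the classical chaotic parameter set.
#' The initial transient is discarded.
#'
#' @param a,b,c Rossler parameters (defaults 0.2, 0.2, 5.7).
#' @param dt integration step in seconds.
#' @param duration total integrated time in seconds.
#' @param transient_discard leading transient to drop, in seconds.
#' @param x0 initial state.
#' @return A \code{\link{ddc_timeseries}} of the retained trajectory.
#' @export
simulate_rossler <- function(a = 0.2, b = 0.2, c = 5.7, dt = 0.01,
                             duration = 1000, transient_discard = 100,
                             x0 = c(0.1, 0.1, 0.1)) {
  if (duration <= transient_discard)
    stop("`duration` must exceed `transient_discard`")
  times <- seq(0, duration, by = dt)
  rhs <- function(t, y, p)
    list(c(-y[2] - y[3], y[1] + a * y[2], b + y[3] * (y[1] - c)))
  sol <- deSolve::ode(y = x0, times = times, func = rhs, parms = NULL,
                      method = "euler")
  x <- t(sol[, -1, drop = FALSE])
  keep <- times >= transient_discard
  ddc_timeseries(x[, keep, drop = FALSE], dt = dt,
                 node_ids = c("x1", "x2", "x3"))
}

#' Simulate a sparse leaky integrate-and-fire network
#'
#' Euler integration of \code{tau_m dV/dt = -V + W r + I_bias} with
#' double-exponential synapses (\code{dr/dt = -r/tau_d + h},
#' \code{dh/dt = -h/tau_r + (1/(tau_d tau_r)) sum delta(t - t_k)}; each
#' spike therefore injects a unit-integral synaptic waveform).  When
#' \code{V} reaches \code{v_thres} the neuron emits a spike and resets to
#' \code{v_reset}.  The reported voltage is the subthreshold trace after
#' reset bookkeeping, downsampled to \code{output_rate}; spike times are
#' returned separately and are consistent with the resets at integration
#' resolution.
#'
#' The numeric defaults (20 ms membrane, 10 ms / 1 ms synapse decay/rise,
#' unit threshold) are package defaults chosen for a sparse, asynchronous
#' firing regime of a few Hz in an inhibitory network; \code{i_bias} is the
#' suprathreshold drive balancing the recurrent inhibition and accepts a
#' per-neuron vector.
#'
#' @param graph a \code{\link{ddc_network}} of synaptic weights (typically
#'   \code{\link{er_graph}} with inhibitory strength).
#' @param tau_m,tau_d,tau_r membrane, synaptic-decay and synaptic-rise time
#'   constants in seconds.
#' @param v_thres,v_reset spike threshold and reset potential
#'   (\code{v_reset < v_thres}).
#' @param i_bias tonic drive, scalar or per-neuron vector.
#' @param dt integration step in seconds (default 0.05 ms).
#' @param duration simulated time in seconds.
#' @param output_rate voltage output rate in Hz (default 2000).
#' @param seed optional RNG seed (used for the random initial voltages).
#' @param v0 initial voltages; default uniform between \code{v_reset} and
#'   \code{v_thres}.
#' @param max_rate mean firing rate (Hz) above which the run is aborted as
#'   runaway.
#' @return list with \code{voltage} (a \code{\link{ddc_timeseries}}),
#'   \code{spikes} (a \code{\link{ddc_spiketrains}}) and \code{graph}.
#' @export
simulate_lif <- function(graph, tau_m = 0.02, tau_d = 0.01, tau_r = 0.001,
                         v_thres = 1, v_reset = 0, i_bias = NULL,
                         dt = 5e-5, duration = 20, output_rate = 2000,
                         seed = NULL, v0 = NULL, max_rate = 200) {
  g <- .as_graph(graph)
  W <- g$W
  n <- nrow(W)
  if (v_reset >= v_thres) stop("`v_reset` must be below `v_thres`")
  if (any(c(tau_m, tau_d, tau_r) <= 0)) stop("time constants must be positive")
  if (!is.null(seed)) set.seed(seed)
  # default drive: 10% above threshold; in the default 200-neuron
  # inhibitory network (sparsity 0.04, strength -0.4) this settles into an
  # asynchronous ~3.5 Hz regime
  if (is.null(i_bias)) i_bias <- 1.1 * v_thres
  i_bias <- rep_len(i_bias, n)
  if (is.null(v0)) v0 <- stats::runif(n, v_reset, v_thres)
  thin <- max(1L, as.integer(round(1 / (output_rate * dt))))
  n_steps <- round(duration / dt)
  res <- sim_lif_cpp(W, tau_m, tau_d, tau_r, v_thres, v_reset, i_bias,
                     dt, n_steps, thin, v0)
  ids <- paste0("n", seq_len(n))
  trains <- split(res$spike_time, factor(res$spike_neuron, levels = seq_len(n)))
  names(trains) <- ids
  spikes <- ddc_spiketrains(lapply(trains, as.numeric), duration = duration)
  mr <- mean(firing_rates(spikes))
  if (mr > max_rate)
    stop("runaway firing (mean rate ", round(mr, 1),
         " Hz); reduce `i_bias` or strengthen inhibition")
  v <- ddc_timeseries(res$V, dt = dt * thin, node_ids = ids)
  attr(v, "truth") <- g
  list(voltage = v, spikes = spikes, graph = g)
}

#' Split samples into active and quiet epochs
#'
#' Partitions the samples of a voltage recording by whether any neuron in
#' the network spikes within \code{window} seconds of the sample.  Each
#' side is returned both as index vectors (a complete partition of the
#' samples) and as lists of contiguous \code{\link{ddc_timeseries}}
#' segments; the derivative-based estimators accept such segment lists and
#' pool cross-products segment-wise, never across gaps.  Segments too short
#' to support a derivative (fewer than 3 samples) are kept in the index
#' partition but omitted from the segment list.
#'
#' @param v a \code{\link{ddc_timeseries}} of membrane voltage (samples
#'   assumed to start at time 0 on the spike clock).
#' @param spikes the matching \code{\link{ddc_spiketrains}}.
#' @param window half-width of the active window around each spike, seconds.
#' @return list with \code{active}, \code{quiet} (segment lists),
#'   \code{active_idx}, \code{quiet_idx}.
#' @export
split_active_quiet <- function(v, spikes, window) {
  .assert_ts(v)
  stopifnot(inherits(spikes, "ddc_spikes"), window >= 0)
  tt <- (seq_len(ncol(v$values)) - 1L) * v$dt
  st <- sort(unlist(spikes$spike_times, use.names = FALSE))
  if (length(st)) {
    lo <- findInterval(tt - window, st)
    hi <- findInterval(tt + window, st)
    active <- hi > lo
  } else {
    active <- rep(FALSE, length(tt))
  }
  if (!any(active)) stop("active partition is empty (no spikes near any sample)")
  if (all(active)) {
    segments <- function(idx) {
      runs <- split(idx, cumsum(c(1L, diff(idx) != 1L)))
      runs <- runs[lengths(runs) >= 3L]
      lapply(runs, function(r)
        ddc_timeseries(v$values[, r, drop = FALSE], dt = v$dt, node_ids = v$node_ids))
    }
    return(list(active = segments(which(active)), quiet = list(),
                active_idx = which(active), quiet_idx = integer(0)))
  }
  segments <- function(idx) {
    if (!length(idx)) return(list())
    runs <- split(idx, cumsum(c(1L, diff(idx) != 1L)))
    runs <- runs[lengths(runs) >= 3L]
    lapply(unname(runs), function(r)
      ddc_timeseries(v$values[, r, drop = FALSE], dt = v$dt, node_ids = v$node_ids))
  }
  list(active = segments(which(active)), quiet = segments(which(!active)),
       active_idx = which(active), quiet_idx = which(!active))
}

#' Simulate the reduced Wong-Wang mean-field model
#'
#' One synaptic gating variable \code{S} per region:
#' \code{dS = (-S/tau_s + (1 - S) gamma H(x)) dt + sigma dbeta} with the
#' firing-rate transfer \code{H(x) = (a x - b)/(1 - exp(-d (a x - b)))}
#' (continuous at \code{a x = b} with value \code{1/d}) and input
#' \code{x_i = c J S_i + G J sum_j W_ij S_j + I0}.  Defaults follow the
#' standard parameterization of the reduced model with the low-activity
#' preset \code{c = 0.01}, \code{I0 = -0.1}; all constants are arguments,
#' not code constants.
#'
#' @param graph nonnegative structural connectivity (anatomical weights).
#' @param a,b,d firing-rate transfer parameters (n/C, Hz, s).
#' @param gamma kinetic scaling of the gating variable.
#' @param tau_s gating time constant in seconds.
#' @param J synaptic coupling in nA.
#' @param G global coupling scaling.
#' @param c_local local (self) coupling scaling.
#' @param I0 background current in nA.
#' @param sigma noise standard deviation.
#' @param dt integration step in seconds.
#' @param duration simulated time in seconds.
#' @param sample_rate output rate in Hz.
#' @param seed optional RNG seed.
#' @param S0 initial gating values (default 0.1).
#' @return A \code{\link{ddc_timeseries}} of gating variables with
#'   \code{"truth"} attribute.
#' @export
simulate_wong_wang <- function(graph, a = 270, b = 108, d = 0.154,
                               gamma = 0.641, tau_s = 0.1, J = 0.2609,
                               G = 1, c_local = 0.01, I0 = -0.1,
                               sigma = 0.01, dt = 1e-3, duration = 100,
                               sample_rate = 1000, seed = NULL, S0 = NULL) {
  g <- .as_graph(graph)
  W <- g$W
  if (any(W < 0)) stop("structural weights must be nonnegative")
  n <- nrow(W)
  if (is.null(S0)) S0 <- rep(0.1, n)
  if (!is.null(seed)) set.seed(seed)
  thin <- max(1L, as.integer(round(1 / (sample_rate * dt))))
  n_steps <- round(duration / dt)
  x <- sim_wong_wang_cpp(W, a, b, d, gamma, tau_s, J, G, c_local, I0,
                         sigma, dt, n_steps, thin, S0)
  ts <- ddc_timeseries(x, dt = dt * thin)
  attr(ts, "truth") <- g
  ts
}

#' Firing-rate transfer function of the reduced Wong-Wang model
#' @param x input current.
#' @inheritParams simulate_wong_wang
#' @export
wong_wang_transfer <- function(x, a = 270, b = 108, d = 0.154) {
  u <- a * x - b
  ifelse(abs(u) < 1e-9, 1 / d, u / (1 - exp(-d * u)))
}
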