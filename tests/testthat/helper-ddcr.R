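# Shared fixtures, all generated in code.

make_ts <- function(values, dt = 0.01) ddc_timeseries(values, dt = dt)

rand_ts <- function(n = 3, Tn = 100, dt = 0.01, seed = 1) {
  set.seed(seed)
  ddc_timeseries(matrix(rnorm(n * Tn), n, Tn), dt = dt)
}

# random stable coupling matrix with strictly negative spectral abscissa
rand_stable_W <- function(n = 5, seed = 1, diag_decay = 1.5, coupling = 0.3) {
  set.seed(seed)
  repeat {
    W <- -diag_decay * diag(n) + coupling * matrix(rnorm(n * n), n, n)
    if (max(Re(eigen(W, only.values = TRUE)$values)) < -0.1) return(W)
  }
}

# noise-free Euler trajectory of dx/dt = W x from a given start; for data
# generated this way the forward difference quotient recovers W x exactly
euler_trajectory <- function(W, x0, dt = 0.01, n_steps = 2000) {
  n <- nrow(W)
  x <- matrix(0, n, n_steps + 1)
  x[, 1] <- x0
  A <- diag(n) + dt * W
  for (t in seq_len(n_steps)) x[, t + 1] <- A %*% x[, t]
  ddc_timeseries(x, dt = dt)
}

# an ensemble of decaying trajectories from random starts; restarting keeps
# the pooled state covariance well conditioned long after single runs decay
euler_segments <- function(W, n_seg = 20, steps_per_seg = 500, dt = 0.01,
                           seed = 1) {
  set.seed(seed)
  lapply(seq_len(n_seg), function(k)
    euler_trajectory(W, x0 = rnorm(nrow(W), sd = 2), dt = dt,
                     n_steps = steps_per_seg))
}

offdiag <- function(M) M[row(M) != col(M)]

# stationary Poisson spike train on [0, duration]
poisson_train <- function(rate, duration) {
  n <- rpois(1, rate * duration)
  sort(runif(n, 0, duration))
}
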