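test_that("covariance estimator is a correlation matrix on z-scored data", {
  set.seed(1)
  x <- matrix(rnorm(2 * 20000), 2, 20000)
  C <- cov_estimator(make_ts(x))$matrix
  expect_equal(diag(C), c(1, 1), tolerance = 1e-12)
  expect_identical(C, t(C))
  expect_lt(abs(C[1, 2]), 3 / sqrt(20000))   # independent nodes

  # a duplicated node correlates perfectly
  y <- rbind(x[1, ], x[1, ], x[2, ])
  C2 <- cov_estimator(make_ts(y))$matrix
  expect_equal(C2[1, 2], 1, tolerance = 1e-12)
})

test_that("covariance reports the confounder false positive that DDC removes", {
  g <- motif_graph("confounder")
  ts <- simulate_linear(g, sigma = 1, duration = 500, seed = 11)
  fp <- g$metadata$false_positive_pair
  C <- cov_estimator(ts)$matrix
  # the unconnected driven pair carries a clear covariance entry (analytic
  # correlation 0.111 for this motif); the DDC entry is smaller
  expect_gt(abs(C[fp[1], fp[2]]), 0.05)
  W <- ddc_linear(ts)$matrix
  expect_lt(abs(W[fp[1], fp[2]]) / max(abs(offdiag(W))),
            abs(C[fp[1], fp[2]]) / max(abs(offdiag(C))))
})

test_that("precision estimator inverts the covariance", {
  # identity covariance -> identity precision
  set.seed(2)
  ts <- rand_ts(2, 50000, seed = 2)
  C <- cov_estimator(ts)$matrix
  P <- precision_estimator(ts)$matrix
  expect_equal(P, solve(C), tolerance = 1e-10)
  # closed-form 2x2: [[1, r], [r, 1]]^-1 = 1/(1-r^2) [[1, -r], [-r, 1]]
  r <- C[1, 2]
  expect_equal(P, matrix(c(1, -r, -r, 1), 2) / (1 - r^2), tolerance = 1e-8)

  # multiply-back on 5 simulated nodes
  ts5 <- simulate_linear(rand_stable_W(5, seed = 3), duration = 50, seed = 3)
  expect_equal(precision_estimator(ts5)$matrix %*% cov_estimator(ts5)$matrix,
               diag(5), tolerance = 1e-8)
})

test_that("rank-deficient covariance demands the explicit pseudoinverse", {
  set.seed(4)
  x <- matrix(rnorm(2 * 500), 2, 500)
  dup <- make_ts(rbind(x, x[1, ] * 2))    # exactly collinear third node
  expect_error(precision_estimator(dup), "pseudoinverse")
  expect_silent(P <- precision_estimator(dup, pseudoinverse = TRUE)$matrix)
  expect_true(all(is.finite(P)))
})

test_that("regularized precision reduces to the plain precision at lambda 0", {
  ts <- simulate_linear(rand_stable_W(4, seed = 5), duration = 30, seed = 5)
  P <- precision_estimator(ts)$matrix
  expect_equal(regularized_precision(ts, "L1", 0)$matrix, P, tolerance = 1e-6)
  expect_lt(max(abs(regularized_precision(ts, "L2", 1e-10)$matrix -
                      P / tcrossprod(sqrt(diag(P))))), 1e-6)
  expect_error(regularized_precision(ts, "L1", -1), "nonnegative")
})

test_that("L1 penalty shrinks off-diagonals monotonically to zero", {
  ts <- simulate_linear(rand_stable_W(6, seed = 6), duration = 60, seed = 6)
  lambdas <- c(0.01, 0.05, 0.2, 0.9)
  counts <- vapply(lambdas, function(l) {
    Th <- regularized_precision(ts, "L1", l)$matrix
    sum(abs(offdiag(Th)) > 1e-3)
  }, 0)
  expect_true(all(diff(counts) <= 0))
  expect_equal(counts[length(counts)], 0)  # full shrinkage
})

test_that("L1 solution satisfies the penalized stationarity condition", {
  ts <- simulate_linear(rand_stable_W(5, seed = 7), duration = 60, seed = 7)
  S <- cov_estimator(ts)$matrix
  lambda <- 0.05
  Th <- regularized_precision(ts, "L1", lambda)$matrix
  Sig <- solve(Th)
  G <- Sig - S                     # should equal lambda * sign(Theta) off-diag
  off <- row(S) != col(S)
  act <- off & abs(Th) > 1e-6
  if (any(act))
    expect_lt(max(abs(G[act] - lambda * sign(Th[act]))), 1e-4)
  inact <- off & abs(Th) <= 1e-6
  if (any(inact))
    expect_lt(max(abs(G[inact])), lambda + 1e-4)
})

test_that("L2 solution is the unit-diagonal rescaled ridge inverse", {
  ts <- simulate_linear(rand_stable_W(10, seed = 8), duration = 60, seed = 8)
  S <- cov_estimator(ts)$matrix
  lambda <- 0.5
  Th <- regularized_precision(ts, "L2", lambda)$matrix
  raw <- solve(S + lambda * diag(10))
  expect_equal(Th, raw / tcrossprod(sqrt(diag(raw))), tolerance = 1e-6)
  expect_equal(diag(Th), rep(1, 10), tolerance = 1e-10)
})

test_that("differential covariance matches its composition oracle", {
  ts <- rand_ts(3, 200, seed = 9)
  M <- delta_c(ts)$matrix
  z <- zscore(ts)
  ref <- time_average_outer(numerical_derivative(z), trim_to_derivative(z))
  expect_equal(M, ref, tolerance = 1e-12)

  # constant input -> zero matrix (raw scale; a constant has no derivative)
  cst <- make_ts(matrix(5, 2, 50))
  expect_equal(delta_c(cst, scale = FALSE)$matrix, matrix(0, 2, 2))

  # pure decay with the analytic derivative substituted: <dx/dt, x> = -<x, x>
  x <- rand_ts(1, 300, seed = 10)
  d <- ddc_timeseries(-x$values, dt = x$dt)
  expect_equal(delta_c(x, scale = FALSE, deriv_ts = d)$matrix,
               -time_average_outer(x, x), tolerance = 1e-12)
})

test_that("partial differential covariance matches a literal loop", {
  ts <- rand_ts(4, 300, seed = 11)
  Dp <- delta_p(ts)$matrix
  dc <- delta_c(ts)$matrix
  C <- cov_estimator(ts)$matrix
  for (i in 1:4) for (j in 1:4) {
    if (i == j) next
    K <- setdiff(1:4, c(i, j))
    ref <- dc[i, j] - C[j, K] %*% solve(C[K, K]) %*% dc[i, K]
    expect_equal(Dp[i, j], as.numeric(ref), tolerance = 1e-10)
  }
  expect_equal(diag(Dp), diag(dc))

  # with two nodes the conditioning set is empty and Dp = Dc
  ts2 <- rand_ts(2, 100, seed = 12)
  expect_equal(delta_p(ts2)$matrix, delta_c(ts2)$matrix)
})

test_that("partial differential covariance vanishes for independent noise", {
  set.seed(13)
  ts <- rand_ts(4, 1e5, seed = 13)
  Dp <- delta_p(ts)$matrix
  # the derivative scale is 1/dt; compare against the matched null bound
  expect_lt(max(abs(offdiag(Dp))) * ts$dt, 5 / sqrt(1e5))
})

test_that("linear DDC is the least-squares solution of the system equations", {
  ts <- rand_ts(3, 400, seed = 14)
  W <- ddc_linear(ts)$matrix
  # normal-equations oracle: regress each derivative node on all state
  # nodes (with an intercept, since the estimator centers the trimmed state)
  z <- zscore(ts)
  d <- numerical_derivative(z, "forward")$values
  x <- trim_to_derivative(z, "forward")$values
  for (i in 1:3) {
    beta <- unname(coef(lm(d[i, ] ~ t(x))))[-1]
    expect_equal(W[i, ], beta, tolerance = 1e-8)
  }
})

test_that("linear DDC recovers W exactly on consistent linear data", {
  W <- rand_stable_W(4, seed = 15)
  segs <- euler_segments(W, n_seg = 10, steps_per_seg = 300, seed = 15)
  full <- ddc_timeseries(do.call(cbind, lapply(segs, `[[`, "values")),
                         dt = 0.01)
  # analytic derivative: substituting dx/dt = W x makes the identity exact
  d <- ddc_timeseries(W %*% full$values, dt = full$dt)
  est <- ddc_linear(full, scale = FALSE, deriv_ts = d)$matrix
  expect_equal(est, W, tolerance = 1e-10)
  # forward quotient on Euler-generated data is exact as well
  est2 <- ddc_linear(segs, deriv = "forward", scale = FALSE)$matrix
  expect_equal(est2, W, tolerance = 1e-8)
})

test_that("linear DDC on leaky dynamics returns (W - I)/tau", {
  W <- rand_stable_W(3, seed = 16, diag_decay = 0.4, coupling = 0.2)
  tau <- 0.2
  Weff <- (W - diag(3)) / tau
  segs <- euler_segments(Weff, n_seg = 10, steps_per_seg = 400, dt = 0.005,
                         seed = 16)
  est <- ddc_linear(segs, scale = FALSE)$matrix
  expect_equal(est, Weff, tolerance = 1e-6)
})

test_that("directed motifs break the symmetry of linear DDC", {
  g <- motif_graph("confounder")
  ts <- simulate_linear(g, duration = 500, seed = 17)
  W <- ddc_linear(ts)$matrix
  expect_gt(abs(W[2, 1]), abs(W[1, 2]))
  expect_gt(abs(W[3, 1]), abs(W[1, 3]))
  C <- cov_estimator(ts)$matrix
  expect_identical(C, t(C))
})

test_that("nonlinear DDC degrades gracefully to the linear estimator", {
  ts <- rand_ts(3, 500, seed = 18)
  lin <- ddc_linear(ts)$matrix
  expect_equal(ddc_nonlinear(ts, response_identity())$matrix, lin,
               tolerance = 1e-12)
  # rectifier threshold below the data minimum leaves the signal untouched
  zmin <- min(zscore(ts)$values)
  expect_equal(ddc_nonlinear(ts, response_relu(zmin - 1))$matrix, lin,
               tolerance = 1e-10)
})

test_that("nonlinear DDC errors informatively on a saturated rectifier", {
  ts <- rand_ts(3, 200, seed = 19)
  zmax <- max(zscore(ts)$values)
  expect_error(ddc_nonlinear(ts, response_relu(zmax + 1)), "rank deficient|singular")
})

test_that("rectifier threshold scan favors the stated optimum", {
  g <- motif_graph("chain")
  ts <- simulate_linear(g, duration = 300, seed = 20)
  # on linear dynamics the optimum approximates the linear estimator
  scan <- relu_threshold_scan(ts, g, criterion = "error")
  lin_err <- error_bias_variance(list(ddc_linear(ts)$matrix), g)$error
  expect_lt(scan$score[which(scan$grid == scan$theta)], lin_err + 0.05)
  # a one-point grid returns that point
  single <- relu_threshold_scan(ts, g, probs = 0.5)
  expect_equal(single$theta, unname(quantile(zscore(ts)$values, 0.5)))
  # default grid optimum within one grid step of an exhaustive finer grid
  fine <- relu_threshold_scan(ts, g, probs = seq(0.05, 0.95, length.out = 91))
  step <- diff(scan$grid[1:2])
  expect_lt(abs(scan$theta - fine$theta), 2 * abs(step) + 1e-8)
  expect_error(relu_threshold_scan(ts, NULL), "ground")
})

test_that("leaky DDC inverts the temporally filtered system", {
  # data satisfying tau dx/dt = -x + W R(x) exactly via the analytic derivative
  set.seed(21)
  W <- rand_stable_W(3, seed = 21, diag_decay = 0.5, coupling = 0.3)
  tau <- 0.15
  xv <- matrix(rnorm(3 * 2000), 3)
  xv <- xv - rowMeans(xv)           # zero-mean state: centering R(x) is exact
  x <- make_ts(xv)
  Rfun <- response_sigmoid(2)
  rx <- apply_response(Rfun, xv)
  d <- ddc_timeseries((-xv + W %*% rx) / tau, dt = x$dt)
  est <- ddc_leaky(x, Rfun, tau = tau, scale = FALSE, deriv_ts = d)$matrix
  expect_equal(est, W, tolerance = 1e-10)
  expect_error(ddc_leaky(x, Rfun, tau = -1), "positive")
})

test_that("leaky DDC tends to the identity as tau vanishes", {
  ts <- rand_ts(4, 2000, seed = 22)
  est <- ddc_leaky(ts, response_identity(), tau = 1e-10)$matrix
  expect_equal(est, diag(4), tolerance = 1e-6)
})

test_that("leaky DDC beats the linear estimator on leaky sigmoid dynamics", {
  # ensemble of relaxations of a stable 5-node leaky sigmoid system; the
  # saturating nonlinearity defeats the purely linear estimator
  set.seed(23)
  repeat {
    W <- -0.3 * diag(5) + 0.6 * matrix(rnorm(25), 5)
    if (max(Re(eigen((W - diag(5)) / 0.1, only.values = TRUE)$values)) < -0.5) break
  }
  tau <- 0.1; alpha <- 4; dt <- 1e-3
  segs <- lapply(1:20, function(k) {
    x <- matrix(0, 5, 501); x[, 1] <- rnorm(5, sd = 2)
    for (t in 1:500) {
      r <- 1 / (1 + exp(-alpha * x[, t])) - 0.5
      x[, t + 1] <- x[, t] + (dt / tau) * (-x[, t] + W %*% r)
    }
    ddc_timeseries(x, dt = dt)
  })
  err <- function(M) error_bias_variance(list(M), W)$error
  eD <- err(ddc_leaky(segs, response_sigmoid(alpha), tau = tau, scale = FALSE)$matrix)
  eL <- err(ddc_linear(segs, scale = FALSE)$matrix)
  expect_lt(eD, 1e-8)               # exact inversion of the generating model
  expect_lt(eD, eL)
})
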