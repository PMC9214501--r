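test_that("motif graphs carry the stated topology", {
  ch <- motif_graph("chain")
  expect_equal(diag(ch$W), rep(-1, 3))
  expect_equal(ch$W[2, 1], -0.5)
  expect_equal(ch$W[3, 2], -0.5)
  expect_equal(ch$W[3, 1], 0)        # no edge between ends of the chain
  cf <- motif_graph("confounder")
  e <- which(edge_mask(cf), arr.ind = TRUE)
  expect_equal(nrow(e), 2)
  expect_equal(unique(e[, "col"]), 1L)   # both edges share the source column
  expect_equal(motif_graph("chain", strength = 0)$W, diag(-1, 3))
})

test_that("Erdos-Renyi graphs hit their edge-count expectation", {
  expect_equal(sum(edge_mask(er_graph(10, 0, seed = 1))), 0)
  expect_equal(sum(edge_mask(er_graph(10, 1, seed = 1))), 90)
  counts <- vapply(1:100, function(s) sum(edge_mask(er_graph(200, 0.04, seed = s))), 0)
  expected <- 0.04 * 200 * 199
  sd_bin <- sqrt(200 * 199 * 0.04 * 0.96)
  expect_lt(abs(mean(counts) - expected), 3 * sd_bin / sqrt(100))
})

test_that("degree-preserving randomization keeps degrees, scrambles edges", {
  g <- er_graph(200, 0.04, seed = 2)
  r <- degree_preserving_randomize(g, seed = 3)
  expect_equal(degree_sequences(r), degree_sequences(g))
  expect_equal(degree_preserving_randomize(g, n_swaps = 0)$W, g$W)
  jac <- sum(edge_mask(g) & edge_mask(r)) / sum(edge_mask(g) | edge_mask(r))
  expect_lt(jac, 0.5)
  tiny <- ddc_network(matrix(c(0, 1, 0, 0), 2))
  expect_warning(degree_preserving_randomize(tiny), "unchanged")
})

test_that("the linear simulator is seeded and degenerate cases behave", {
  g <- motif_graph("confounder")
  a <- simulate_linear(g, duration = 5, seed = 42)
  b <- simulate_linear(g, duration = 5, seed = 42)
  expect_identical(a$values, b$values)
  z <- simulate_linear(g, sigma = 0, duration = 5, seed = 1)
  expect_true(all(z$values == 0))
  expect_warning(simulate_linear(matrix(0.5, 1, 1), duration = 1),
                 "spectral abscissa")
})

test_that("Lyapunov solver satisfies its equation and closed forms", {
  expect_equal(lyapunov_steady_cov(-diag(3)), diag(3) / 2)
  W <- rand_stable_W(5, seed = 4)
  set.seed(4)
  D <- matrix(rnorm(25), 5)
  Q <- crossprod(matrix(rnorm(25), 5)) / 5
  P <- lyapunov_steady_cov(W, D, Q)
  expect_lt(norm(W %*% P + P %*% t(W) + D %*% Q %*% t(D), "F"), 1e-10)
  expect_gte(min(eigen(P, symmetric = TRUE, only.values = TRUE)$values), -1e-10)
  expect_error(lyapunov_steady_cov(diag(2)), "not stable")
})

test_that("state-dependent noise structures shape the analytic covariance", {
  W <- motif_graph("confounder")$W
  D2 <- matrix(c(1, 0, 1, 1, 1, 0, 0, 1, 1), 3, 3, byrow = TRUE)
  P1 <- lyapunov_steady_cov(W, diag(3))
  P2 <- lyapunov_steady_cov(W, D2)
  expect_gt(max(abs(offdiag(P1) - offdiag(P2))), 0.1)
})

test_that("long-run simulated covariance approaches the Lyapunov solution", {
  g <- motif_graph("confounder")
  ts <- simulate_linear(g, sigma = 1, duration = 500, seed = 5)
  x <- ts$values - rowMeans(ts$values)
  Ps <- tcrossprod(x) / ncol(x)
  Pa <- lyapunov_steady_cov(g$W, diag(3), diag(3))
  expect_lt(norm(Ps - Pa, "F") / norm(Pa, "F"), 0.2)
})

test_that("two-state simulation switches the noise structure as configured", {
  ts <- simulate_two_state(duration = 40, switch_time = 20, seed = 6)
  st <- attr(ts, "states")
  expect_equal(st$D2, matrix(c(1, 0, 1, 1, 1, 0, 0, 1, 1), 3, 3, byrow = TRUE))
  expect_equal(st$D1, diag(3))
  expect_error(simulate_two_state(duration = 10, switch_time = 10), "before")
})

test_that("Rossler trajectory is bounded and the transient is discarded", {
  ts <- simulate_rossler(duration = 300, transient_discard = 100)
  expect_equal(ncol(ts$values), round(200 / 0.01) + 1)
  expect_lt(max(abs(ts$values)), 1e3)
  expect_error(simulate_rossler(duration = 50, transient_discard = 100),
               "exceed")
})

test_that("the centered sigmoid response is odd with slope alpha/4 at zero", {
  R <- response_sigmoid(1.7)
  x <- seq(-4, 4, by = 0.25)
  expect_equal(apply_response(R, -x), -apply_response(R, x), tolerance = 1e-14)
  expect_equal(apply_response(R, 1e-8) / 1e-8, 1.7 / 4, tolerance = 1e-6)
})

test_that("small-signal sigmoid dynamics recover the coupling pattern", {
  g <- motif_graph("chain")
  hits <- vapply(1:3, function(s) {
    ts <- simulate_sigmoid(g, sigma = 0.5, duration = 600, seed = s)
    M <- ddc_linear(ts)$matrix
    diag(M) <- 0
    setequal(order(abs(M), decreasing = TRUE)[1:2], which(edge_mask(g)))
  }, logical(1))
  expect_gte(sum(hits), 2)
})

test_that("LIF neurons without input settle at the bias fixed point", {
  g <- ddc_network(matrix(0, 3, 3))
  res <- simulate_lif(g, i_bias = 0.8, duration = 1, seed = 8)
  expect_equal(sum(firing_rates(res$spikes)), 0)
  expect_equal(unname(res$voltage$values[, ncol(res$voltage$values)]),
               rep(0.8, 3), tolerance = 1e-3)
})

test_that("reported LIF voltage respects threshold and reset bookkeeping", {
  g <- er_graph(20, 0.1, -0.4, seed = 9)
  res <- simulate_lif(g, duration = 2, seed = 9, output_rate = 20000)
  expect_lt(max(res$voltage$values), 1 + 1e-12)
  # every spike coincides with a reset at integration resolution
  dt <- res$voltage$dt
  for (i in seq_len(5)) {
    tk <- res$spikes$spike_times[[i]]
    if (!length(tk)) next
    idx <- round(tk / dt) + 1L
    idx <- idx[idx <= ncol(res$voltage$values)]
    expect_true(all(res$voltage$values[i, idx] == 0))
  }
  expect_error(simulate_lif(g, i_bias = 60, duration = 0.5, seed = 1),
               "runaway")
})

test_that("active/quiet splitting partitions the samples", {
  g <- er_graph(10, 0.1, -0.4, seed = 10)
  res <- simulate_lif(g, duration = 2, seed = 10)
  sp <- split_active_quiet(res$voltage, res$spikes, window = 0.002)
  total <- ncol(res$voltage$values)
  expect_equal(sort(c(sp$active_idx, sp$quiet_idx)), seq_len(total))
  expect_gt(length(sp$active), 0)
  # no spikes at all -> the active side is empty and reported as such
  quiet_sp <- ddc_spiketrains(rep(list(numeric(0)), 10), duration = 2)
  expect_error(split_active_quiet(res$voltage, quiet_sp, 0.002), "active")
  # a spike next to every sample -> everything is active
  dense <- ddc_spiketrains(list(seq(0, 2, by = 0.001)), duration = 2)
  all_active <- split_active_quiet(res$voltage, dense, window = 0.01)
  expect_equal(length(all_active$quiet_idx), 0)
})

test_that("segmented estimation pools cross-products without crossing gaps", {
  ts <- rand_ts(3, 60, seed = 11)
  seg1 <- ddc_timeseries(ts$values[, 1:30], dt = ts$dt)
  seg2 <- ddc_timeseries(ts$values[, 31:60], dt = ts$dt)
  pooled <- ddc_linear(list(seg1, seg2), scale = FALSE)$matrix
  d1 <- numerical_derivative(seg1, "forward")$values
  d2 <- numerical_derivative(seg2, "forward")$values
  x1 <- seg1$values[, 1:29]; x2 <- seg2$values[, 1:29]
  xp <- cbind(x1, x2)
  xp <- xp - rowMeans(xp)            # pooled centering, as the estimator does
  dC <- tcrossprod(cbind(d1, d2), xp) / 58
  C <- tcrossprod(xp) / 58
  expect_equal(pooled, dC %*% solve(C), tolerance = 1e-12)
})

test_that("Wong-Wang transfer is continuous at its removable singularity", {
  d <- 0.154
  expect_equal(wong_wang_transfer(108 / 270), 1 / d, tolerance = 1e-6)
  eps <- 1e-12
  expect_equal(wong_wang_transfer(108 / 270 + eps),
               wong_wang_transfer(108 / 270 - eps), tolerance = 1e-6)
})

test_that("uncoupled noise-free Wong-Wang nodes reach the bisection fixed point", {
  W <- matrix(0, 3, 3)
  ts <- simulate_wong_wang(W, G = 0, sigma = 0, duration = 5, seed = 12)
  final <- ts$values[, ncol(ts$values)]
  # independent root finder for dS/dt = 0
  f <- function(S) -S / 0.1 + (1 - S) * 0.641 *
    wong_wang_transfer(0.01 * 0.2609 * S - 0.1)
  root <- uniroot(f, c(0, 0.9), tol = 1e-12)$root
  expect_equal(unname(final), rep(root, 3), tolerance = 1e-4)
})

test_that("simulators reject invalid structural input", {
  expect_error(simulate_wong_wang(matrix(-1, 2, 2)), "nonnegative")
  expect_error(er_graph(5, 1.5), "sparsity")
})
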