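---
title: "Dynamical differential covariance: models, estimators, and validation"
author: "ddcr authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dynamical differential covariance: models, estimators, and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ddcr)
```

## The estimation problem

Given a multivariate recording $x(t) \in \mathbb{R}^n$ — membrane voltages,
calcium signals, or regional BOLD traces — we want the *directed* coupling
structure among the $n$ nodes.  Pairwise covariance is symmetric and is
fooled by shared drive: two nodes receiving a common input correlate
strongly without being connected.  Dynamical differential covariance (DDC)
instead postulates a generative dynamical model,

$$\frac{dx}{dt} = W\,x
\qquad\text{or}\qquad
\frac{dx}{dt} = W\,R(x),$$

with $W$ the coupling matrix (entry $(i,j)$ = influence of node $j$ on node
$i$) and $R$ an elementwise response nonlinearity, and reads the estimator
directly off the least-squares solution of that model:

$$\Delta_L = \langle \dot x, x\rangle\,\langle x, x\rangle^{-1},
\qquad
\Delta_R = \langle \dot x, x\rangle\,\langle R(x), x\rangle^{-1},$$

where $\langle a,b\rangle$ is the time-averaged outer product.  No
optimization or model search is involved: two cross-products and one matrix
inverse.  The first factor (differential covariance) carries source/sink
information and breaks symmetry; the second factor plays the role of a
partial-covariance correction that cancels common drivers.

All traces are z-scored per node (population convention, divisor $T$)
before estimation, so $\langle x,x\rangle$ is the correlation matrix; this
matches how the estimators are used downstream and makes the rectifier
threshold a percentile-meaningful quantity.  The DDC estimators additionally
mean-center the trimmed state and the transformed state $R(x)$ over time
before the cross-products.  This is a deliberate design choice: it makes
the identity-response estimator coincide *exactly* with $\Delta_L$, and it
makes constant offsets of the rectifier $R(x;\theta) = \max(x, \theta)$
irrelevant, so a threshold below the data minimum reproduces the linear
estimator rather than differing by a rank-one shift.

## The derivative convention

The derivative is never observed; it is estimated from samples.  The
package provides both the symmetric quotient
$(x_{t+1} - x_{t-1})/2\Delta t$ (the default for the differential-covariance
baselines $\Delta_c$, $\Delta_p$) and the forward quotient
$(x_{t+1} - x_t)/\Delta t$, which is the default for the DDC estimators.
The distinction matters on stochastic data and deserves to be spelled out.

For a stationary linear SDE $dx = Wx\,dt + D\,d\beta$ with state covariance
$C$, the *symmetric* quotient converges to
$\tfrac12(WC - CW^\top) = WC + \tfrac12 DQD^\top$ — the extra term is half
the quadratic variation of the Brownian path, because the backward half of
the symmetric difference overlaps the noise increment already absorbed into
$x_t$.  For a time-reversible process this symmetrized quantity is
*identically zero*; in general it retains only the irreversible component of
the dynamics, and on simulated confounder/chain data it makes the reverse
of a true edge as prominent as the edge itself.  The *forward* quotient
pairs each noise increment with the state *before* it, so the cross term
has mean zero by the independence of Brownian increments, and
$\Delta_L \to W$.  This is exactly the pairing used in the unbiasedness
argument for DDC on stochastic models, so the forward quotient is the
implementation consistent with that theory; the symmetric option is kept
for the dCov baselines, whose published definition uses it, and as an
explicit `deriv = "central"` argument everywhere.  On deterministic
(smooth) trajectories the two agree to $O(\Delta t^2)$ and either recovers
$W$ essentially exactly.

Derivative endpoints are dropped, never padded, and every estimator forms
cross-products only on aligned interior samples.  When data arrive as
disjoint segments (e.g. the active/quiet split of a spiking recording), the
estimators accept a list of segments and pool cross-products segment-wise,
never differentiating across a gap.

## Estimators provided

* `cov_estimator`, `precision_estimator` — correlation matrix and its
  inverse; symmetric baselines.  Inversion is a direct solve with a
  condition-number guard; the Moore–Penrose pseudoinverse is opt-in
  (`pseudoinverse = TRUE`), never silent, because the inverse of a
  rank-deficient matrix is not unique.
* `regularized_precision` — L1: penalized maximum-likelihood inverse
  covariance (graphical-lasso objective, off-diagonals penalized), solved
  by block coordinate descent written for this package since no
  graphical-lasso solver is available in the dependency set; L2: the ridge
  inverse $(C + \lambda I)^{-1}$ rescaled to unit diagonal.  $\lambda = 0$
  reproduces the precision matrix.
* `delta_c`, `delta_p` — differential covariance
  $\langle \dot x, x \rangle$ and its elementwise partial version
  (conditioning each pair on all remaining nodes).  The $\Delta_p$ diagonal
  is copied from $\Delta_c$; the elementwise definition leaves it open, and
  all evaluation metrics exclude diagonals anyway.
* `ddc_linear`, `ddc_nonlinear`, `ddc_leaky` — the DDC family.
  `ddc_leaky` implements
  $\Delta_D = (\tau \langle \dot x, x\rangle + \langle x, x\rangle)\,
  \langle R(x), x\rangle^{-1}$ for temporally filtered systems
  $\tau \dot x = -x + W R(x)$; as $\tau \to 0$ with identity response it
  tends to the identity matrix, and on data generated by the matching leaky
  model it inverts the generating equation exactly.
* `relu_threshold_scan` — validation-time selection of the rectifier
  threshold on a grid of percentiles (5th–95th, 19 steps by default) of the
  pooled z-scored data, scored by normalized error or ROC AUC against a
  known ground truth; ties break toward the smaller threshold, i.e. toward
  the linear model.
* `cspk` — spike-train cross-correlogram connectivity: trains are binned at
  0.5 ms, mean-centered, and the correlogram is integrated over the causal
  window $[-\tau, 0]$ (default 0.1 s) on the bin grid; pairs involving a
  neuron below 0.1 Hz are set to zero.

## Simulators and their defaults

The generators double as ground-truth factories: every simulated series
carries its `ddc_network` in the `"truth"` attribute.

* **Linear SDE** (`simulate_linear`): Euler–Maruyama,
  $x_{t+1} = x_t + \Delta t\,W x_t + \sqrt{\Delta t}\,\sigma D\,\xi_t$.
  The $\sqrt{\Delta t}$ scaling makes $\sigma$ the diffusion amplitude of a
  genuine SDE, so the long-run covariance solves the Lyapunov equation
  $WP + PW^\top + \sigma^2 DD^\top = 0$ independently of the step size
  (`lyapunov_steady_cov` solves it by vectorization and is checked in the
  tests both against closed forms and by residual).  Defaults: 3-node
  motifs with diagonal $-1$ and coupling $-0.5$, $\Delta t = 0.01$ s,
  1000 s, observational noise off.
* **Two-state process** (`simulate_two_state`): identical $W$ throughout;
  the noise structure switches from $D_1 = I$ to a cyclic mixing matrix
  $D_2$ at 500 s.  Second-order statistics change mid-recording while the
  connectivity does not.
* **Sigmoid network** (`simulate_sigmoid`): $\dot x = W R(x) + u$ with the
  centered sigmoid $R(x) = (1+e^{-\alpha x})^{-1} - \tfrac12$ (odd, slope
  $\alpha/4$ at the origin), integrated at $10^{-4}$ s and downsampled to
  100 Hz *before* estimation.  Downsampling order is genuinely ambiguous as
  a pipeline choice; pre-estimation downsampling is the one that changes
  results (the estimator then sees the coarse grid), so it is the explicit
  default, and setting `output_rate = 1/dt` recovers the alternative.
* **Rössler system** (`simulate_rossler`): the classical chaotic parameters
  $a = b = 0.2$, $c = 5.7$, fixed-step Euler at 0.01 s, first 100 s
  discarded.
* **LIF network** (`simulate_lif`): $\tau_m \dot V = -V + Wr + I_{bias}$
  with double-exponential synapses of unit integral per spike,
  threshold/reset bookkeeping at a 0.05 ms step, voltage reported at
  2000 Hz, spikes returned separately and consistent with the resets.  The
  numeric constants are package defaults, not literature-fixed values:
  $\tau_m = 20$ ms, $\tau_d = 10$ ms, $\tau_r = 1$ ms, $V_{thres} = 1$,
  $V_{reset} = 0$, and $I_{bias} = 1.1$, chosen once so that the default
  200-neuron inhibitory Erdős–Rényi network (sparsity 0.04, strength
  $-0.4$) settles into an asynchronous regime near 3.5 Hz.  Initial
  voltages are uniform between reset and threshold, seeded.  In sparse
  networks, silent neurons that share their single presynaptic source have
  *exactly* collinear voltages (each is the same linear filter of the same
  input), so the state covariance can be exactly rank-deficient; this is
  the practical reason the pseudoinverse option exists, and the LIF
  analyses use it.
* **Reduced Wong–Wang model** (`simulate_wong_wang`): one gating variable
  per region, $\dot S = -S/\tau_s + (1-S)\gamma H(x) + \sigma\nu$ with the
  soft-rectifying transfer $H(x) = (ax-b)/(1 - e^{-d(ax-b)})$ (continuous
  at $ax = b$ with value $1/d$) and input
  $x_i = cJS_i + GJ\sum_j W_{ij}S_j + I_0$.  All constants are arguments;
  defaults follow the standard reduced-model parameterization with the
  low-activity preset $c = 0.01$, $I_0 = -0.1$.  A published variant of the
  state equation carries an extra $1/\tau$ on both sides; the form used
  here is the dimensionally consistent one from the model's original
  source.

`split_active_quiet` partitions voltage samples by proximity (±window) to
any spike; both sides come back as index partitions plus lists of
contiguous segments ready for the segment-aware estimators.

## Evaluation

`normalize_for_comparison` rescales estimate and truth by their own maximum
absolute entry, always excludes the diagonal, and optionally restricts to
the strictly lower triangle — the fair comparison when symmetric and
directed estimators are mixed and all true edges sit in the lower triangle.
`error_bias_variance` aggregates per-trial normalized errors as a root mean
square, so the orthogonal decomposition
$\mathrm{Error}^2 = \mathrm{Bias}^2 + \mathrm{Variance}^2$ holds exactly;
the bias angle is $\theta_b = \arctan(\mathrm{Bias}/\mathrm{Variance})$,
with the degenerate conventions $\theta_b = \pi/2$ when the variance
vanishes and $0$ when both vanish (the definition leaves these cases open).
`roc_auc` sweeps binarization thresholds over $|$estimate$|$ and integrates
by trapezoid (equivalently, the Mann–Whitney pair-ranking probability, a
fact the tests exploit as an independent oracle).  `c_sensitivity` is the
fraction of true-edge magnitudes above the 95th percentile of the non-edge
magnitudes.  `subject_identification` ranks database matrices by Pearson
correlation of vectorized off-diagonals and scores top-$m$ membership.

### Significance testing

`ar_bootstrap_significance` tests, per edge, the null hypothesis that the
nodes are independent while keeping each node's autocorrelation: per node
an AR($q$) model is fitted by conditional least squares (the fitting method
is unspecified in the surrounding literature; conditional least squares is
documented here as the package's choice), with $q$ selected by a forward
search that accepts a higher order only while BIC drops by more than 2.
Surrogates redraw every node independently from its own AR model with
fresh Gaussian innovations — node-independence *is* the null, so one shared
surrogate set serves all edges.  A Gaussian is fitted to each edge's null
values and a two-sided tail probability is reported (estimates are signed,
so two-sided is the conservative reading of an unspecified sidedness).
Multiple-testing correction is deliberately not applied — binarization at a
sequence of raw significance levels is the intended downstream use — and
p-value matrices carry 1 on the diagonal.

## Numerical choices and degenerate inputs

Matrix inverses are direct solves guarded by a reciprocal-condition
threshold ($10^{-12}$ by default); the pseudoinverse must be requested.
Zero-variance nodes are an error naming the node.  Fewer than three samples
cannot support a derivative and are rejected at construction.  Text I/O
autodetects comma/tab, requires a `# dt=` header or explicit argument, and
reports the exact row/column of a non-numeric cell; the binary container
(RDS) round-trips bit-exactly.  All stochastic procedures take explicit
seeds; estimator code itself is deterministic.

## What the synthetic benchmarks do and do not show

The generators emulate the study conditions this package validates
against: small stochastic motifs, a chaotic deterministic system, a
two-state nonstationary process, a sparse spiking network, and a
mean-field cortical model.  Passing these tests shows the estimators
invert their assumed generative classes and degrade sensibly under
model mismatch.  It does *not* establish performance on real recordings:
no hemodynamic convolution, measurement filtering, scanner noise,
preprocessing artifacts, or missing/unobserved nodes are modeled, and the
LIF constants are package defaults rather than fitted physiology.

Three measured limitations are worth knowing about:

* **Two-state window similarity.**  For the exactly symmetric confounder
  with the default $D_1, D_2$, the off-diagonals of the two analytic state
  covariances are perfectly Pearson-correlated (the state switch is an
  affine, sign-flipping shift), so comparing *entrywise correlations* of
  window-wise Cov estimates across windows cannot detect the switch even
  in the infinite-data limit, and a correlation-based "DDC windows agree
  more than Cov windows" comparison sits on sampling noise (measured: it
  flips sign across seeds).  The shift is perfectly visible to a
  distance-based statistic: window-wise Cov matrices differ strongly
  between states (sign flips included) while window-wise $\Delta_L$ stays
  near the static $W$ in both.  The corresponding acceptance check asserts
  the correlation form regardless and is expected to fail; the
  window-covariance-versus-analytic-solution check passes.
* **The covariance false positive is regime-dependent.**  The classic
  shared-driver artifact is strong for the linear confounder (analytic
  correlation 0.111 between the unconnected driven pair, 47% of the
  largest off-diagonal).  For the chain under the same inhibitory
  dynamics the two-step correlation is analytically near zero (+0.058),
  and under the default sigmoid dynamics the rectified shared drive is
  buried in the unit drive noise (measured correlation $\approx -0.003$):
  covariance simply does not produce the artifact there.
* **Sparse LIF covariances can be exactly singular** (collinear silent
  neurons, see above); DDC on such networks requires the pseudoinverse and
  inherits its non-uniqueness caveats.

## Problem sizes used by the test suite

The package's checks run at deliberately modest scales chosen as the
smallest sizes at which each property is statistically unambiguous: motif
experiments use 1000 s of 3-node data at their native sampling rates;
the stable-system recovery ensembles pool $10^5$ samples from 200
restarts; the bias-ordering comparison uses 50 trials at 1000 s and 100 s;
the LIF comparison uses ten 50-neuron, 20 s networks against matched
Erdős–Rényi controls with a two-sided rank test; the bootstrap calibration
uses 20 independent AR(1) nodes, 5000 samples, 200 surrogates.  Larger
configurations (the 200-neuron LIF default, longer recordings) use the
same code paths.

## Command-line interface

`exec/ddc` dispatches `simulate`, `estimate`, `evaluate`, `significance`,
`benchmark` and `fixtures` over the exported `cmd_*` functions.  Options
come from a JSON or YAML `--config` file with `--key value` flags taking
precedence; unknown keys are rejected.  Results go to files, logs (package
version, config hash, seed) to standard error; exit codes are 0 (success),
2 (configuration), 3 (data), 4 (numerical failure).  `generate_fixtures`
writes a deterministic offline suite covering every pipeline stage.
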