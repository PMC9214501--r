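// Euler(-Maruyama) integration kernels for the network simulators.  All
// randomness is drawn from R's RNG so set.seed() in R fully determines the
// trajectories.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Linear SDE dx = W x dt + sqrt(dt) sigma D xi, with an optional switch of
// the noise structure from D to D2 at step `switch_step` (-1 = never).
// Returns the trajectory (n x (n_steps+1)) and, optionally, the per-step
// noise increments expressed as dbeta/dt = sigma xi / sqrt(dt).
// [[Rcpp::export]]
List sim_linear_cpp(const arma::mat& W, const arma::mat& D,
                    const arma::mat& D2, int switch_step,
                    double sigma, double sigma_obs, double dt, int n_steps,
                    const arma::vec& x0, bool keep_drive) {
  const int n = W.n_rows;
  arma::mat x(n, n_steps + 1);
  x.col(0) = x0;
  arma::mat drive;
  if (keep_drive) drive.set_size(n, n_steps);
  const double sq = sigma * std::sqrt(dt);
  arma::vec xi(n);
  for (int t = 0; t < n_steps; ++t) {
    for (int i = 0; i < n; ++i) xi(i) = R::norm_rand();
    const arma::mat& Dt = (switch_step >= 0 && t >= switch_step) ? D2 : D;
    x.col(t + 1) = x.col(t) + dt * (W * x.col(t)) + sq * (Dt * xi);
    if (keep_drive) drive.col(t) = (sigma / std::sqrt(dt)) * (Dt * xi);
    if (arma::abs(x.col(t + 1)).max() > 1e6)
      stop("trajectory diverged (|x| > 1e6 at t = %g s); use a smaller dt or a stable W",
           (t + 1) * dt);
  }
  if (sigma_obs > 0) {
    for (arma::uword k = 0; k < x.n_elem; ++k) x(k) += sigma_obs * R::norm_rand();
  }
  List out = List::create(Named("x") = x);
  if (keep_drive) out["drive"] = drive;
  return out;
}

// Sigmoid-coupled SDE dx = W R(x) dt + sqrt(dt) sigma xi with the centered
// sigmoid R(x) = 1/(1+exp(-alpha x)) - 1/2.  Integrated at dt and thinned
// by `thin` on output.
// [[Rcpp::export]]
arma::mat sim_sigmoid_cpp(const arma::mat& W, double alpha, double sigma,
                          double dt, int n_steps, int thin,
                          const arma::vec& x0) {
  const int n = W.n_rows;
  const int n_out = n_steps / thin + 1;
  arma::mat out(n, n_out);
  arma::vec x = x0, r(n), xi(n);
  out.col(0) = x;
  const double sq = sigma * std::sqrt(dt);
  int k = 1;
  for (int t = 0; t < n_steps; ++t) {
    for (int i = 0; i < n; ++i) {
      r(i) = 1.0 / (1.0 + std::exp(-alpha * x(i))) - 0.5;
      xi(i) = R::norm_rand();
    }
    x += dt * (W * r) + sq * xi;
    if (arma::abs(x).max() > 1e6)
      stop("trajectory diverged (|x| > 1e6 at t = %g s)", (t + 1) * dt);
    if ((t + 1) % thin == 0 && k < n_out) out.col(k++) = x;
  }
  return out.cols(0, k - 1);
}

// Leaky integrate-and-fire network with double-exponential synapses:
//   tau_m dV/dt = -V + W r + I_bias
//   dr/dt = -r/tau_d + h,  dh/dt = -h/tau_r + (1/(tau_d tau_r)) sum delta(t-t_k)
// Threshold/reset: V >= v_thres emits a spike and resets to v_reset.  The
// reported trace is the subthreshold voltage after reset bookkeeping,
// thinned to the output rate.  Spikes are returned as (neuron, time) pairs.
// [[Rcpp::export]]
List sim_lif_cpp(const arma::mat& W, double tau_m, double tau_d, double tau_r,
                 double v_thres, double v_reset, const arma::vec& i_bias,
                 double dt, int n_steps, int thin, const arma::vec& v0) {
  const int n = W.n_rows;
  const int n_out = n_steps / thin + 1;
  arma::mat V_out(n, n_out);
  arma::vec V = v0, r(n, arma::fill::zeros), h(n, arma::fill::zeros);
  std::vector<int> spk_id;
  std::vector<double> spk_t;
  V_out.col(0) = V;
  const double h_jump = 1.0 / (tau_d * tau_r);
  int k = 1;
  for (int t = 0; t < n_steps; ++t) {
    arma::vec syn = W * r;
    V += (dt / tau_m) * (-V + syn + i_bias);
    r += dt * (-r / tau_d + h);
    h += dt * (-h / tau_r);
    for (int i = 0; i < n; ++i) {
      if (V(i) >= v_thres) {
        spk_id.push_back(i + 1);
        spk_t.push_back((t + 1) * dt);
        V(i) = v_reset;
        h(i) += h_jump;
      }
    }
    if ((t + 1) % thin == 0 && k < n_out) V_out.col(k++) = V;
  }
  return List::create(Named("V") = V_out.cols(0, k - 1),
                      Named("spike_neuron") = wrap(spk_id),
                      Named("spike_time") = wrap(spk_t));
}

// Reduced Wong-Wang dynamic mean-field model:
//   dS_i = (-S_i/tau_s + (1 - S_i) gamma H(x_i)) dt + sigma sqrt(dt) xi
//   H(x) = (a x - b) / (1 - exp(-d (a x - b))),  continuous at a x = b
//   x_i = c J S_i + G J sum_j W_ij S_j + I0
// [[Rcpp::export]]
arma::mat sim_wong_wang_cpp(const arma::mat& W, double a, double b, double d,
                            double gamma_, double tau_s, double J, double G,
                            double c_local, double I0, double sigma,
                            double dt, int n_steps, int thin,
                            const arma::vec& S0) {
  const int n = W.n_rows;
  const int n_out = n_steps / thin + 1;
  arma::mat out(n, n_out);
  arma::vec S = S0, xi(n);
  out.col(0) = S;
  const double sq = sigma * std::sqrt(dt);
  int k = 1, bad_run = 0;
  for (int t = 0; t < n_steps; ++t) {
    arma::vec x = c_local * J * S + G * J * (W * S) + I0 * arma::ones(n);
    arma::vec H(n);
    for (int i = 0; i < n; ++i) {
      double u = a * x(i) - b;
      H(i) = (std::fabs(u) < 1e-9) ? 1.0 / d : u / (1.0 - std::exp(-d * u));
      xi(i) = R::norm_rand();
    }
    S += dt * (-S / tau_s + (1.0 - S) % (gamma_ * H)) + sq * xi;
    if (S.min() < -0.1 || S.max() > 1.1) {
      if (++bad_run > 100)
        stop("gating variable left [-0.1, 1.1] persistently; adjust coupling or noise");
    } else bad_run = 0;
    if ((t + 1) % thin == 0 && k < n_out) out.col(k++) = S;
  }
  return out.cols(0, k - 1);
}
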