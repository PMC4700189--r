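#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Uniform neuron pick in [0, N); uses R's RNG so set.seed() governs runs.
static inline int pick_neuron(int N) {
  int i = (int)(unif_rand() * N);
  return (i == N) ? N - 1 : i;
}

// One asynchronous micro-update at neuron i against the maintained field h.
// Returns true if the neuron flipped; h is updated with column i of T.
static inline bool micro_update(const NumericMatrix& T, std::vector<int>& v,
                                std::vector<double>& h,
                                const std::vector<double>& theta, int i) {
  const int N = T.nrow();
  const int nv = (h[i] > theta[i]) ? 1 : 0;
  if (nv == v[i]) return false;
  const double dv = nv ? 1.0 : -1.0;
  v[i] = nv;
  const double* col = &T(0, i);
  for (int r = 0; r < N; ++r) h[r] += dv * col[r];
  return true;
}

static std::vector<double> init_field(const NumericMatrix& T,
                                      const std::vector<int>& v) {
  const int N = T.nrow();
  std::vector<double> h(N, 0.0);
  for (int j = 0; j < N; ++j) {
    if (!v[j]) continue;
    const double* col = &T(0, j);
    for (int i = 0; i < N; ++i) h[i] += col[i];
  }
  return h;
}

// [[Rcpp::export]]
List cpp_async_relax(const NumericMatrix& T, const IntegerVector& v0,
                     const NumericVector& theta, int max_sweeps) {
  const int N = T.nrow();
  std::vector<int> v(v0.begin(), v0.end());
  std::vector<double> th(theta.begin(), theta.end());
  std::vector<double> h = init_field(T, v);
  bool converged = false;
  int sweep = 0;
  while (sweep < max_sweeps) {
    ++sweep;
    bool changed = false;
    for (int m = 0; m < N; ++m)
      if (micro_update(T, v, h, th, pick_neuron(N))) changed = true;
    if (!changed) {
      // random selection may have missed a neuron: confirm deterministically
      bool fixed = true;
      for (int i = 0; i < N; ++i)
        if (((h[i] > th[i]) ? 1 : 0) != v[i]) { fixed = false; break; }
      if (fixed) { converged = true; break; }
    }
  }
  return List::create(_["state"] = IntegerVector(v.begin(), v.end()),
                      _["sweeps"] = sweep, _["converged"] = converged);
}

// Asynchronous dynamics with sliding-window threshold accommodation.
// Per sweep: N random micro-updates against thresholds
//   theta_i = theta0 + dtheta * (# active sweeps of neuron i among the
//   last tau sweeps),
// then the activity window is advanced by one sweep.
// [[Rcpp::export]]
List cpp_accommodation_run(const NumericMatrix& T, const IntegerVector& v0,
                           int sweeps, double dtheta, int tau, double theta0,
                           bool record_thresholds) {
  const int N = T.nrow();
  std::vector<int> v(v0.begin(), v0.end());
  std::vector<double> th(N, theta0);
  std::vector<unsigned char> hist((size_t)tau * N, 0);
  std::vector<double> h = init_field(T, v);
  IntegerMatrix states(sweeps + 1, N);
  NumericMatrix thmat(record_thresholds ? sweeps + 1 : 1,
                      record_thresholds ? N : 1);
  for (int i = 0; i < N; ++i) states(0, i) = v[i];
  if (record_thresholds)
    for (int i = 0; i < N; ++i) thmat(0, i) = th[i];
  for (int s = 1; s <= sweeps; ++s) {
    for (int m = 0; m < N; ++m)
      micro_update(T, v, h, th, pick_neuron(N));
    const size_t slot = (size_t)(s % tau) * N;
    for (int r = 0; r < N; ++r) {
      th[r] += dtheta * (v[r] - (int)hist[slot + r]);
      hist[slot + r] = (unsigned char)v[r];
    }
    for (int i = 0; i < N; ++i) states(s, i) = v[i];
    if (record_thresholds)
      for (int i = 0; i < N; ++i) thmat(s, i) = th[i];
    if (s % 512 == 0) Rcpp::checkUserInterrupt();
  }
  List out = List::create(_["states"] = states);
  if (record_thresholds) out["thresholds"] = thmat;
  return out;
}

// Winner-take-L ("rank") dynamics with the same sliding-window fatigue:
// per sweep the L neurons with the largest (net input - threshold) are
// active; ties break to the lowest index.  Deterministic given the
// network and initial state.
// [[Rcpp::export]]
List cpp_rank_accommodation_run(const NumericMatrix& T,
                                const IntegerVector& v0, int L, int sweeps,
                                double dtheta, int tau, double theta0,
                                double score_noise,
                                bool record_thresholds) {
  const int N = T.nrow();
  std::vector<int> v(v0.begin(), v0.end());
  std::vector<double> th(N, theta0), score(N), h(N);
  std::vector<unsigned char> hist((size_t)tau * N, 0);
  std::vector<int> ord(N);
  IntegerMatrix states(sweeps + 1, N);
  NumericMatrix thmat(record_thresholds ? sweeps + 1 : 1,
                      record_thresholds ? N : 1);
  for (int i = 0; i < N; ++i) states(0, i) = v[i];
  if (record_thresholds)
    for (int i = 0; i < N; ++i) thmat(0, i) = th[i];
  for (int s = 1; s <= sweeps; ++s) {
    std::fill(h.begin(), h.end(), 0.0);
    for (int j = 0; j < N; ++j) {
      if (!v[j]) continue;
      const double* col = &T(0, j);
      for (int i = 0; i < N; ++i) h[i] += col[i];
    }
    for (int i = 0; i < N; ++i) {
      score[i] = h[i] - th[i];
      if (score_noise > 0) score[i] += score_noise * norm_rand();
      ord[i] = i;
    }
    std::partial_sort(ord.begin(), ord.begin() + L, ord.end(),
                      [&](int a, int b) {
                        return score[a] > score[b] ||
                               (score[a] == score[b] && a < b);
                      });
    std::fill(v.begin(), v.end(), 0);
    for (int r = 0; r < L; ++r) v[ord[r]] = 1;
    const size_t slot = (size_t)(s % tau) * N;
    for (int r = 0; r < N; ++r) {
      th[r] += dtheta * (v[r] - (int)hist[slot + r]);
      hist[slot + r] = (unsigned char)v[r];
    }
    for (int i = 0; i < N; ++i) states(s, i) = v[i];
    if (record_thresholds)
      for (int i = 0; i < N; ++i) thmat(s, i) = th[i];
    if (s % 512 == 0) Rcpp::checkUserInterrupt();
  }
  List out = List::create(_["states"] = states);
  if (record_thresholds) out["thresholds"] = thmat;
  return out;
}

// Winner-take-L relaxation by greedy swaps: repeatedly exchange the
// weakest active neuron for the strongest inactive one while that raises
// the summed drive.  Activity stays at exactly L; each swap strictly
// increases total input, so the descent terminates in a state where no
// single exchange improves (ties: no swap, lowest index wins the rank).
// [[Rcpp::export]]
List cpp_wtl_relax(const NumericMatrix& T, const IntegerVector& v0, int L,
                   int max_swaps) {
  const int N = T.nrow();
  std::vector<int> v(v0.begin(), v0.end());
  std::vector<double> h(N, 0.0);
  for (int j = 0; j < N; ++j) {
    if (!v[j]) continue;
    const double* col = &T(0, j);
    for (int i = 0; i < N; ++i) h[i] += col[i];
  }
  int swaps = 0;
  while (swaps < max_swaps) {
    int worst = -1, best = -1;
    double hw = R_PosInf, hb = R_NegInf;
    for (int i = 0; i < N; ++i) {
      if (v[i]) { if (h[i] < hw) { hw = h[i]; worst = i; } }
      else      { if (h[i] > hb) { hb = h[i]; best = i; } }
    }
    if (best < 0 || worst < 0) break;
    // set-energy gain of the exchange: the entrant's drive within the
    // new set (excluding the leaver) must beat the leaver's drive
    if (hb - T(best, worst) <= hw) break;
    v[worst] = 0; v[best] = 1;
    const double* cw = &T(0, worst);
    const double* cb = &T(0, best);
    for (int r = 0; r < N; ++r) h[r] += cb[r] - cw[r];
    ++swaps;
  }
  return List::create(_["state"] = IntegerVector(v.begin(), v.end()),
                      _["swaps"] = swaps);
}

// Leaky integrate-and-fire network with calcium-dependent adaptation and a
// lumped inhibitory pool.  Euler integration at fixed dt:
//   dv/dt = (-(v - v_rest) - g_ahp * Ca * (v - v_rest) + I_exc - w_inh * p) / tau_m
// plus Gaussian membrane noise of amplitude noise_amp * sqrt(dt).  On
// crossing v_thresh: spike, v <- v_reset, Ca <- Ca + delta_ca; Ca decays
// with tau_ca, the per-neuron excitatory drive with tau_syn, the pool p
// with tau_inh.  Each spike adds w_exc to the drive of its excitatory
// postsynaptic targets and 1 to the pool.
// [[Rcpp::export]]
List cpp_lif_simulate(const List& exc_post, double duration,
                      double tau_m, double v_rest, double v_thresh,
                      double v_reset, double tau_ca, double delta_ca,
                      double g_ahp, double w_exc, double w_inh,
                      double tau_syn, double tau_inh, double dt,
                      double noise_amp, double t_ref, double sample_dt,
                      const IntegerVector& init_bump, double init_drive,
                      double init_duration) {
  const int N = exc_post.size();
  std::vector< std::vector<int> > post(N);
  for (int i = 0; i < N; ++i) {
    IntegerVector pi = exc_post[i];
    post[i].assign(pi.begin(), pi.end());
  }
  std::vector<double> v(N, v_rest), ca(N, 0.0), syn(N, 0.0), ref_until(N, -1.0);
  std::vector<double> ext(N, 0.0);
  std::vector< std::vector<double> > spikes(N);
  for (int k = 0; k < init_bump.size(); ++k)
    ext[init_bump[k]] = init_drive;
  double p = 0.0;
  const int n_steps = (int)std::ceil(duration / dt);
  const int n_samp = (int)std::floor(duration / sample_dt) + 1;
  NumericMatrix vsamp(n_samp, N);
  NumericVector tsamp(n_samp);
  int samp = 0;
  const double f_syn = std::exp(-dt / tau_syn);
  const double f_inh = std::exp(-dt / tau_inh);
  const double f_ca = std::exp(-dt / tau_ca);
  const double sdt = std::sqrt(dt);
  for (int step = 0; step <= n_steps; ++step) {
    const double t = step * dt;
    if (samp < n_samp && t >= samp * sample_dt - 1e-12) {
      for (int i = 0; i < N; ++i) vsamp(samp, i) = v[i];
      tsamp[samp] = t;
      ++samp;
    }
    if (step == n_steps) break;
    for (int i = 0; i < N; ++i) {
      if (t < ref_until[i]) { v[i] = v_reset; continue; }
      double drive = -(v[i] - v_rest) * (1.0 + g_ahp * ca[i]) +
                     syn[i] - w_inh * p;
      if (t < init_duration) drive += ext[i];
      v[i] += dt * drive / tau_m + noise_amp * sdt * norm_rand();
    }
    for (int i = 0; i < N; ++i) {
      if (t >= ref_until[i] && v[i] >= v_thresh) {
        spikes[i].push_back(t + dt);
        v[i] = v_reset;
        ref_until[i] = t + dt + t_ref;
        ca[i] += delta_ca;
        for (size_t k = 0; k < post[i].size(); ++k) syn[post[i][k]] += w_exc;
        p += 1.0;
      }
      if (!std::isfinite(v[i]) || std::fabs(v[i]) > 1e4)
        stop("numerical instability: membrane potential diverged (reduce dt)");
    }
    for (int i = 0; i < N; ++i) { syn[i] *= f_syn; ca[i] *= f_ca; }
    p *= f_inh;
    if (step % 4096 == 0) Rcpp::checkUserInterrupt();
  }
  List sp(N);
  for (int i = 0; i < N; ++i)
    sp[i] = NumericVector(spikes[i].begin(), spikes[i].end());
  return List::create(_["spikes"] = sp, _["potentials"] = vsamp,
                      _["times"] = tsamp);
}
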