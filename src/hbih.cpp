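// Compiled core: HB + Ih vector field, fixed-step Euler integration of
// single neurons and gap-junction-coupled networks, two-trajectory maximal
// Lyapunov exponent estimation, and the windowed pairwise phase-agreement
// (functional connectivity) kernel.
//
// Parameter vectors follow the fixed column order defined in R/model.R
// (hbih_param_names). State order: V, a_r, a_sd, a_sr, a_h.

#include <Rcpp.h>
#include <cmath>
#include <random>
using namespace Rcpp;

static const int NPAR = 28;
enum par_idx {
  iCm, iT, igd, igr, igsd, igsr, igl, igh,
  iV0d, iV0r, iV0sd, iV0h,
  isd, isr, issd, ish,
  itaur, itausd, itausr, itauh,
  ieta, ikappa,
  iEd, iEr, iEsd, iEsr, iEl, iEh
};

static inline double sigm(double V, double s, double V0) {
  return 1.0 / (1.0 + std::exp(-s * (V - V0)));
}

// rho, phi: temperature factors, precomputed once per neuron.
static inline void hb_deriv(const double* x, const double* p,
                            double rho, double phi, double Isyn,
                            double* dx) {
  const double V = x[0], ar = x[1], asd = x[2], asr = x[3], ah = x[4];
  const double ad = sigm(V, p[isd], p[iV0d]);
  const double Id  = rho * p[igd]  * ad  * (V - p[iEd]);
  const double Ir  = rho * p[igr]  * ar  * (V - p[iEr]);
  const double Isd = rho * p[igsd] * asd * (V - p[iEsd]);
  const double Ih  = rho * p[igh]  * ah  * (V - p[iEh]);
  const double Il  = rho * p[igl]         * (V - p[iEl]);
  const double Isr = rho * p[igsr] * (asr * asr / (asr * asr + 0.16)) *
                     (V - p[iEsr]);
  dx[0] = (-Isd - Isr - Ih - Id - Ir - Il + Isyn) / p[iCm];
  dx[1] = phi * (sigm(V, p[isr],  p[iV0r])  - ar)  / p[itaur];
  dx[2] = phi * (sigm(V, p[issd], p[iV0sd]) - asd) / p[itausd];
  dx[3] = phi * (-p[ieta] * Isd - p[ikappa] * asr) / p[itausr];
  dx[4] = phi * (sigm(V, p[ish],  p[iV0h])  - ah)  / p[itauh];
}

static inline void temp_factors(const double* p, double& rho, double& phi) {
  rho = std::pow(1.3, (p[iT] - 25.0) / 10.0);
  phi = std::pow(3.0, (p[iT] - 25.0) / 10.0);
}

static void check_params(const NumericVector& p) {
  if (p.size() != NPAR) stop("parameter vector must have %d entries", NPAR);
}

// [[Rcpp::export]]
NumericVector hbih_deriv_cpp(NumericVector state, NumericVector params,
                             double Isyn) {
  check_params(params);
  if (state.size() != 5) stop("state must have 5 entries (V, a_r, a_sd, a_sr, a_h)");
  for (int i = 0; i < 5; ++i)
    if (!R_finite(state[i])) stop("non-finite state: numerical blow-up");
  double rho, phi;
  temp_factors(params.begin(), rho, phi);
  NumericVector dx(5);
  hb_deriv(state.begin(), params.begin(), rho, phi, Isyn, dx.begin());
  return dx;
}

// [[Rcpp::export]]
NumericVector hbih_currents_cpp(NumericVector state, NumericVector params) {
  check_params(params);
  const double* p = params.begin();
  double rho, phi;
  temp_factors(p, rho, phi);
  const double V = state[0], ar = state[1], asd = state[2],
               asr = state[3], ah = state[4];
  const double ad = sigm(V, p[isd], p[iV0d]);
  NumericVector out = NumericVector::create(
    _["I_d"]  = rho * p[igd]  * ad  * (V - p[iEd]),
    _["I_r"]  = rho * p[igr]  * ar  * (V - p[iEr]),
    _["I_sd"] = rho * p[igsd] * asd * (V - p[iEsd]),
    _["I_sr"] = rho * p[igsr] * (asr * asr / (asr * asr + 0.16)) * (V - p[iEsr]),
    _["I_h"]  = rho * p[igh]  * ah  * (V - p[iEh]),
    _["I_l"]  = rho * p[igl]  * (V - p[iEl]));
  return out;
}

static inline void step_check(double V, long step) {
  if (!R_finite(V) || std::fabs(V) > 500.0)
    stop("simulation diverged (|V| > 500 mV or non-finite) at step %ld", step);
}

// [[Rcpp::export]]
List hbih_integrate_cpp(NumericVector params, NumericVector state0,
                        double dt, double t_transient, double t_record,
                        int stride) {
  check_params(params);
  if (dt <= 0) stop("dt must be > 0");
  if (stride < 1) stop("stride must be >= 1");
  const double* p = params.begin();
  double rho, phi;
  temp_factors(p, rho, phi);
  double x[5], dx[5];
  for (int i = 0; i < 5; ++i) x[i] = state0[i];

  const long n_trans = (long)std::floor(t_transient / dt + 0.5);
  const long n_rec   = (long)std::floor(t_record / dt + 0.5);
  const long n_out   = n_rec / stride + 1;
  NumericVector V_out(n_out);

  for (long s = 0; s < n_trans; ++s) {
    hb_deriv(x, p, rho, phi, 0.0, dx);
    for (int i = 0; i < 5; ++i) x[i] += dt * dx[i];
    step_check(x[0], s);
  }
  long k = 0;
  for (long s = 0; s <= n_rec; ++s) {
    if (s % stride == 0 && k < n_out) V_out[k++] = x[0];
    hb_deriv(x, p, rho, phi, 0.0, dx);
    for (int i = 0; i < 5; ++i) x[i] += dt * dx[i];
    step_check(x[0], n_trans + s);
  }
  NumericVector xf(5);
  for (int i = 0; i < 5; ++i) xf[i] = x[i];
  return List::create(_["V"] = V_out, _["final_state"] = xf);
}

// Gap-junction input currents for one voltage configuration:
// Isyn[k] = g * sum_l C_kl (V_l - V_k), edges listed once (undirected).
static inline void gap_currents(const double* V, const int* ek, const int* el,
                                int n_edges, double g, double* Isyn, int N) {
  for (int k = 0; k < N; ++k) Isyn[k] = 0.0;
  for (int e = 0; e < n_edges; ++e) {
    const int a = ek[e], b = el[e];
    const double d = g * (V[b] - V[a]);
    Isyn[a] += d;
    Isyn[b] -= d;
  }
}

// [[Rcpp::export]]
NumericVector network_isyn_cpp(NumericVector V, IntegerMatrix edges, double g) {
  const int N = V.size(), E = edges.nrow();
  NumericVector Isyn(N);
  std::vector<int> ek(E), el(E);
  for (int e = 0; e < E; ++e) { ek[e] = edges(e, 0); el[e] = edges(e, 1); }
  gap_currents(V.begin(), ek.data(), el.data(), E, g, Isyn.begin(), N);
  return Isyn;
}

struct NetWork {
  int N;
  std::vector<double> par;     // N x NPAR, row-major per neuron
  std::vector<double> rho, phi;
  std::vector<int> ek, el;
  double g;

  void rhs(const double* x, double* dx, std::vector<double>& Vbuf,
           std::vector<double>& Ibuf) const {
    for (int k = 0; k < N; ++k) Vbuf[k] = x[5 * k];
    gap_currents(Vbuf.data(), ek.data(), el.data(), (int)ek.size(), g,
                 Ibuf.data(), N);
    for (int k = 0; k < N; ++k)
      hb_deriv(x + 5 * k, par.data() + NPAR * k, rho[k], phi[k], Ibuf[k],
               dx + 5 * k);
  }
};

static NetWork make_network(const NumericMatrix& params,
                            const IntegerMatrix& edges, double g) {
  NetWork net;
  net.N = params.nrow();
  if (params.ncol() != NPAR) stop("params must have %d columns", NPAR);
  net.par.resize((size_t)net.N * NPAR);
  net.rho.resize(net.N);
  net.phi.resize(net.N);
  for (int k = 0; k < net.N; ++k) {
    for (int j = 0; j < NPAR; ++j) net.par[(size_t)NPAR * k + j] = params(k, j);
    temp_factors(net.par.data() + (size_t)NPAR * k, net.rho[k], net.phi[k]);
  }
  const int E = edges.nrow();
  net.ek.resize(E);
  net.el.resize(E);
  for (int e = 0; e < E; ++e) {
    net.ek[e] = edges(e, 0);
    net.el[e] = edges(e, 1);
    if (net.ek[e] < 0 || net.ek[e] >= net.N || net.el[e] < 0 || net.el[e] >= net.N)
      stop("edge index out of range");
  }
  net.g = g;
  return net;
}

// [[Rcpp::export]]
List hbih_network_integrate_cpp(NumericMatrix params, IntegerMatrix edges,
                                double g, NumericMatrix state0, double dt,
                                double t_transient, double t_record,
                                int stride) {
  if (dt <= 0) stop("dt must be > 0");
  if (stride < 1) stop("stride must be >= 1");
  NetWork net = make_network(params, edges, g);
  const int N = net.N;
  if (state0.nrow() != N || state0.ncol() != 5)
    stop("state0 must be N x 5");
  std::vector<double> x((size_t)5 * N), dx((size_t)5 * N), Vbuf(N), Ibuf(N);
  for (int k = 0; k < N; ++k)
    for (int i = 0; i < 5; ++i) x[5 * k + i] = state0(k, i);

  const long n_trans = (long)std::floor(t_transient / dt + 0.5);
  const long n_rec   = (long)std::floor(t_record / dt + 0.5);
  const long n_out   = n_rec / stride + 1;
  NumericMatrix V_out(n_out, N);

  for (long s = 0; s < n_trans; ++s) {
    net.rhs(x.data(), dx.data(), Vbuf, Ibuf);
    for (size_t i = 0; i < x.size(); ++i) x[i] += dt * dx[i];
    step_check(x[0], s);
  }
  long row = 0;
  for (long s = 0; s <= n_rec; ++s) {
    if (s % stride == 0 && row < n_out) {
      for (int k = 0; k < N; ++k) V_out(row, k) = x[5 * k];
      ++row;
    }
    net.rhs(x.data(), dx.data(), Vbuf, Ibuf);
    for (size_t i = 0; i < x.size(); ++i) x[i] += dt * dx[i];
    for (int k = 0; k < N; ++k) step_check(x[5 * k], n_trans + s);
  }
  NumericMatrix xf(N, 5);
  for (int k = 0; k < N; ++k)
    for (int i = 0; i < 5; ++i) xf(k, i) = x[5 * k + i];
  return List::create(_["V"] = V_out, _["final_state"] = xf);
}

// Two-trajectory MLE with periodic renormalization (Sprott/Benettin style).
// Returns the per-interval log expansion ratios; averaging, transient
// discard within the ratio sequence and convergence checks live in R.
template <typename RHS>
static List mle_core(RHS rhs, std::vector<double>& x, int dim, double d0,
                     double dt, double t_transient, double t_average,
                     double renorm_ms, unsigned int seed) {
  if (d0 <= 0) stop("d0 must be > 0");
  std::mt19937 rng(seed);
  std::normal_distribution<double> gauss(0.0, 1.0);

  const long n_trans = (long)std::floor(t_transient / dt + 0.5);
  const long n_sub   = std::max(1L, (long)std::floor(renorm_ms / dt + 0.5));
  const long n_int   = (long)std::floor(t_average / (n_sub * dt) + 0.5);

  std::vector<double> dx(dim), y(dim), dy(dim);
  for (long s = 0; s < n_trans; ++s) {
    rhs(x.data(), dx.data());
    for (int i = 0; i < dim; ++i) x[i] += dt * dx[i];
    step_check(x[0], s);
  }
  auto perturb = [&]() {
    double nrm = 0.0;
    std::vector<double> u(dim);
    do {
      nrm = 0.0;
      for (int i = 0; i < dim; ++i) { u[i] = gauss(rng); nrm += u[i] * u[i]; }
      nrm = std::sqrt(nrm);
    } while (nrm == 0.0);
    for (int i = 0; i < dim; ++i) y[i] = x[i] + d0 * u[i] / nrm;
  };
  perturb();

  NumericVector logr(n_int);
  int n_reperturb = 0;
  const double dt_renorm = n_sub * dt;
  for (long m = 0; m < n_int; ++m) {
    for (long s = 0; s < n_sub; ++s) {
      rhs(x.data(), dx.data());
      rhs(y.data(), dy.data());
      for (int i = 0; i < dim; ++i) { x[i] += dt * dx[i]; y[i] += dt * dy[i]; }
      step_check(x[0], m * n_sub + s);
      step_check(y[0], m * n_sub + s);
    }
    double d = 0.0;
    for (int i = 0; i < dim; ++i) d += (y[i] - x[i]) * (y[i] - x[i]);
    d = std::sqrt(d);
    if (d == 0.0) {
      perturb();
      ++n_reperturb;
      logr[m] = NA_REAL;
      continue;
    }
    logr[m] = std::log(d / d0);
    const double f = d0 / d;
    for (int i = 0; i < dim; ++i) y[i] = x[i] + (y[i] - x[i]) * f;
  }
  return List::create(_["log_ratios"] = logr,
                      _["dt_renorm"] = dt_renorm,
                      _["n_reperturb"] = n_reperturb);
}

// [[Rcpp::export]]
List hbih_mle_cpp(NumericVector params, NumericVector state0, double d0,
                  double dt, double t_transient, double t_average,
                  double renorm_ms, int seed) {
  check_params(params);
  const double* p = params.begin();
  double rho, phi;
  temp_factors(p, rho, phi);
  std::vector<double> x(5);
  for (int i = 0; i < 5; ++i) x[i] = state0[i];
  auto rhs = [&](const double* xx, double* dd) {
    hb_deriv(xx, p, rho, phi, 0.0, dd);
  };
  return mle_core(rhs, x, 5, d0, dt, t_transient, t_average, renorm_ms,
                  (unsigned int)seed);
}

// [[Rcpp::export]]
List hbih_network_mle_cpp(NumericMatrix params, IntegerMatrix edges, double g,
                          NumericMatrix state0, double d0, double dt,
                          double t_transient, double t_average,
                          double renorm_ms, int seed) {
  NetWork net = make_network(params, edges, g);
  const int N = net.N;
  std::vector<double> x((size_t)5 * N), Vbuf(N), Ibuf(N);
  for (int k = 0; k < N; ++k)
    for (int i = 0; i < 5; ++i) x[5 * k + i] = state0(k, i);
  auto rhs = [&](const double* xx, double* dd) {
    net.rhs(xx, dd, Vbuf, Ibuf);
  };
  return mle_core(rhs, x, 5 * N, d0, dt, t_transient, t_average, renorm_ms,
                  (unsigned int)seed);
}

// FC_{k,l}(window) = mean_t |cos((phi_k - phi_l)/2)|, the time-averaged
// modulus of the mean pair phasor. phases: T x N matrix; starts are 0-based
// window start rows; all windows have `width` rows.
// [[Rcpp::export]]
NumericVector fc_windows_cpp(NumericMatrix phases, IntegerVector starts,
                             int width) {
  const int Tn = phases.nrow(), N = phases.ncol(), M = starts.size();
  if (width < 1) stop("width must be >= 1");
  NumericVector out((size_t)N * N * M);
  out.attr("dim") = IntegerVector::create(N, N, M);
  for (int m = 0; m < M; ++m) {
    const int s0 = starts[m];
    if (s0 < 0 || s0 + width > Tn) stop("window out of range");
    double* fc = out.begin() + (size_t)m * N * N;
    for (int k = 0; k < N; ++k) {
      fc[k * N + k] = 1.0;
      for (int l = k + 1; l < N; ++l) {
        double acc = 0.0;
        for (int t = s0; t < s0 + width; ++t)
          acc += std::fabs(std::cos(0.5 * (phases(t, k) - phases(t, l))));
        const double v = acc / width;
        fc[k * N + l] = v;
        fc[l * N + k] = v;
      }
    }
  }
  return out;
}
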