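#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Activity-based population network:
//   C dV/dt = -INaP - IL - ISynE - ISynI - INoise   (rhythm-generator centers)
//   C dV/dt =        - IL - ISynE - ISynI - INoise  (all other populations)
//   tau_h(V) dh/dt = h_inf(V) - h                   (RG centers only)
// Synaptic input sums use the piecewise-linear population output f(V) and
// half-rectified signed weights; deleted populations contribute zero output.
//
// The noisy current is an Ornstein-Uhlenbeck process discretized exactly on a
// fixed 1 ms grid and held constant within each grid cell, so the adaptive
// solver always integrates a smooth right-hand side; steps never straddle a
// grid boundary.

struct CpgSystem {
  int n_pop, n_rg;
  // excitatory / inhibitory edge lists (post-rectification)
  std::vector<int> esrc, edst, isrc, idst;
  std::vector<double> ew, iw;
  std::vector<double> Cm, gL, EL, DE, DI;
  std::vector<bool> deleted;
  std::vector<int> rg_idx;           // positions of INaP-carrying populations
  std::vector<int> rg_slot;          // n_pop-long, -1 or index into h block
  // constants
  double gSynE, gSynI, ESynE, ESynI, ENa, Vthr, Vmax;
  double gNaP, V12m, km, V12h, kh, V12tau, ktau, tau0, taumax;

  double fout(double V) const {
    if (V < Vthr) return 0.0;
    if (V >= Vmax) return 1.0;
    return (V - Vthr) / (Vmax - Vthr);
  }

  // y = [V (n_pop), h (n_rg)]; noise = per-population current (pA)
  void rhs(const std::vector<double>& y, const std::vector<double>& noise,
           std::vector<double>& dy, std::vector<double>& act,
           std::vector<double>& sumE, std::vector<double>& sumI) const {
    for (int j = 0; j < n_pop; ++j)
      act[j] = deleted[j] ? 0.0 : fout(y[j]);
    for (int i = 0; i < n_pop; ++i) { sumE[i] = DE[i]; sumI[i] = DI[i]; }
    for (size_t e = 0; e < esrc.size(); ++e) sumE[edst[e]] += ew[e] * act[esrc[e]];
    for (size_t e = 0; e < isrc.size(); ++e) sumI[idst[e]] += iw[e] * act[isrc[e]];
    for (int i = 0; i < n_pop; ++i) {
      double V = y[i];
      double I = gL[i] * (V - EL[i])
               + gSynE * sumE[i] * (V - ESynE)
               + gSynI * sumI[i] * (V - ESynI)
               + noise[i];
      int s = rg_slot[i];
      if (s >= 0) {
        double h = y[n_pop + s];
        double minf = 1.0 / (1.0 + std::exp((V - V12m) / km));
        I += gNaP * minf * h * (V - ENa);
        double hinf = 1.0 / (1.0 + std::exp((V - V12h) / kh));
        double tauh = tau0 + (taumax - tau0) / std::cosh((V - V12tau) / ktau);
        dy[n_pop + s] = (hinf - h) / tauh;
      }
      dy[i] = -I / Cm[i];
    }
  }
};

// Dormand-Prince 5(4) tableau
static const double c2 = 1.0 / 5, c3 = 3.0 / 10, c4 = 4.0 / 5, c5 = 8.0 / 9;
static const double a21 = 1.0 / 5;
static const double a31 = 3.0 / 40, a32 = 9.0 / 40;
static const double a41 = 44.0 / 45, a42 = -56.0 / 15, a43 = 32.0 / 9;
static const double a51 = 19372.0 / 6561, a52 = -25360.0 / 2187,
                    a53 = 64448.0 / 6561, a54 = -212.0 / 729;
static const double a61 = 9017.0 / 3168, a62 = -355.0 / 33, a63 = 46732.0 / 5247,
                    a64 = 49.0 / 176, a65 = -5103.0 / 18656;
static const double b1 = 35.0 / 384, b3 = 500.0 / 1113, b4 = 125.0 / 192,
                    b5 = -2187.0 / 6784, b6 = 11.0 / 84;
static const double e1 = 71.0 / 57600, e3 = -71.0 / 16695, e4 = 71.0 / 1920,
                    e5 = -17253.0 / 339200, e6 = 22.0 / 525, e7 = -1.0 / 40;

// Integrate one smooth span [t0, t0+span] (noise constant), adapting dt.
static void integrate_span(const CpgSystem& sys, std::vector<double>& y,
                           const std::vector<double>& noise, double span,
                           double rel_tol, double abs_tol, double& dt_next,
                           double t0_report) {
  const int n = (int)y.size();
  std::vector<double> k1(n), k2(n), k3(n), k4(n), k5(n), k6(n), k7(n),
      ytmp(n), ynew(n), act(sys.n_pop), sumE(sys.n_pop), sumI(sys.n_pop);
  double t = 0.0;
  double dt = std::min(dt_next, span);
  int guard = 0;
  while (t < span - 1e-12) {
    if (++guard > 100000)
      stop("step-size underflow near t = %f ms", t0_report + t);
    if (dt > span - t) dt = span - t;
    sys.rhs(y, noise, k1, act, sumE, sumI);
    for (int i = 0; i < n; ++i) ytmp[i] = y[i] + dt * a21 * k1[i];
    sys.rhs(ytmp, noise, k2, act, sumE, sumI);
    for (int i = 0; i < n; ++i) ytmp[i] = y[i] + dt * (a31 * k1[i] + a32 * k2[i]);
    sys.rhs(ytmp, noise, k3, act, sumE, sumI);
    for (int i = 0; i < n; ++i)
      ytmp[i] = y[i] + dt * (a41 * k1[i] + a42 * k2[i] + a43 * k3[i]);
    sys.rhs(ytmp, noise, k4, act, sumE, sumI);
    for (int i = 0; i < n; ++i)
      ytmp[i] = y[i] + dt * (a51 * k1[i] + a52 * k2[i] + a53 * k3[i] + a54 * k4[i]);
    sys.rhs(ytmp, noise, k5, act, sumE, sumI);
    for (int i = 0; i < n; ++i)
      ytmp[i] = y[i] + dt * (a61 * k1[i] + a62 * k2[i] + a63 * k3[i] +
                             a64 * k4[i] + a65 * k5[i]);
    sys.rhs(ytmp, noise, k6, act, sumE, sumI);
    for (int i = 0; i < n; ++i)
      ynew[i] = y[i] + dt * (b1 * k1[i] + b3 * k3[i] + b4 * k4[i] +
                             b5 * k5[i] + b6 * k6[i]);
    sys.rhs(ynew, noise, k7, act, sumE, sumI);
    double err = 0.0;
    for (int i = 0; i < n; ++i) {
      double ei = dt * (e1 * k1[i] + e3 * k3[i] + e4 * k4[i] + e5 * k5[i] +
                        e6 * k6[i] + e7 * k7[i]);
      double sc = abs_tol + rel_tol * std::max(std::fabs(y[i]), std::fabs(ynew[i]));
      double r = ei / sc;
      err += r * r;
    }
    err = std::sqrt(err / n);
    if (err <= 1.0) {
      t += dt;
      y = ynew;
      if (!std::isfinite(y[0]))
        stop("non-finite state near t = %f ms", t0_report + t);
      double fac = (err == 0.0) ? 5.0 : 0.9 * std::pow(err, -0.2);
      dt *= std::min(5.0, std::max(0.2, fac));
    } else {
      dt *= std::max(0.2, 0.9 * std::pow(err, -0.2));
      if (dt < 1e-10)
        stop("step-size underflow (dt < 1e-10 ms) near t = %f ms", t0_report + t);
    }
  }
  dt_next = dt;
}

// [[Rcpp::export]]
List cpg_integrate_cpp(IntegerVector edge_src, IntegerVector edge_dst,
                       NumericVector edge_w, NumericVector Cm, NumericVector gL,
                       NumericVector EL, NumericVector DE, NumericVector DI,
                       LogicalVector deleted, IntegerVector rg_idx, List cst,
                       double duration, double record_every, NumericVector V0,
                       NumericVector h0, NumericVector noise0, double noise_sd,
                       double rel_tol, double abs_tol, IntegerVector record_idx) {
  CpgSystem sys;
  sys.n_pop = V0.size();
  sys.n_rg = rg_idx.size();
  for (int e = 0; e < edge_w.size(); ++e) {
    double w = edge_w[e];
    if (w >= 0) {
      sys.esrc.push_back(edge_src[e]); sys.edst.push_back(edge_dst[e]);
      sys.ew.push_back(w);
    } else {
      sys.isrc.push_back(edge_src[e]); sys.idst.push_back(edge_dst[e]);
      sys.iw.push_back(-w);
    }
  }
  sys.Cm = as<std::vector<double> >(Cm);
  sys.gL = as<std::vector<double> >(gL);
  sys.EL = as<std::vector<double> >(EL);
  sys.DE = as<std::vector<double> >(DE);
  sys.DI = as<std::vector<double> >(DI);
  sys.deleted.assign(deleted.begin(), deleted.end());
  sys.rg_idx = as<std::vector<int> >(rg_idx);
  sys.rg_slot.assign(sys.n_pop, -1);
  for (int s = 0; s < sys.n_rg; ++s) sys.rg_slot[sys.rg_idx[s]] = s;
  sys.gSynE = cst["gSynE"]; sys.gSynI = cst["gSynI"];
  sys.ESynE = cst["ESynE"]; sys.ESynI = cst["ESynI"];
  sys.ENa = cst["ENa"]; sys.Vthr = cst["Vthr"]; sys.Vmax = cst["Vmax"];
  sys.gNaP = cst["gNaP"]; sys.V12m = cst["V12m"]; sys.km = cst["km"];
  sys.V12h = cst["V12h"]; sys.kh = cst["kh"]; sys.V12tau = cst["V12tau"];
  sys.ktau = cst["ktau"]; sys.tau0 = cst["tau0"]; sys.taumax = cst["taumax"];
  const double grid_dt = 1.0;                 // ms, noise/recording grid
  const double tau_noise = cst["tauNoise"];

  int n_cells = (int)std::ceil(duration / grid_dt - 1e-9);
  int rec_stride = std::max(1, (int)std::lround(record_every / grid_dt));
  int n_rec_t = 1 + n_cells / rec_stride;
  int n_rec_pop = record_idx.size();

  NumericVector t_out(n_rec_t);
  NumericMatrix V_out(n_rec_t, n_rec_pop), h_out(n_rec_t, sys.n_rg);

  std::vector<double> y(sys.n_pop + sys.n_rg);
  for (int i = 0; i < sys.n_pop; ++i) y[i] = V0[i];
  for (int s = 0; s < sys.n_rg; ++s) y[sys.n_pop + s] = h0[s];
  std::vector<double> noise = as<std::vector<double> >(noise0);

  int r = 0;
  t_out[r] = 0.0;
  for (int j = 0; j < n_rec_pop; ++j) V_out(r, j) = y[record_idx[j]];
  for (int s = 0; s < sys.n_rg; ++s) h_out(r, s) = y[sys.n_pop + s];
  ++r;

  const double kee = std::exp(-grid_dt / tau_noise);
  const double ksd = noise_sd * std::sqrt(1.0 - kee * kee);
  double dt_next = 0.1;
  for (int cell = 0; cell < n_cells; ++cell) {
    double t0 = cell * grid_dt;
    double span = std::min(grid_dt, duration - t0);
    integrate_span(sys, y, noise, span, rel_tol, abs_tol, dt_next, t0);
    if (noise_sd > 0.0)
      for (int i = 0; i < sys.n_pop; ++i)
        noise[i] = noise[i] * kee + ksd * norm_rand();
    if ((cell + 1) % rec_stride == 0 && r < n_rec_t) {
      t_out[r] = t0 + span;
      for (int j = 0; j < n_rec_pop; ++j) V_out(r, j) = y[record_idx[j]];
      for (int s = 0; s < sys.n_rg; ++s) h_out(r, s) = y[sys.n_pop + s];
      ++r;
    }
    if (cell % 5000 == 0) checkUserInterrupt();
  }
  if (r < n_rec_t) {                      // duration not a multiple of stride
    t_out[r] = duration;
    for (int j = 0; j < n_rec_pop; ++j) V_out(r, j) = y[record_idx[j]];
    for (int s = 0; s < sys.n_rg; ++s) h_out(r, s) = y[sys.n_pop + s];
    ++r;
  }
  if (r < n_rec_t) {
    t_out = head(t_out, r);
    V_out = V_out(Range(0, r - 1), _);
    h_out = h_out(Range(0, r - 1), _);
  }

  NumericVector Vf(sys.n_pop), hf(sys.n_rg), nf(sys.n_pop);
  for (int i = 0; i < sys.n_pop; ++i) { Vf[i] = y[i]; nf[i] = noise[i]; }
  for (int s = 0; s < sys.n_rg; ++s) hf[s] = y[sys.n_pop + s];
  return List::create(_["t"] = t_out, _["V"] = V_out, _["h"] = h_out,
                      _["V_final"] = Vf, _["h_final"] = hf,
                      _["noise_final"] = nf);
}
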