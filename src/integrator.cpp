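// Fixed-step RK4 integration of the 7-dimensional voltage/ion system.
// State layout: y = (V, m, n, h, K_o, Na_i, Cl_i).
// Units: t ms, V mV, concentrations mM, conductances mS/cm^2,
// currents uA/cm^2, fluxes mM/s (divided by tau_ion to the ms base).

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

struct Pars {
  double C, gNa, gK, gNaL, gKL, gClL, gamma, rho, Ukcc2, Unkcc1,
    epsk, Kbath, beta, Ehco3, rhco3, nernst, tau, gsign,
    ktot, naob, clob, nair, clir;
};

static Pars unpack_pars(const NumericVector& p) {
  Pars q;
  q.C = p[0]; q.gNa = p[1]; q.gK = p[2]; q.gNaL = p[3]; q.gKL = p[4];
  q.gClL = p[5]; q.gamma = p[6]; q.rho = p[7]; q.Ukcc2 = p[8];
  q.Unkcc1 = p[9]; q.epsk = p[10]; q.Kbath = p[11]; q.beta = p[12];
  q.Ehco3 = p[13]; q.rhco3 = p[14]; q.nernst = p[15]; q.tau = p[16];
  q.gsign = p[17]; q.ktot = p[18]; q.naob = p[19]; q.clob = p[20];
  q.nair = p[21]; q.clir = p[22];
  return q;
}

struct Stim {
  int type;              // 0 none, 1 step, 2 spike train
  double g, t0, t1;      // step conductance and window
  double a0, tau1, tau2; // kernel amplitude and time constants
  double period;         // inter-spike interval (ms)
  int form;              // 0 sum kernel, 1 difference kernel
};

static Stim unpack_stim(const NumericVector& s) {
  Stim st;
  st.type = (int)s[0]; st.g = s[1]; st.t0 = s[2]; st.t1 = s[3];
  st.a0 = s[4]; st.tau1 = s[5]; st.tau2 = s[6]; st.period = s[7];
  st.form = (int)s[8];
  if (st.type == 1 && st.g == 0.0) st.type = 0;
  if (st.type == 2 && st.a0 == 0.0) st.type = 0;
  return st;
}

static inline double g_gaba_at(double t, const Stim& st) {
  if (st.type == 0) return 0.0;
  if (st.type == 1)
    return (t >= st.t0 && t <= st.t1) ? st.g : 0.0;
  // spike train: regular spikes at t0 + k*period while <= t1
  if (t < st.t0) return 0.0;
  double cutoff = 40.0 * st.tau1; // kernel negligible beyond this
  double tlast = std::min(t, st.t1);
  long kmax = (long)std::floor((tlast - st.t0) / st.period);
  long kmin = 0;
  if (t - st.t0 > cutoff)
    kmin = (long)std::ceil((t - cutoff - st.t0) / st.period);
  double sgn = (st.form == 0) ? 1.0 : -1.0;
  double g = 0.0;
  for (long k = kmin; k <= kmax; ++k) {
    double d = t - (st.t0 + k * st.period);
    if (d < 0) continue;
    g += std::exp(-d / st.tau1) + sgn * std::exp(-d / st.tau2);
  }
  return st.a0 * g;
}

static inline double vtrap(double x, double y) {
  if (std::fabs(x) < 1e-6) return y + 0.5 * x;
  return x / (1.0 - std::exp(-x / y));
}

// Returns false on a domain violation (non-positive concentration in a log).
static inline bool deriv(double t, const double* y, const Pars& p,
                         const Stim& st, double* dy) {
  const double V = y[0], m = y[1], n = y[2], h = y[3];
  const double Ko = y[4], Nai = y[5], Cli = y[6];

  const double Ki  = p.ktot - Nai + Cli;
  const double Nao = p.naob - p.beta * (Nai - p.nair);
  const double Clo = p.clob - p.beta * (Cli - p.clir);
  if (Ki <= 0 || Nao <= 0 || Clo <= 0 || Ko <= 0 || Nai <= 0 || Cli <= 0)
    return false;

  const double ENa = p.nernst * std::log(Nao / Nai);
  const double EK  = p.nernst * std::log(Ko / Ki);
  const double ECl = p.nernst * std::log(Cli / Clo);

  const double gg = g_gaba_at(t, st);

  const double INa  = p.gNa * m * m * m * h * (V - ENa);
  const double IK   = p.gK * n * n * n * n * (V - EK);
  const double INaL = p.gNaL * (V - ENa);
  const double IKL  = p.gKL * (V - EK);
  const double IClL = p.gClL * (V - ECl);
  const double rpump = p.rho / (1.0 + std::exp((25.0 - Nai) / 3.0)) /
    (1.0 + std::exp(3.5 - Ko));
  const double Ipump = rpump / p.gamma;
  const double Igcl = gg * (V - ECl);
  const double Ighco3 = p.rhco3 * gg * (V - p.Ehco3);

  dy[0] = (-IK - INa - IKL - INaL - IClL - Ipump +
           p.gsign * (Igcl + Ighco3)) / p.C;

  const double am = 0.32 * vtrap(V + 54.0, 4.0);
  const double bm = 0.28 * vtrap(-(V + 27.0), 5.0);
  const double ah = 0.128 * std::exp(-(V + 50.0) / 18.0);
  const double bh = 4.0 / (1.0 + std::exp(-(V + 27.0) / 5.0));
  const double an = 0.032 * vtrap(V + 52.0, 5.0);
  const double bn = 0.5 * std::exp(-(V + 57.0) / 40.0);
  dy[1] = am * (1.0 - m) - bm * m;
  dy[2] = an * (1.0 - n) - bn * n;
  dy[3] = ah * (1.0 - h) - bh * h;

  const double fKo = 1.0 / (1.0 + std::exp(16.0 - Ko));
  const double rkcc2 = p.Ukcc2 * std::log((Ki * Cli) / (Ko * Clo));
  const double rnkcc1 = p.Unkcc1 * fKo *
    (std::log((Ko * Clo) / (Ki * Cli)) + std::log((Nao * Clo) / (Nai * Cli)));

  dy[4] = (p.gamma * (IK + IKL) - 2.0 * rpump - rnkcc1 + rkcc2 -
           p.epsk * (Ko - p.Kbath)) / p.tau;
  dy[5] = (-p.gamma * (INa + INaL) - 3.0 * rpump + rnkcc1) / p.tau;
  dy[6] = (p.gamma * (IClL + Igcl) + 2.0 * rnkcc1 - rkcc2) / p.tau;
  return true;
}

// [[Rcpp::export]]
double g_at_cpp(double t, NumericVector stim) {
  return g_gaba_at(t, unpack_stim(stim));
}

// [[Rcpp::export]]
NumericVector rhs_cpp(double t, NumericVector y, NumericVector pars,
                      NumericVector stim) {
  Pars p = unpack_pars(pars);
  Stim st = unpack_stim(stim);
  double dy[7];
  if (!deriv(t, REAL(y), p, st, dy))
    stop("domain violation: non-positive concentration at t = %f", t);
  NumericVector out(7);
  for (int i = 0; i < 7; ++i) out[i] = dy[i];
  return out;
}

// Fixed-step RK4 with on-the-fly spike detection (upward threshold crossing
// with refractory separation, on the undecimated voltage stream), optional
// convergence-window early exit, and optional stop after a spike budget.
//
// status: 0 ran to t_end, 1 converged (all state variables varied less than
// tol over a window_ms window with no spikes in it), 2 domain violation,
// 3 spike budget reached.
// [[Rcpp::export]]
List integrate_cpp(NumericVector y0, NumericVector pars, NumericVector stim,
                   double t0, double t_end, double dt, int record_every,
                   double spike_thresh, double refractory,
                   bool stop_on_converged, double window_ms, double tol,
                   int max_spikes) {
  Pars p = unpack_pars(pars);
  Stim st = unpack_stim(stim);

  const long nstep = (long)std::ceil((t_end - t0) / dt - 1e-9);
  const long nrec_max = nstep / record_every + 3;
  NumericVector trec(nrec_max);
  NumericMatrix yrec(nrec_max, 7);
  NumericVector grec(nrec_max);
  std::vector<double> spikes;

  double y[7], k1[7], k2[7], k3[7], k4[7], ytmp[7];
  for (int i = 0; i < 7; ++i) y[i] = y0[i];

  long irec = 0;
  trec[0] = t0;
  for (int i = 0; i < 7; ++i) yrec(0, i) = y[i];
  grec[0] = g_gaba_at(t0, st);
  irec = 1;

  double t = t0;
  double last_spike = -1e300;
  int status = 0;
  double wlo[7], whi[7];
  for (int i = 0; i < 7; ++i) { wlo[i] = y[i]; whi[i] = y[i]; }
  double wstart = t0;
  long wspikes0 = 0;
  bool ok = true;

  for (long s = 0; s < nstep; ++s) {
    double hdt = dt;
    if (t + dt > t_end) hdt = t_end - t;
    double Vprev = y[0];

    ok = deriv(t, y, p, st, k1);
    if (ok) {
      for (int i = 0; i < 7; ++i) ytmp[i] = y[i] + 0.5 * hdt * k1[i];
      ok = deriv(t + 0.5 * hdt, ytmp, p, st, k2);
    }
    if (ok) {
      for (int i = 0; i < 7; ++i) ytmp[i] = y[i] + 0.5 * hdt * k2[i];
      ok = deriv(t + 0.5 * hdt, ytmp, p, st, k3);
    }
    if (ok) {
      for (int i = 0; i < 7; ++i) ytmp[i] = y[i] + hdt * k3[i];
      ok = deriv(t + hdt, ytmp, p, st, k4);
    }
    if (!ok) { status = 2; break; }
    for (int i = 0; i < 7; ++i)
      y[i] += hdt / 6.0 * (k1[i] + 2.0 * k2[i] + 2.0 * k3[i] + k4[i]);
    t += hdt;

    if (!std::isfinite(y[0])) { status = 2; break; }

    // spike detection on every step
    if (Vprev < spike_thresh && y[0] >= spike_thresh &&
        (t - last_spike) > refractory) {
      double frac = (spike_thresh - Vprev) / (y[0] - Vprev);
      double tsp = t - hdt + frac * hdt;
      spikes.push_back(tsp);
      last_spike = tsp;
    }

    if ((s + 1) % record_every == 0 || t >= t_end) {
      trec[irec] = t;
      for (int i = 0; i < 7; ++i) yrec(irec, i) = y[i];
      grec[irec] = g_gaba_at(t, st);
      ++irec;
    }

    if (max_spikes > 0 && (long)spikes.size() >= max_spikes) {
      status = 3;
      break;
    }

    if (stop_on_converged) {
      for (int i = 0; i < 7; ++i) {
        if (y[i] < wlo[i]) wlo[i] = y[i];
        if (y[i] > whi[i]) whi[i] = y[i];
      }
      if (t - wstart >= window_ms) {
        bool quiet = ((long)spikes.size() == wspikes0);
        bool small = true;
        for (int i = 0; i < 7 && small; ++i)
          if (whi[i] - wlo[i] >= tol) small = false;
        if (quiet && small) { status = 1; break; }
        for (int i = 0; i < 7; ++i) { wlo[i] = y[i]; whi[i] = y[i]; }
        wstart = t;
        wspikes0 = (long)spikes.size();
      }
    }
  }

  // ensure the final point is recorded
  if (irec == 0 || trec[irec - 1] < t) {
    trec[irec] = t;
    for (int i = 0; i < 7; ++i) yrec(irec, i) = y[i];
    grec[irec] = g_gaba_at(t, st);
    ++irec;
  }

  NumericVector yfin(7);
  for (int i = 0; i < 7; ++i) yfin[i] = y[i];

  return List::create(
    _["t"] = trec[Range(0, irec - 1)],
    _["y"] = yrec(Range(0, irec - 1), _),
    _["g_gaba"] = grec[Range(0, irec - 1)],
    _["spikes"] = NumericVector(spikes.begin(), spikes.end()),
    _["status"] = status,
    _["t_final"] = t,
    _["y_final"] = yfin);
}
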