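// Fixed-step charge-difference integrator.
//
// Each step evaluates all transmembrane fluxes from the beginning-of-step
// state, accumulates ion amounts and charge, increments the membrane
// potential by dQ/c, and relaxes the cell volume toward osmotic balance
// with time constant tau.  The order of the three calculation sets is part
// of the method and is never sub-iterated.
//
// Concentrations cross this boundary in mol/L; the amount-to-concentration
// conversion dX/(vol*L) is then direct.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

namespace {

struct Params {
  double gNa, gK, gCl, cap, T;
  double Rp, hNa, x, y, Rnkc, Rkc, z, tau;
  double R, F, L, e;
  double RTF;  // R*T/F, V
};

struct State {
  double Na, K, Cl, An, osm;  // mol/L
  double Em;                  // V
  double vol;                 // L
  double atp;                 // cumulative pump cycles
};

struct Bath {
  double Na, K, Cl, osm;  // mol/L
};

struct Fluxes {
  double NaFc, KFc, ClFc;        // ions/s, inward positive
  double NaFp, KFp;              // pump
  double Ankc, Akc;              // cotransporter activities, cycles/s
  double Ap;                     // pump activity, cycles/s
};

inline void check_pos(double co, double ci, const char *what) {
  if (co <= 0.0 || ci <= 0.0)
    stop("non-positive concentration in %s driving force", what);
}

Fluxes compute_fluxes(const State &s, const Bath &b, const Params &p) {
  Fluxes f = {0, 0, 0, 0, 0, 0, 0, 0};
  if (p.gNa > 0.0) {
    check_pos(b.Na, s.Na, "Na+ conductance");
    f.NaFc = p.gNa * (p.RTF * std::log(b.Na / s.Na) - s.Em);
  }
  if (p.gK > 0.0) {
    check_pos(b.K, s.K, "K+ conductance");
    f.KFc = p.gK * (p.RTF * std::log(b.K / s.K) - s.Em);
  }
  if (p.gCl > 0.0) {
    check_pos(b.Cl, s.Cl, "Cl- conductance");
    f.ClFc = p.gCl * (p.RTF * std::log(b.Cl / s.Cl) + s.Em);
  }
  if (p.Rp > 0.0 && s.Na > 0.0) {
    double r = 1.0 + (p.hNa / s.Na);
    f.Ap = p.Rp / (r * r * r);
    f.NaFp = -p.x * f.Ap;
    f.KFp = p.y * f.Ap;
  }
  if (p.Rnkc > 0.0) {
    check_pos(b.Na * b.K * b.Cl, s.Na * s.K * s.Cl, "NKCC");
    f.Ankc = p.Rnkc * std::log10((b.Na * b.K * b.Cl * b.Cl) /
                                 (s.Na * s.K * s.Cl * s.Cl));
  }
  if (p.Rkc > 0.0) {
    check_pos(b.K * b.Cl, s.K * s.Cl, "KCC");
    f.Akc = p.Rkc * std::log10((b.K * b.Cl) / (s.K * s.Cl));
  }
  return f;
}

const double CONC_FLOOR = 1e-12;  // mol/L
const int MAX_HALVINGS = 40;

// One attempt at a step of size h starting from (s, b) at absolute time t.
// Returns false when a permeant-ion concentration is driven through the
// floor (caller then retries with two half steps).
bool try_step(State &s, Bath &b, const Params &p,
              const double *bu_rate, const double *bu_on, const double *bu_off,
              double t, double h, double &dQ_out) {
  Fluxes f = compute_fluxes(s, b, p);

  double dNa = (f.NaFc + f.NaFp + f.Ankc) * h;
  double dK  = (f.KFc + f.KFp + f.Ankc + f.Akc) * h;
  double dCl = (f.ClFc + 2.0 * f.Ankc + f.Akc) * h;

  // buildups: 0 bOso, 1 bNaCl, 2 bOsi, 3 bAn (rates mol/L per s)
  double act[4];
  for (int i = 0; i < 4; ++i)
    act[i] = (t >= bu_on[i] && t < bu_off[i]) ? bu_rate[i] : 0.0;

  State ns = s;
  Bath nb = b;
  nb.osm += act[0] * h;
  nb.Na += act[1] * h;
  nb.Cl += act[1] * h;
  ns.osm += act[2] * h;
  ns.An += act[3] * h;

  double volL = s.vol * p.L;
  ns.Na += dNa / volL + act[3] * h * (-p.z);
  ns.K += dK / volL;
  ns.Cl += dCl / volL;

  // reject if a flux drove a permeant concentration through the floor
  if ((ns.Na < CONC_FLOOR && ns.Na < s.Na) ||
      (ns.K < CONC_FLOOR && ns.K < s.K) ||
      (ns.Cl < CONC_FLOOR && ns.Cl < s.Cl))
    return false;

  double dQ = (dNa + dK - dCl) * p.e;
  ns.Em += dQ / p.cap;

  double osV = (ns.Na + ns.K + ns.Cl + ns.An + ns.osm) /
               (nb.Na + nb.K + nb.Cl + nb.osm);
  double VoR;
  if (p.tau > 1e8) VoR = 0.0;
  else if (p.tau < h) VoR = 1.0 / h;
  else VoR = 1.0 / p.tau;
  double chV = 1.0 - (1.0 - osV) * VoR * h;
  if (chV <= 0.0)
    stop("osmotic collapse: chV <= 0 (time step too large for tau)");
  ns.vol *= chV;
  ns.Na /= chV;
  ns.K /= chV;
  ns.Cl /= chV;
  ns.An /= chV;
  ns.osm /= chV;

  ns.atp += f.Ap * h;
  s = ns;
  b = nb;
  dQ_out = dQ;
  return true;
}

void do_step(State &s, Bath &b, const Params &p,
             const double *bu_rate, const double *bu_on, const double *bu_off,
             double t, double h, int depth, double &dQ_out) {
  double dq = 0.0;
  if (try_step(s, b, p, bu_rate, bu_on, bu_off, t, h, dq)) {
    dQ_out += dq;
    return;
  }
  if (depth >= MAX_HALVINGS)
    stop("step rejection limit reached: concentration driven below floor");
  do_step(s, b, p, bu_rate, bu_on, bu_off, t, h / 2.0, depth + 1, dQ_out);
  do_step(s, b, p, bu_rate, bu_on, bu_off, t + h / 2.0, h / 2.0, depth + 1, dQ_out);
}

}  // namespace

// [[Rcpp::export(name = ".cd_integrate")]]
List cd_integrate(NumericVector state0, NumericVector bath0,
                  NumericVector params, NumericMatrix buildups,
                  double st, double t_end, int record_every,
                  bool steady_mode, double steady_tol,
                  int check_every, int steady_need,
                  double vol_max_ratio) {
  Params p;
  p.gNa = params[0]; p.gK = params[1]; p.gCl = params[2];
  p.cap = params[3]; p.T = params[4];
  p.Rp = params[5]; p.hNa = params[6] * 1e-3;  // mM -> mol/L
  p.x = params[7]; p.y = params[8];
  p.Rnkc = params[9]; p.Rkc = params[10];
  p.z = params[11]; p.tau = params[12];
  p.R = params[13]; p.F = params[14]; p.L = params[15]; p.e = params[16];
  p.RTF = p.R * p.T / p.F;

  State s;
  s.Na = state0[0]; s.K = state0[1]; s.Cl = state0[2];
  s.An = state0[3]; s.osm = state0[4];
  s.Em = state0[5]; s.vol = state0[6];
  double t0 = state0[7];
  s.atp = state0[8];

  Bath b;
  b.Na = bath0[0]; b.K = bath0[1]; b.Cl = bath0[2]; b.osm = bath0[3];

  double bu_rate[4], bu_on[4], bu_off[4];
  for (int i = 0; i < 4; ++i) {
    bu_rate[i] = buildups(i, 0);
    bu_on[i] = buildups(i, 1);
    bu_off[i] = buildups(i, 2);
  }

  long n_steps = (long)std::llround(t_end / st);
  if (n_steps < 0) stop("t_end must be >= 0");

  long n_rec = 0;
  if (record_every > 0) n_rec = n_steps / record_every + 1;
  NumericMatrix traj(n_rec + 1, 17);
  long irec = 0;
  double vol0 = s.vol;
  double q_cum = 0.0;

  auto snapshot = [&](double t) {
    if (irec > n_rec) return;
    Fluxes f = compute_fluxes(s, b, p);
    traj(irec, 0) = t;
    traj(irec, 1) = s.Na; traj(irec, 2) = s.K; traj(irec, 3) = s.Cl;
    traj(irec, 4) = s.An; traj(irec, 5) = s.osm;
    traj(irec, 6) = s.Em; traj(irec, 7) = s.vol;
    traj(irec, 8) = f.Ap; traj(irec, 9) = f.Ankc; traj(irec, 10) = f.Akc;
    traj(irec, 11) = s.atp; traj(irec, 12) = q_cum;
    traj(irec, 13) = b.Na; traj(irec, 14) = b.K;
    traj(irec, 15) = b.Cl; traj(irec, 16) = b.osm;
    ++irec;
  };

  snapshot(t0);

  bool converged = false, swelling = false;
  int hold = 0;
  long i = 0;
  for (i = 1; i <= n_steps; ++i) {
    double t_b = t0 + (double)(i - 1) * st;
    do_step(s, b, p, bu_rate, bu_on, bu_off, t_b, st, 0, q_cum);
    if (record_every > 0 && (i % record_every == 0)) snapshot(t0 + (double)i * st);
    if (steady_mode && (i % check_every == 0)) {
      Fluxes f = compute_fluxes(s, b, p);
      double volL = s.vol * p.L;
      double rNa = std::fabs(f.NaFc + f.NaFp + f.Ankc) / volL;
      double rK = std::fabs(f.KFc + f.KFp + f.Ankc + f.Akc) / volL;
      double rCl = std::fabs(f.ClFc + 2.0 * f.Ankc + f.Akc) / volL;
      if (rNa < steady_tol && rK < steady_tol && rCl < steady_tol) ++hold;
      else hold = 0;
      if (hold >= steady_need) { converged = true; break; }
      if (s.vol > vol_max_ratio * vol0) { swelling = true; break; }
    }
    if (i % 2000000 == 0) Rcpp::checkUserInterrupt();
  }
  long steps_done = std::min(i, n_steps);
  double t_final = t0 + (double)steps_done * st;
  if (record_every > 0 &&
      (irec == 0 || traj(irec - 1, 0) != t_final)) snapshot(t_final);

  Fluxes f = compute_fluxes(s, b, p);
  NumericVector fin = NumericVector::create(
      s.Na, s.K, s.Cl, s.An, s.osm, s.Em, s.vol, t_final, s.atp);
  NumericVector bfin = NumericVector::create(b.Na, b.K, b.Cl, b.osm);
  NumericVector net = NumericVector::create(
      _["Na"] = f.NaFc + f.NaFp + f.Ankc,
      _["K"] = f.KFc + f.KFp + f.Ankc + f.Akc,
      _["Cl"] = f.ClFc + 2.0 * f.Ankc + f.Akc);

  return List::create(
      _["state"] = fin, _["bath"] = bfin,
      _["traj"] = traj(Range(0, std::max((long)0, irec - 1)), _),
      _["converged"] = converged, _["swelling"] = swelling,
      _["steps"] = (double)steps_done, _["q_cum"] = q_cum,
      _["net_flux"] = net, _["Ap"] = f.Ap,
      _["Ankc"] = f.Ankc, _["Akc"] = f.Akc);
}
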