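#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Lumped-parameter bench model, fixed-step classical RK4.
//
// State: v = lung volume above residual (ml, total over parallel test lungs),
//        w = water displaced from the container into the abdominal sack (ml).
// Pleural pressure is algebraic: the amount of gas sealed in the pleural space
// is conserved (isothermal), so (Patm + Ppl) * Vgas(v, w, Ppl) = N with
// Vgas = vg0 - (v - v0) + w + cw * (Ppl - pev).  Solving that quadratic each
// derivative evaluation keeps gas conservation exact by construction.

struct ModelPar {
  // lung
  double n_units, cap_per_unit, r_aw;
  std::vector<double> ptab, vtab;   // total lung P/V curve, strictly increasing
  // pleural space / chest wall
  double vg0, cw, patm, pev, krec;
  // abdomen
  double k_head, r_valve;
  bool isolated;
  // ventilator
  double vt, t_flow, t_pause, t_exp, r_exp;
  double dt;
  // derived
  double v0;   // lung volume at baseline (PTP = -pev)
  double Ngas; // conserved pleural gas amount (cmH2O * ml, absolute)
};

static double interp(const std::vector<double>& x, const std::vector<double>& y,
                     double xq) {
  const int n = x.size();
  if (n == 2 || xq <= x[0]) {
    // linear (2-point table) or extrapolate below with first segment slope
    double s = (y[1] - y[0]) / (x[1] - x[0]);
    if (xq <= x[0]) return y[0] + s * (xq - x[0]);
  }
  if (xq >= x[n - 1]) {
    double s = (y[n - 1] - y[n - 2]) / (x[n - 1] - x[n - 2]);
    return y[n - 1] + s * (xq - x[n - 1]);
  }
  int lo = 0, hi = n - 1;
  while (hi - lo > 1) {
    int mid = (lo + hi) / 2;
    if (x[mid] <= xq) lo = mid; else hi = mid;
  }
  double s = (y[hi] - y[lo]) / (x[hi] - x[lo]);
  return y[lo] + s * (xq - x[lo]);
}

static double ptp_of_v(const ModelPar& p, double v) { return interp(p.vtab, p.ptab, v); }

// pleural pressure from gas conservation; unique root above -Patm
static double solve_ppl(const ModelPar& p, double v, double w) {
  double B = p.vg0 - (v - p.v0) + w;
  if (p.cw < 1e-12) return p.Ngas / B - p.patm;
  double a = p.cw;
  double b = B + p.cw * (p.patm - p.pev);
  double c = p.patm * (B - p.cw * p.pev) - p.Ngas;
  double disc = b * b - 4.0 * a * c;
  if (disc < 0.0) disc = 0.0;
  return (-b + std::sqrt(disc)) / (2.0 * a);
}

// mode: 0 inspiratory flow, 1 pause, 2 expiration, 3 CPAP hold
struct Deriv { double dv, dw; };

static Deriv deriv(const ModelPar& p, double v, double w, int mode,
                   double peep, double p_hold) {
  Deriv d;
  double ppl = p.isolated ? 0.0 : solve_ppl(p, v, w);
  double palv = ppl + ptp_of_v(p, v);
  switch (mode) {
  case 0: d.dv = p.vt / p.t_flow; break;
  case 1: d.dv = 0.0; break;
  case 2: {
    double q = (palv - peep) / (p.r_aw + p.r_exp);
    d.dv = q > 0.0 ? -q : 0.0;   // one-way expiratory valve
    break;
  }
  default: d.dv = (p_hold - palv) / p.r_aw; break;
  }
  d.dw = p.isolated ? 0.0
                    : (ppl - p.pev - (p.k_head + p.krec) * w) / p.r_valve;
  return d;
}

static void rk4(const ModelPar& p, double& v, double& w, int mode,
                double peep, double p_hold) {
  const double dt = p.dt;
  Deriv k1 = deriv(p, v, w, mode, peep, p_hold);
  Deriv k2 = deriv(p, v + 0.5 * dt * k1.dv, w + 0.5 * dt * k1.dw, mode, peep, p_hold);
  Deriv k3 = deriv(p, v + 0.5 * dt * k2.dv, w + 0.5 * dt * k2.dw, mode, peep, p_hold);
  Deriv k4 = deriv(p, v + dt * k3.dv, w + dt * k3.dw, mode, peep, p_hold);
  v += dt / 6.0 * (k1.dv + 2.0 * k2.dv + 2.0 * k3.dv + k4.dv);
  w += dt / 6.0 * (k1.dw + 2.0 * k2.dw + 2.0 * k3.dw + k4.dw);
}

static ModelPar unpack(const List& par) {
  ModelPar p;
  p.n_units = as<double>(par["n_units"]);
  p.cap_per_unit = as<double>(par["cap_per_unit"]);
  p.r_aw = as<double>(par["r_aw"]);
  p.ptab = as<std::vector<double> >(par["ptab"]);
  p.vtab = as<std::vector<double> >(par["vtab"]);
  p.vg0 = as<double>(par["vg0"]);
  p.cw = as<double>(par["cw"]);
  p.patm = as<double>(par["patm"]);
  p.pev = as<double>(par["pev"]);
  p.krec = as<double>(par["krec"]);
  p.k_head = as<double>(par["k_head"]);
  p.r_valve = as<double>(par["r_valve"]);
  p.isolated = as<bool>(par["isolated"]);
  p.vt = as<double>(par["vt"]);
  p.t_flow = as<double>(par["t_flow"]);
  p.t_pause = as<double>(par["t_pause"]);
  p.t_exp = as<double>(par["t_exp"]);
  p.r_exp = as<double>(par["r_exp"]);
  p.dt = as<double>(par["dt"]);
  p.v0 = interp(p.ptab, p.vtab, -p.pev);
  p.Ngas = (p.patm + p.pev) * p.vg0;
  return p;
}

// Instantaneous recorded pressures at a sample instant.
static void record_pressures(const ModelPar& p, double v, double w, int mode,
                             double peep, double& paw, double& ppl) {
  ppl = p.isolated ? 0.0 : solve_ppl(p, v, w);
  double palv = ppl + ptp_of_v(p, v);
  switch (mode) {
  case 0: paw = palv + p.r_aw * (p.vt / p.t_flow); break;
  case 1: paw = palv; break;
  default: {
    double q = (palv - peep) / (p.r_aw + p.r_exp);
    paw = q > 0.0 ? peep + p.r_exp * q : peep;
    break;
  }
  }
}

// [[Rcpp::export(name = ".sim_breaths_cpp")]]
List sim_breaths_cpp(List par, NumericVector peep_per_breath,
                     double v_init, double w_init) {
  ModelPar p = unpack(par);
  const double cycle = p.t_flow + p.t_pause + p.t_exp;
  const long steps_flow = (long)std::lround(p.t_flow / p.dt);
  const long steps_pause = (long)std::lround(p.t_pause / p.dt);
  const long steps_cycle = (long)std::lround(cycle / p.dt);
  const long rec_every = (long)std::lround(0.01 / p.dt);
  const long samp_cycle = steps_cycle / rec_every;
  const int n_breaths = peep_per_breath.size();
  const long n_samp = (long)n_breaths * samp_cycle;

  NumericVector time(n_samp), paw(n_samp), ppl(n_samp), flow(n_samp),
      vlung(n_samp), wdisp(n_samp);
  IntegerVector phase(n_samp), breath(n_samp);

  double v = v_init, w = w_init;
  const double cap = p.n_units * p.cap_per_unit;
  long isamp = 0;
  bool cap_error = false;
  int cap_breath = 0;

  for (int b = 0; b < n_breaths && !cap_error; ++b) {
    const double peep = peep_per_breath[b];
    for (long s = 0; s < steps_cycle; ++s) {
      int mode = s < steps_flow ? 0 : (s < steps_flow + steps_pause ? 1 : 2);
      if (s % rec_every == 0) {
        double pa, pp;
        record_pressures(p, v, w, mode, peep, pa, pp);
        time[isamp] = (b * (double)steps_cycle + s) * p.dt;
        paw[isamp] = pa;
        ppl[isamp] = pp;
        vlung[isamp] = v;
        wdisp[isamp] = w;
        phase[isamp] = mode + 1;
        breath[isamp] = b + 1;
      }
      double v_before = v;
      rk4(p, v, w, mode, peep, 0.0);
      if (v > cap) { cap_error = true; cap_breath = b + 1; break; }
      if (s % rec_every == rec_every - 1) {
        // forward interval-average airway flow over the 10 ms ending here
        flow[isamp] += (v - vlung[isamp]) / 0.01;
        ++isamp;
      } else {
        (void)v_before;
      }
    }
  }
  if (isamp < n_samp) {
    time = head(time, isamp); paw = head(paw, isamp); ppl = head(ppl, isamp);
    flow = head(flow, isamp); vlung = head(vlung, isamp);
    wdisp = head(wdisp, isamp);
    phase = head(phase, isamp); breath = head(breath, isamp);
  }
  return List::create(
      _["time"] = time, _["paw"] = paw, _["ppl"] = ppl, _["flow"] = flow,
      _["vlung"] = vlung, _["w"] = wdisp, _["phase"] = phase,
      _["breath"] = breath, _["v_final"] = v, _["w_final"] = w,
      _["capacity_error"] = cap_error, _["capacity_breath"] = cap_breath);
}

// Apneic CPAP hold: airway held at a constant pressure, no tidal ventilation.
// [[Rcpp::export(name = ".sim_hold_cpp")]]
List sim_hold_cpp(List par, double pressure, double duration,
                  double v_init, double w_init) {
  ModelPar p = unpack(par);
  const long nsteps = (long)std::lround(duration / p.dt);
  const long rec_every = (long)std::lround(0.01 / p.dt);
  const long n_samp = nsteps / rec_every;
  NumericVector time(n_samp), ppl(n_samp), vlung(n_samp), wdisp(n_samp);
  double v = v_init, w = w_init;
  long isamp = 0;
  const double cap = p.n_units * p.cap_per_unit;
  for (long s = 0; s < nsteps; ++s) {
    if (s % rec_every == 0 && isamp < n_samp) {
      time[isamp] = s * p.dt;
      ppl[isamp] = p.isolated ? 0.0 : solve_ppl(p, v, w);
      vlung[isamp] = v;
      wdisp[isamp] = w;
      ++isamp;
    }
    rk4(p, v, w, 3, 0.0, pressure);
    if (v > cap) stop("lung volume exceeded capacity during hold");
  }
  return List::create(_["time"] = time, _["ppl"] = ppl, _["vlung"] = vlung,
                      _["w"] = wdisp, _["v_final"] = v, _["w_final"] = w);
}

// Pleural pressure solver exposed for R-level derivatives/oracle checks.
// [[Rcpp::export(name = ".solve_ppl_cpp")]]
double solve_ppl_export(List par, double v, double w) {
  ModelPar p = unpack(par);
  if (p.isolated) return 0.0;
  return solve_ppl(p, v, w);
}
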