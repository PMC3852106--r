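#include <Rcpp.h>
using namespace Rcpp;

// Single-compartment granule-cell model, current-clamp integration.
//
// State: V (mV), h (Na inactivation), n (delayed rectifier), a (delay-current
// activation), b (delay-current inactivation). Na activation m is treated as
// instantaneous (m = m_inf(V)). Gates use exponential-Euler updates; V uses an
// explicit update. Units: mV, pA, nS, pF; internal time step in ms.
//
// pars layout (positional):
//  0 C_m, 1 g_L, 2 E_L, 3 g_Na, 4 E_Na, 5 g_Kdr, 6 g_Kir, 7 g_D,
//  8 V50_act, 9 k_act, 10 tau_act_ms, 11 V50_inact, 12 k_inact,
// 13 tau_inact_ms, 14 E_K

static inline double minf(double V)  { return 1.0 / (1.0 + exp(-(V + 38.0) / 7.0)); }
static inline double hinf(double V)  { return 1.0 / (1.0 + exp((V + 47.0) / 6.0)); }
static inline double ninf(double V)  { return 1.0 / (1.0 + exp(-(V + 30.0) / 10.0)); }
static inline double kirinf(double V){ return 1.0 / (1.0 + exp((V + 80.0) / 12.0)); }

// [[Rcpp::export]]
NumericVector sim_cc_core(NumericVector pars, NumericVector I_inj,
                          double dt_s, double v0) {
  const double C    = pars[0];
  const double gL   = pars[1],  EL  = pars[2];
  const double gNa  = pars[3],  ENa = pars[4];
  const double gKdr = pars[5];
  const double gKir = pars[6];
  const double gD   = pars[7];
  const double V50a = pars[8],  ka  = pars[9],  taua = pars[10];
  const double V50b = pars[11], kb  = pars[12], taub = pars[13];
  const double EK   = pars[14];

  const double dt = dt_s * 1000.0;      // ms
  const double tauh = 5.0, taun = 4.0;  // ms, fixed spike-gate kinetics
  const double eh = 1.0 - exp(-dt / tauh);
  const double en = 1.0 - exp(-dt / taun);
  const double ea = 1.0 - exp(-dt / taua);
  const double eb = 1.0 - exp(-dt / taub);

  const R_xlen_t nT = I_inj.size();
  NumericVector V(nT);

  double v = v0;
  double h = hinf(v), n = ninf(v);
  double a = 1.0 / (1.0 + exp((V50a - v) / ka));
  double b = 1.0 / (1.0 + exp((v - V50b) / kb));

  for (R_xlen_t i = 0; i < nT; ++i) {
    V[i] = v;
    const double m = minf(v);
    const double iion =
        gL * (v - EL) +
        gNa * m * m * m * h * (v - ENa) +
        gKdr * n * n * n * n * (v - EK) +
        gKir * kirinf(v) * (v - EK) +
        gD * a * b * (v - EK);
    const double dv = dt * (-iion + I_inj[i]) / C;
    v += dv;
    if (!R_finite(v))
      stop("non-finite membrane potential at step %td", (ptrdiff_t)i);
    h += (hinf(v) - h) * eh;
    n += (ninf(v) - n) * en;
    a += (1.0 / (1.0 + exp((V50a - v) / ka)) - a) * ea;
    b += (1.0 / (1.0 + exp((v - V50b) / kb)) - b) * eb;
  }
  return V;
}

// Steady-state total membrane current (pA) at clamped voltage V with all
// gates at their steady state; used for resting-potential root finding.
// [[Rcpp::export]]
double ss_membrane_current(NumericVector pars, double V) {
  const double gL = pars[1], EL = pars[2];
  const double gNa = pars[3], ENa = pars[4];
  const double gKdr = pars[5], gKir = pars[6], gD = pars[7];
  const double V50a = pars[8], ka = pars[9];
  const double V50b = pars[11], kb = pars[12];
  const double EK = pars[14];
  const double m = minf(V), h = hinf(V), n = ninf(V);
  const double a = 1.0 / (1.0 + exp((V50a - V) / ka));
  const double b = 1.0 / (1.0 + exp((V - V50b) / kb));
  return gL * (V - EL) + gNa * m * m * m * h * (V - ENa) +
         gKdr * n * n * n * n * (V - EK) + gKir * kirinf(V) * (V - EK) +
         gD * a * b * (V - EK);
}
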