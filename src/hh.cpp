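#include <Rcpp.h>
using namespace Rcpp;

// x / (exp(x / y) - 1) with the removable singularity at x = 0 filled in by
// its limit value -y (note the sign: limit of x/(exp(x/y)-1) as x->0 is y).
static inline double vtrap(double x, double y) {
  if (std::fabs(x / y) < 1e-7) return y * (1.0 - x / (2.0 * y));
  return x / (std::exp(x / y) - 1.0);
}

// Voltage-dependent gating rate constants (1/ms) of the point-conductance
// model: m/h gate the Na conductance, n the delayed-rectifier K conductance.
// `a` shifts the Na inactivation (h) curves, moving the half-inactivation
// voltage away from its default of about -46 mV.
// [[Rcpp::export]]
NumericVector hh_rates_cpp(double V, double a) {
  NumericVector r(6);
  r[0] = 0.32 * vtrap(-(V + 45.0), 4.0);                 // alpha_m
  r[1] = 0.28 * vtrap(V + 18.0, 5.0);                    // beta_m
  r[2] = 0.128 * std::exp(-(V + 51.0 + a) / 18.0);       // alpha_h
  r[3] = 4.0 / (1.0 + std::exp(-(V + 28.0 + a) / 5.0));  // beta_h
  r[4] = 0.032 * vtrap(-(V + 43.0), 5.0);                // alpha_n
  r[5] = 0.5 * std::exp(-(V + 48.0) / 40.0);             // beta_n
  r.names() = CharacterVector::create("alpha_m", "beta_m", "alpha_h",
                                      "beta_h", "alpha_n", "beta_n");
  return r;
}

// Forward-Euler integration of the Hodgkin-Huxley point-conductance neuron.
// `I` is the input current in pA on the time grid; `pA_to_uAcm2` converts it
// to a current density (uA/cm^2). Gating variables start at their V0 steady
// state. Spikes are upward crossings of 0 mV with a 1 ms dead time.
// [[Rcpp::export]]
List hh_integrate_cpp(NumericVector I, double dt, double Cm, double gNa,
                      double gK, double gL, double ENa, double EK, double EL,
                      double a, double pA_to_uAcm2, double V0) {
  const int n = I.size();
  NumericVector Vm(n);
  double V = V0;
  NumericVector r0 = hh_rates_cpp(V0, a);
  double m = r0[0] / (r0[0] + r0[1]);
  double h = r0[2] / (r0[2] + r0[3]);
  double ng = r0[4] / (r0[4] + r0[5]);
  std::vector<double> spikes;
  double dead_until = -1.0;
  Vm[0] = V;

  for (int i = 1; i < n; ++i) {
    const double t = i * dt;
    const double Vp = V;
    const double J = I[i] * pA_to_uAcm2;
    V += (-gNa * m * m * m * h * (Vp - ENa) - gK * ng * ng * ng * ng * (Vp - EK) -
          gL * (Vp - EL) + J) * dt / Cm;
    const double am = 0.32 * vtrap(-(Vp + 45.0), 4.0);
    const double bm = 0.28 * vtrap(Vp + 18.0, 5.0);
    const double ah = 0.128 * std::exp(-(Vp + 51.0 + a) / 18.0);
    const double bh = 4.0 / (1.0 + std::exp(-(Vp + 28.0 + a) / 5.0));
    const double an = 0.032 * vtrap(-(Vp + 43.0), 5.0);
    const double bn = 0.5 * std::exp(-(Vp + 48.0) / 40.0);
    m += (am * (1.0 - m) - bm * m) * dt;
    h += (ah * (1.0 - h) - bh * h) * dt;
    ng += (an * (1.0 - ng) - bn * ng) * dt;
    if (!std::isfinite(V)) {
      stop("non-finite membrane potential at t = %f ms (step %d)", t, i + 1);
    }
    if (Vp <= 0.0 && V > 0.0 && t >= dead_until) {
      spikes.push_back(t);
      dead_until = t + 1.0;
    }
    Vm[i] = V;
  }

  return List::create(_["Vm"] = Vm,
                      _["spikes"] = NumericVector(spikes.begin(), spikes.end()));
}
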