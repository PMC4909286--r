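#include <Rcpp.h>
using namespace Rcpp;

// Steady-state threshold theta_inf(Vm) = alpha*(Vm-Vi) + VT + ka*log(1+exp((Vm-Vi)/ki)),
// evaluated with a softplus-stable form so large depolarizations do not overflow.
inline double theta_inf_c(double Vm, double alpha, double VT, double ka,
                          double ki, double Vi) {
  double x = (Vm - Vi) / ki;
  double sp = (x > 30.0) ? x : std::log1p(std::exp(x));
  return alpha * (Vm - Vi) + VT + ka * sp;
}

// [[Rcpp::export]]
double theta_inf_cpp(double Vm, double alpha, double VT, double ka,
                     double ki, double Vi) {
  return theta_inf_c(Vm, alpha, VT, ka, ki, Vi);
}

// Forward-Euler integration of the exponential integrate-and-fire neuron for a
// batch of trials. Each column of `impulses` is one trial's train of synaptic
// charge deposits on the time grid; the synaptic current obeys
// I[i] = syn_decay * I[i-1] + impulses[i], which for syn_decay = exp(-dt/tau)
// is the exact sampling of a sum of instantaneous-rise exponential EPSCs.
// Passing syn_decay = 0 makes `impulses` the current trace itself.
//
// A spike is registered at the first grid sample with Vm > theta + spike_margin;
// Vm is clamped to Vreset for the refractory period and integration resumes
// from Vreset. For the adaptive model theta obeys
// tau_theta * dtheta/dt = theta_inf(Vm) - theta throughout (also during the
// refractory clamp); for the fixed model theta is constant.
// [[Rcpp::export]]
List eif_batch_cpp(NumericMatrix impulses, double dt, double syn_decay,
                   double Cm, double gL, double EL, double DeltaT,
                   double Vreset, double refractory, double spike_margin,
                   bool adaptive, double tau_theta, double alpha, double ka,
                   double ki, double VT, double Vi, double theta_fixed,
                   double V0, double theta0, bool return_traces) {
  const int n_steps = impulses.nrow();
  const int n_trials = impulses.ncol();
  List spike_list(n_trials);
  NumericMatrix Vtr(return_traces ? n_steps : 1, return_traces ? n_trials : 1);
  NumericMatrix Ttr(return_traces ? n_steps : 1, return_traces ? n_trials : 1);
  const double emax = 30.0;  // clamp on the exponential argument

  for (int tr = 0; tr < n_trials; ++tr) {
    double Vm = V0;
    double theta = adaptive ? theta0 : theta_fixed;
    double I = 0.0;
    double refr_until = -1.0;
    std::vector<double> spikes;

    for (int i = 0; i < n_steps; ++i) {
      const double t = i * dt;
      I = I * syn_decay + impulses(i, tr);
      if (i > 0) {
        const double Vprev = Vm;
        if (t < refr_until) {
          Vm = Vreset;
        } else {
          double ex = (Vprev - theta) / DeltaT;
          if (ex > emax) ex = emax;
          Vm += (-gL * (Vprev - EL) + gL * DeltaT * std::exp(ex) + I) * dt / Cm;
        }
        if (adaptive) {
          theta += (theta_inf_c(Vprev, alpha, VT, ka, ki, Vi) - theta) * dt / tau_theta;
        }
        if (!std::isfinite(Vm) || !std::isfinite(theta)) {
          stop("non-finite state at t = %f ms (step %d, trial %d)", t, i + 1, tr + 1);
        }
        if (t >= refr_until && Vm > theta + spike_margin) {
          spikes.push_back(t);
          refr_until = t + refractory;
          if (return_traces) {  // record the crossing value, reset next step
            Vtr(i, tr) = Vm;
            Ttr(i, tr) = theta;
          }
          Vm = Vreset;
          continue;
        }
      }
      if (return_traces) {
        Vtr(i, tr) = Vm;
        Ttr(i, tr) = theta;
      }
    }
    spike_list[tr] = NumericVector(spikes.begin(), spikes.end());
  }

  List out = List::create(_["spikes"] = spike_list);
  if (return_traces) {
    out["Vm"] = Vtr;
    out["theta"] = Ttr;
  }
  return out;
}
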