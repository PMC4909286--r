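#' EIF membrane parameters
#'
#' Parameters of the exponential integrate-and-fire (EIF) membrane equation
#' \deqn{C_m \frac{dV_m}{dt} = -g_L (V_m - E_L) + g_L \Delta_T
#'   \exp\!\left(\frac{V_m - \theta}{\Delta_T}\right) + I.}
#' Units are pF, nS, mV, ms and pA throughout, under which the equation is
#' dimensionally consistent (pF mV/ms = pA). The defaults give a membrane
#' time constant \eqn{\tau_m = C_m / g_L = 5} ms.
#'
#' @param Cm membrane capacitance (pF).
#' @param gL leak conductance (nS).
#' @param EL leak reversal potential (mV); also the knob that sets the
#'   membrane "state" (depolarized vs hyperpolarized resting regimes).
#' @param DeltaT spike-initiation slope factor (mV).
#' @param Vreset post-spike reset potential (mV).
#' @param refractory absolute refractory period (ms) during which the
#'   membrane is clamped at `Vreset`.
#' @param spike_margin detection margin (mV): a spike is registered at the
#'   first sample with `Vm > theta + spike_margin`.
#' @return An object of class `eif_params`.
#' @export
eif_params <- function(Cm = 50, gL = 10, EL = -70, DeltaT = 1,
                       Vreset = -70, refractory = 0.5, spike_margin = 3) {
  stopifnot(Cm > 0, gL > 0, DeltaT > 0, refractory >= 0)
  structure(list(Cm = Cm, gL = gL, EL = EL, DeltaT = DeltaT, Vreset = Vreset,
                 refractory = refractory, spike_margin = spike_margin),
            class = "eif_params")
}

#' Adaptive-threshold parameters
#'
#' Parameters of the first-order threshold dynamics
#' \deqn{\tau_\theta \frac{d\theta}{dt} = \theta_\infty(V_m) - \theta,
#'  \qquad \theta_\infty(V_m) = \alpha (V_m - V_i) + V_T +
#'   k_a \log\!\left(1 + e^{(V_m - V_i)/k_i}\right),}
#' with the natural logarithm. `beta` is carried for completeness of the
#' published parameter set but does not enter the equations.
#'
#' @param tau_theta threshold time constant (ms).
#' @param alpha linear gain (dimensionless).
#' @param beta stored constant, unused by the dynamics.
#' @param ka gain of the soft-rectified term (mV).
#' @param ki voltage scale of the soft-rectified term (mV).
#' @param VT threshold offset (mV).
#' @param Vi inflection voltage (mV).
#' @return An object of class `adaptive_threshold_params`.
#' @export
adaptive_threshold_params <- function(tau_theta = 6, alpha = 0.3, beta = 1.1,
                                      ka = 7, ki = 8.75, VT = -50, Vi = -55) {
  stopifnot(tau_theta > 0, ka > 0, ki > 0)
  structure(list(tau_theta = tau_theta, alpha = alpha, beta = beta, ka = ka,
                 ki = ki, VT = VT, Vi = Vi),
            class = "adaptive_threshold_params")
}

#' Fixed-threshold parameters
#'
#' @param theta constant spike threshold (mV). In firing-rate-matched
#'   experiments calibrated values fall around -52 to -53.8 mV.
#' @return An object of class `fixed_threshold_params`.
#' @export
fixed_threshold_params <- function(theta) {
  stopifnot(is.finite(theta))
  structure(list(theta = theta), class = "fixed_threshold_params")
}

#' Hodgkin-Huxley point-conductance parameters
#'
#' Single-compartment conductance model
#' \deqn{C_m \frac{dV_m}{dt} = -g_{Na} m^3 h (V_m - E_{Na})
#'   - g_K n^4 (V_m - E_K) - g_L (V_m - E_L) + I}
#' in density units (uF/cm^2, mS/cm^2, mV, ms). With `gL = 0.2` and
#' `Cm = 1` the passive membrane time constant is 5 ms, matching the EIF
#' defaults. `area` converts pA inputs to current density; the default
#' 5e-5 cm^2 makes total capacitance 50 pF, so a given pA input depolarizes
#' the HH and EIF membranes identically in the passive regime.
#'
#' @param Cm specific capacitance (uF/cm^2).
#' @param gNa,gK,gL maximal conductances (mS/cm^2).
#' @param ENa,EK,EL reversal potentials (mV).
#' @param a voltage shift (mV) of the Na inactivation rates; `a = 0` puts
#'   the half-inactivation voltage near -46 mV.
#' @param area membrane area (cm^2) used to convert pA to uA/cm^2.
#' @return An object of class `hh_params`.
#' @export
hh_params <- function(Cm = 1, gNa = 60, gK = 10, gL = 0.2, ENa = 50,
                      EK = -90, EL = -70, a = 0, area = 5e-5) {
  stopifnot(gNa >= 0, gK >= 0, gL >= 0, Cm > 0, area > 0)
  structure(list(Cm = Cm, gNa = gNa, gK = gK, gL = gL, ENa = ENa, EK = EK,
                 EL = EL, a = a, area = area),
            class = "hh_params")
}

#' Simulation grid configuration
#'
#' @param dt integration step (ms); 0.1 for the EIF models, 0.01 for HH.
#' @param duration total simulated time (ms); must be a multiple of `dt`.
#' @param V0 initial membrane potential (mV).
#' @param seed optional integer seed attached for bookkeeping.
#' @return An object of class `sim_config`. The time grid is
#'   `seq(0, duration - dt, by = dt)`.
#' @export
sim_config <- function(dt = 0.1, duration = 100, V0 = -70, seed = NULL) {
  stopifnot(dt > 0, duration > 0)
  n <- round(duration / dt)
  if (abs(n * dt - duration) > 1e-9) {
    stop("`duration` must be a multiple of `dt`")
  }
  structure(list(dt = dt, duration = duration, V0 = V0, seed = seed,
                 n_steps = as.integer(n)),
            class = "sim_config")
}

new_voltage_trace <- function(times, Vm, theta, spikes, dt) {
  structure(list(times = times, Vm = Vm, theta = theta,
                 spikes = as.numeric(spikes), dt = dt),
            class = "voltage_trace")
}

#' @export
print.voltage_trace <- function(x, ...) {
  cat(sprintf("<voltage_trace> %d samples, dt = %g ms, %d spike(s)\n",
              length(x$times), x$dt, length(x$spikes)))
  invisible(x)
}

#' @export
as.data.frame.voltage_trace <- function(x, ...) {
  d <- data.frame(time_ms = x$times, Vm_mV = x$Vm)
  if (!is.null(x$theta)) d$theta_mV <- x$theta
  d
}

#' Steady-state spike threshold
#'
#' Evaluates \eqn{\theta_\infty(V_m) = \alpha (V_m - V_i) + V_T + k_a
#' \log(1 + e^{(V_m - V_i)/k_i})} with an overflow-safe softplus, so the
#' asymptotic slope for depolarized potentials is `alpha + ka/ki` and the
#' log term vanishes for strongly hyperpolarized potentials.
#'
#' @param Vm membrane potential (mV), vectorized.
#' @param p an [adaptive_threshold_params()] object.
#' @return Steady-state threshold (mV).
#' @export
steady_state_threshold <- function(Vm, p = adaptive_threshold_params()) {
  if (!all(is.finite(Vm))) stop("`Vm` must be finite")
  x <- (Vm - p$Vi) / p$ki
  sp <- ifelse(x > 30, x, log1p(exp(pmin(x, 30))))
  p$alpha * (Vm - p$Vi) + p$VT + p$ka * sp
}

run_eif <- function(impulses, dt, syn_decay, p, adaptive, q = NULL,
                    theta_fixed = NA_real_, V0, theta0 = NA_real_,
                    return_traces = FALSE) {
  if (adaptive && is.na(theta0)) theta0 <- steady_state_threshold(V0, q)
  if (!adaptive) theta0 <- theta_fixed
  if (is.null(q)) q <- adaptive_threshold_params()
  eif_batch_cpp(impulses, dt, syn_decay, p$Cm, p$gL, p$EL, p$DeltaT,
                p$Vreset, p$refractory, p$spike_margin, adaptive,
                q$tau_theta, q$alpha, q$ka, q$ki, q$VT, q$Vi,
                theta_fixed, V0, theta0, return_traces)
}

check_current <- function(I, cfg) {
  if (length(I) != cfg$n_steps) {
    stop(sprintf("current trace has %d samples but the grid has %d",
                 length(I), cfg$n_steps))
  }
  if (!all(is.finite(I))) stop("current trace contains non-finite values")
}

#' Simulate an adaptive-threshold EIF neuron
#'
#' Forward-Euler co-integration of the membrane potential and the adaptive
#' threshold; the instantaneous threshold enters the exponential
#' spike-initiation term. The threshold starts at its steady state for `V0`
#' and keeps integrating its relaxation law during and after spikes (no
#' spike-triggered jump); the membrane is clamped at the reset potential for
#' the refractory period.
#'
#' @param I input current (pA) sampled on the `cfg` time grid.
#' @param p an [eif_params()] object.
#' @param q an [adaptive_threshold_params()] object.
#' @param cfg a [sim_config()] object.
#' @return A `voltage_trace` with fields `times`, `Vm`, `theta`, `spikes`.
#' @export
simulate_adaptive_eif <- function(I, p = eif_params(),
                                  q = adaptive_threshold_params(),
                                  cfg = sim_config()) {
  check_current(I, cfg)
  res <- run_eif(matrix(I, ncol = 1), cfg$dt, 0, p, TRUE, q, V0 = cfg$V0,
                 return_traces = TRUE)
  new_voltage_trace(seq(0, by = cfg$dt, length.out = cfg$n_steps),
                    res$Vm[, 1], res$theta[, 1], res$spikes[[1]], cfg$dt)
}

#' Simulate a fixed-threshold EIF neuron
#'
#' As [simulate_adaptive_eif()] but with a constant spike threshold.
#'
#' @param I input current (pA) on the `cfg` grid.
#' @param p an [eif_params()] object.
#' @param f a [fixed_threshold_params()] object.
#' @param cfg a [sim_config()] object.
#' @return A `voltage_trace`; `theta` is the constant threshold vector.
#' @export
simulate_fixed_eif <- function(I, p = eif_params(),
                               f = fixed_threshold_params(-53),
                               cfg = sim_config()) {
  check_current(I, cfg)
  res <- run_eif(matrix(I, ncol = 1), cfg$dt, 0, p, FALSE,
                 theta_fixed = f$theta, V0 = cfg$V0, return_traces = TRUE)
  new_voltage_trace(seq(0, by = cfg$dt, length.out = cfg$n_steps),
                    res$Vm[, 1], res$theta[, 1], res$spikes[[1]], cfg$dt)
}

#' Gating rate constants of the HH point-conductance model
#'
#' Returns the six voltage-dependent rate constants (1/ms) for the Na
#' activation (m), Na inactivation (h) and K activation (n) gates, with
#' removable singularities replaced by their limit values. The shift `a`
#' moves the Na inactivation curves along the voltage axis.
#'
#' @param V membrane potential (mV), scalar.
#' @param a inactivation shift (mV).
#' @return Named numeric vector `alpha_m, beta_m, alpha_h, beta_h,
#'   alpha_n, beta_n`, all non-negative.
#' @export
hh_rates <- function(V, a = 0) {
  stopifnot(is.finite(V), is.finite(a))
  hh_rates_cpp(V, a)
}

#' Simulate the Hodgkin-Huxley point-conductance neuron
#'
#' Forward Euler at fine `dt` (default 0.01 ms); gating variables start at
#' their steady state for `V0`. Spikes are registered at upward crossings of
#' 0 mV with a 1 ms dead time. Inputs given in pA are converted to current
#' density via the membrane area in `p`.
#'
#' @param I input current (pA) on the `cfg` grid.
#' @param p an [hh_params()] object.
#' @param cfg a [sim_config()] object; `dt` larger than 0.05 ms triggers an
#'   instability warning.
#' @return A `voltage_trace` (no threshold trajectory).
#' @export
simulate_hh <- function(I, p = hh_params(), cfg = sim_config(dt = 0.01)) {
  check_current(I, cfg)
  if (cfg$dt > 0.05) {
    warning("dt > 0.05 ms risks numerical instability for the HH model")
  }
  conv <- 1e-6 / p$area
  res <- hh_integrate_cpp(I, cfg$dt, p$Cm, p$gNa, p$gK, p$gL, p$ENa, p$EK,
                          p$EL, p$a, conv, cfg$V0)
  new_voltage_trace(seq(0, by = cfg$dt, length.out = cfg$n_steps),
                    res$Vm, NULL, res$spikes, cfg$dt)
}

#' Calibrate a fixed threshold to match an adaptive-model firing rate
#'
#' Finds the constant threshold at which the fixed-threshold EIF matches the
#' overall mean evoked spike count per trial of an adaptive-threshold run,
#' pooled across all conditions of the experiment, by bisection on the
#' threshold. Spike count per trial is monotonically non-increasing in the
#' threshold, so the bracket is refined until the rate mismatch or the
#' bracket width is below tolerance.
#'
#' @param experiment an [experiment_config()] describing the conditions (the
#'   same one used for the adaptive run).
#' @param adaptive_results a `response_dataset` from [run_condition()] with
#'   the adaptive model covering the experiment's conditions.
#' @param bracket numeric length-2: initial threshold bracket (mV).
#' @param tol convergence tolerance on the bracket width (mV).
#' @param calibration_networks number of replicate networks used while
#'   calibrating (a subset keeps calibration cheap; the matched rate is a
#'   population average and stabilizes quickly).
#' @return A [fixed_threshold_params()] object with attributes
#'   `target_rate`, `achieved_rate` and `residual` (spikes/trial).
#' @export
calibrate_fixed_threshold <- function(experiment, adaptive_results,
                                      bracket = c(-60, -38), tol = 0.01,
                                      calibration_networks = NULL) {
  target <- mean(lengths(adaptive_results$spikes))
  if (target <= 0) {
    stop("adaptive run has zero mean firing rate; calibration is undefined")
  }
  cal_cfg <- experiment
  if (!is.null(calibration_networks)) {
    cal_cfg$n_networks <- min(calibration_networks, experiment$n_networks)
  }
  rate_at <- function(theta) {
    ds <- run_condition("fixed_eif", cal_cfg$stim_set, cal_cfg$states,
                        cal_cfg, theta_fixed = theta)
    mean(lengths(ds$spikes))
  }
  lo <- bracket[1]; hi <- bracket[2]
  r_lo <- rate_at(lo); r_hi <- rate_at(hi)
  if (r_lo < target || r_hi > target) {
    stop(sprintf(
      "bracket [%g, %g] does not straddle the target rate %.3f (rates %.3f, %.3f)",
      lo, hi, target, r_lo, r_hi))
  }
  theta <- NA_real_; achieved <- NA_real_
  while (hi - lo > tol) {
    theta <- (lo + hi) / 2
    achieved <- rate_at(theta)
    if (achieved > target) lo <- theta else hi <- theta
  }
  out <- fixed_threshold_params((lo + hi) / 2)
  attr(out, "target_rate") <- target
  attr(out, "achieved_rate") <- achieved
  attr(out, "residual") <- achieved - target
  out
}
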