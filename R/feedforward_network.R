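#' Synapse statistics
#'
#' All 100 feedforward connections share these statistics, resembling layer
#' 4 to layer 2/3 excitatory connections in barrel cortex: EPSC peak 14 pA,
#' release failure probability 0.03, amplitude coefficient of variation 0.3,
#' and a single-exponential EPSC decay of 5 ms. Trial-to-trial variability
#' of these synaptic weights (including failures) is the study's baseline
#' noise source.
#'
#' @param amplitude_mean EPSC peak amplitude (pA).
#' @param failure_rate release failure probability.
#' @param amplitude_cv coefficient of variation of the amplitude.
#' @param epsc_tau EPSC decay time constant (ms).
#' @return An object of class `synapse_params`.
#' @export
synapse_params <- function(amplitude_mean = 14, failure_rate = 0.03,
                           amplitude_cv = 0.3, epsc_tau = 5) {
  stopifnot(failure_rate >= 0, failure_rate <= 1, amplitude_mean > 0,
            epsc_tau > 0, amplitude_cv >= 0)
  structure(list(amplitude_mean = amplitude_mean, failure_rate = failure_rate,
                 amplitude_cv = amplitude_cv, epsc_tau = epsc_tau),
            class = "synapse_params")
}

#' Poisson background-noise specification
#'
#' Independent Poisson spike trains inserted into every presynaptic neuron;
#' `rate_hz` is the mean event rate per presynaptic neuron. Events span the
#' whole `window` and draw fresh synaptic amplitudes from the same synapse
#' statistics as stimulus-evoked spikes.
#'
#' @param rate_hz event rate per presynaptic neuron (Hz).
#' @param window numeric length-2, (start, end) in ms.
#' @return An object of class `noise_spec`.
#' @export
noise_spec <- function(rate_hz = 0, window = c(0, 100)) {
  stopifnot(rate_hz >= 0, length(window) == 2, window[2] >= window[1])
  structure(list(rate_hz = rate_hz, window = window), class = "noise_spec")
}

#' Build a frozen presynaptic network instance
#'
#' Draws the per-synapse latencies once, from a normal law with standard
#' deviation `sigma` (the temporal dispersion of the input) around a common
#' 1 ms mean delay. The latencies stay fixed for the lifetime of the
#' instance, so pattern-encoded stimuli produce identical presynaptic
#' arrival times across trials; replicate "neurons" are obtained by building
#' new instances with different seeds.
#'
#' @param n_pre number of presynaptic neurons.
#' @param sigma latency standard deviation (ms), 0 to 4 in the experiments.
#' @param synapse a [synapse_params()] object.
#' @param seed integer seed; the instance is deterministic given the seed.
#' @return An object of class `network_instance` with a `latencies` field.
#' @export
build_network <- function(n_pre = 100, sigma, synapse = synapse_params(),
                          seed) {
  stopifnot(n_pre >= 1)
  if (sigma < 0) stop("`sigma` must be non-negative")
  lat <- with_seed(seed, rnorm(n_pre, mean = 1, sd = sigma))
  structure(list(n_pre = as.integer(n_pre), sigma = sigma, latencies = lat,
                 synapse = synapse, seed = seed),
            class = "network_instance")
}

#' Single-exponential EPSC kernel
#'
#' Instantaneous rise to `amplitude` at arrival, exponential decay with time
#' constant `tau`; zero before arrival (causality).
#'
#' @param t_since_arrival time since EPSC onset (ms), vectorized.
#' @param amplitude peak current (pA).
#' @param tau decay constant (ms).
#' @return Current (pA).
#' @export
epsc_kernel <- function(t_since_arrival, amplitude = 14, tau = 5) {
  stopifnot(tau > 0)
  ifelse(t_since_arrival < 0, 0, amplitude * exp(-t_since_arrival / tau))
}

draw_amplitudes <- function(n, synapse) {
  ok <- runif(n) >= synapse$failure_rate
  amp <- rnorm(n, synapse$amplitude_mean,
               synapse$amplitude_mean * synapse$amplitude_cv)
  # negative draws truncated at 0 (a < 0.05% event at CV 0.3)
  pmax(amp, 0) * ok
}

#' Draw per-trial effective synaptic amplitudes
#'
#' Per synapse: with probability `failure_rate` the synapse fails (0 pA);
#' otherwise the amplitude is drawn from a normal law with the configured
#' mean and CV, truncated at 0. Deterministic given `trial_seed`.
#'
#' @param net a [build_network()] instance.
#' @param trial_seed integer seed for this trial.
#' @return Numeric vector of length `net$n_pre` (pA).
#' @export
draw_trial_synapses <- function(net, trial_seed) {
  with_seed(trial_seed, draw_amplitudes(net$n_pre, net$synapse))
}

# Deposit synaptic charge impulses on the time grid. `arrivals` in ms,
# `amps` in pA; events falling outside the grid are dropped. Returns a
# vector of length n_steps whose recursive exponential filtering yields the
# summed EPSC trace exactly (the kernel peaks at its arrival sample).
deposit_impulses <- function(arrivals, amps, dt, n_steps) {
  idx <- round(arrivals / dt) + 1
  keep <- idx >= 1 & idx <= n_steps & amps != 0
  imp <- numeric(n_steps)
  if (any(keep)) {
    agg <- rowsum(amps[keep], group = idx[keep])
    imp[as.integer(rownames(agg))] <- agg
  }
  imp
}

# Decay-filter an impulse vector/matrix into the summed EPSC current.
filter_epsc <- function(impulses, dt, tau) {
  r <- exp(-dt / tau)
  as.matrix(stats::filter(impulses, r, method = "recursive"))
}

#' Synthesize the postsynaptic input current for one trial
#'
#' Sums EPSC kernels for the active presynaptic neurons (each spiking once
#' at `spike_time`, arriving after its frozen synaptic latency, with a
#' freshly drawn trial amplitude) plus EPSCs for independent Poisson noise
#' events in every presynaptic neuron.
#'
#' @param net a [build_network()] instance.
#' @param active_set integer ids of the presynaptic neurons active in this
#'   trial (subset of `1:net$n_pre`).
#' @param spike_time presynaptic spike time (ms), 60 in the experiments.
#' @param noise a [noise_spec()] object.
#' @param cfg a [sim_config()] giving the time grid.
#' @param trial_seed integer seed for the trial's stochastic draws.
#' @return Numeric current trace (pA) of length `cfg$n_steps`.
#' @export
synthesize_input_current <- function(net, active_set, spike_time = 60,
                                     noise = noise_spec(), cfg = sim_config(),
                                     trial_seed) {
  active_set <- as.integer(active_set)
  if (length(active_set) && (min(active_set) < 1 || max(active_set) > net$n_pre)) {
    stop("`active_set` contains ids outside 1..n_pre")
  }
  imp <- with_seed(trial_seed, {
    amps <- draw_amplitudes(length(active_set), net$synapse)
    arr <- spike_time + net$latencies[active_set]
    v <- deposit_impulses(arr, amps, cfg$dt, cfg$n_steps)
    if (noise$rate_hz > 0) {
      span <- noise$window[2] - noise$window[1]
      n_ev <- rpois(1, net$n_pre * noise$rate_hz * span / 1000)
      if (n_ev > 0) {
        t_ev <- runif(n_ev, noise$window[1], noise$window[2])
        a_ev <- draw_amplitudes(n_ev, net$synapse)
        v <- v + deposit_impulses(t_ev, a_ev, cfg$dt, cfg$n_steps)
      }
    }
    v
  })
  drop(filter_epsc(imp, cfg$dt, net$synapse$epsc_tau))
}
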