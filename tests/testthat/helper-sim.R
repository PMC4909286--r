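# Shared fixtures built in code: time grids, ramp stimuli, quick experiment
# configurations at reduced replicate counts.

time_grid <- function(cfg) seq(0, by = cfg$dt, length.out = cfg$n_steps)

# linear current ramp (pA/ms) starting at `t_on`
ramp_current <- function(cfg, slope_pa_ms, t_on = 100) {
  tt <- time_grid(cfg)
  pmax(0, tt - t_on) * slope_pa_ms
}

quick_cfg <- function(..., sigma_grid = c(0.5, 2, 4), n_trials = 30,
                      n_networks = 4, seed = 101) {
  experiment_config(sigma_grid = sigma_grid, n_trials = n_trials,
                    n_networks = n_networks, seed = seed, ...)
}

# ramp-driven trace of a model plus its detected threshold, for the
# threshold-metrology checks
ramp_threshold_case <- function(slope_pa_ms, model = c("adaptive", "fixed"),
                                theta = -50, smooth_ms = 1) {
  model <- match.arg(model)
  cfg <- sim_config(dt = 0.1, duration = 200, V0 = -70)
  I <- ramp_current(cfg, slope_pa_ms)
  tr <- if (model == "adaptive") {
    simulate_adaptive_eif(I, cfg = cfg)
  } else {
    simulate_fixed_eif(I, f = fixed_threshold_params(theta), cfg = cfg)
  }
  t1 <- tr$spikes[1]
  sw <- preprocess(make_sweep(time_grid(cfg), tr$Vm, onset = 100),
                   smooth_ms = smooth_ms)
  est <- detect_spike_threshold(sw, search = c(100, t1), min_upstroke = 3)
  i1 <- round(t1 / cfg$dt) + 1
  list(trace = tr, est = est, theta_at_spike = tr$theta[i1], spike_time = t1)
}
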