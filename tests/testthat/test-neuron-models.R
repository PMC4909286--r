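test_that("steady-state threshold matches the closed form and its limits", {
  p <- adaptive_threshold_params()
  # independent evaluation of the formula, term by term
  direct <- function(v) {
    p$alpha * (v - p$Vi) + p$VT + p$ka * log(1 + exp((v - p$Vi) / p$ki))
  }
  expect_equal(steady_state_threshold(-55), -50 + 7 * log(2), tolerance = 1e-12)
  expect_equal(steady_state_threshold(-70), direct(-70), tolerance = 1e-12)
  expect_equal(steady_state_threshold(-70), -53.34085, tolerance = 1e-5)
  # hyperpolarized limit: the log term vanishes
  lin <- p$alpha * (-200 - p$Vi) + p$VT
  expect_lt(abs(steady_state_threshold(-200) - lin), 1e-6)
  # depolarized: overflow-safe, asymptotic slope alpha + ka/ki
  expect_true(is.finite(steady_state_threshold(500)))
  sl <- (steady_state_threshold(401) - steady_state_threshold(400))
  expect_equal(sl, p$alpha + p$ka / p$ki, tolerance = 1e-6)
  expect_error(steady_state_threshold(NaN), "finite")
})

test_that("quiescent EIF neurons sit at their fixed point", {
  cfg <- sim_config(dt = 0.1, duration = 100, V0 = -70)
  I0 <- numeric(cfg$n_steps)
  tra <- simulate_adaptive_eif(I0, cfg = cfg)
  expect_lt(max(abs(tra$Vm + 70)), 1e-6)
  expect_length(tra$spikes, 0)
  # theta starts and stays at its steady state for V0
  expect_lt(max(abs(tra$theta - steady_state_threshold(-70))), 1e-6)
  trf <- simulate_fixed_eif(I0, f = fixed_threshold_params(-53), cfg = cfg)
  expect_lt(max(abs(trf$Vm + 70)), 1e-6)
  expect_length(trf$spikes, 0)
})

test_that("theta relaxes exponentially at clamped Vm", {
  # start away from the steady state by initializing at V0 = -60 and
  # clamping the membrane with a large negative-feedback-free trick:
  # instead, verify against the closed form along the simulated trajectory
  cfg <- sim_config(dt = 0.01, duration = 60, V0 = -60)
  q <- adaptive_threshold_params()
  # V0 = -60 with I = 0: Vm relaxes toward EL; theta follows theta_inf(Vm).
  # Use the first 2 ms where Vm is approximately constant only as a sanity
  # band, then check the full ODE solution numerically via fine-dt Euler as
  # the oracle for the coarse run.
  tr_fine <- simulate_adaptive_eif(numeric(cfg$n_steps), cfg = cfg)
  cfg2 <- sim_config(dt = 0.1, duration = 60, V0 = -60)
  tr_coarse <- simulate_adaptive_eif(numeric(cfg2$n_steps), cfg = cfg2)
  idx <- seq(1, cfg$n_steps, by = 10)
  expect_lt(max(abs(tr_fine$theta[idx] - tr_coarse$theta)), 0.05)
  # analytic check in a truly clamped setting: theta ODE alone
  theta0 <- steady_state_threshold(-60)
  tinf <- steady_state_threshold(-70)
  t_end <- tail(tr_fine$times, 1)
  closed <- tinf + (theta0 - tinf) * exp(-t_end / q$tau_theta)
  # Vm reaches EL quickly (tau_m = 5 ms), so late theta is within the band
  # between the clamped-at--70 solution and theta_inf(-70)
  expect_lt(abs(tail(tr_fine$theta, 1) - tinf), abs(closed - tinf) + 0.2)
})

test_that("adaptive threshold at the spike is lower for faster ramps", {
  fast <- ramp_threshold_case(60)
  slow <- ramp_threshold_case(25)
  expect_lt(fast$theta_at_spike, slow$theta_at_spike)
})

test_that("refractory period and reset are honored", {
  cfg <- sim_config(dt = 0.1, duration = 150, V0 = -70)
  I <- rep(400, cfg$n_steps)  # strong sustained drive, repetitive firing
  tr <- simulate_adaptive_eif(I, cfg = cfg)
  expect_gt(length(tr$spikes), 3)
  expect_true(all(diff(tr$spikes) >= 0.5 - 1e-9))
  # Vm is clamped at Vreset during the refractory period
  i1 <- round(tr$spikes[1] / cfg$dt) + 1
  expect_equal(tr$Vm[i1 + 2], -70)
})

test_that("halving dt moves spike times by less than one coarse step", {
  cfg1 <- sim_config(dt = 0.1, duration = 150, V0 = -70)
  cfg2 <- sim_config(dt = 0.05, duration = 150, V0 = -70)
  I1 <- ramp_current(cfg1, 40)
  I2 <- ramp_current(cfg2, 40)
  t1 <- simulate_adaptive_eif(I1, cfg = cfg1)$spikes[1]
  t2 <- simulate_adaptive_eif(I2, cfg = cfg2)$spikes[1]
  expect_lt(abs(t1 - t2), 0.1 + 1e-9)
})

test_that("lowering the fixed threshold never decreases the spike count", {
  cfg <- sim_config(dt = 0.1, duration = 150, V0 = -70)
  I <- ramp_current(cfg, 30)
  n_hi <- length(simulate_fixed_eif(I, f = fixed_threshold_params(-50), cfg = cfg)$spikes)
  n_lo <- length(simulate_fixed_eif(I, f = fixed_threshold_params(-55), cfg = cfg)$spikes)
  expect_gte(n_lo, n_hi)
})

test_that("HH gating rates match limits and stay non-negative", {
  r <- hh_rates(-45)
  expect_equal(unname(r["alpha_m"]), 1.28, tolerance = 1e-6)
  expect_equal(unname(hh_rates(-51)["alpha_h"]), 0.128, tolerance = 1e-9)
  expect_equal(unname(hh_rates(-43)["alpha_n"]), 0.032 * 5, tolerance = 1e-6)
  for (v in c(-90, -70, -45, -18, 0, 40)) {
    expect_true(all(hh_rates(v) >= 0))
    expect_true(all(is.finite(hh_rates(v))))
  }
})

test_that("HH model rests near its fixed point and spikes to steps", {
  cfg <- sim_config(dt = 0.01, duration = 100, V0 = -70)
  tr <- simulate_hh(numeric(cfg$n_steps), cfg = cfg)
  v_end <- tail(tr$Vm, 1)
  dv <- diff(tail(tr$Vm, 2000))
  expect_lt(abs(v_end + 70), 1)
  expect_lt(max(abs(dv)) / cfg$dt, 1e-3)
  step <- c(numeric(2000), rep(200, cfg$n_steps - 2000))
  tr2 <- simulate_hh(step, cfg = cfg)
  expect_gte(length(tr2$spikes), 1)
  expect_gt(max(tr2$Vm), 0)
  expect_warning(simulate_hh(numeric(1000), cfg = sim_config(dt = 0.1, duration = 100, V0 = -70)),
                 "instability")
})

test_that("Na inactivation half-voltage is near -46 mV for a = 0", {
  V <- seq(-50, -36, by = 0.5)
  hinf <- vapply(V, function(v) {
    r <- hh_rates(v)
    unname(r["alpha_h"] / (r["alpha_h"] + r["beta_h"]))
  }, numeric(1))
  fit <- nls(hinf ~ 1 / (1 + exp((V - vh) / k)),
             start = list(vh = -45, k = 4))
  expect_equal(unname(coef(fit)["vh"]), -46, tolerance = 0.02)
})

test_that("fixed-threshold calibration is self-consistent", {
  ss <- make_rate_stimulus_set(50, 60, 5, 100)
  cfg <- quick_cfg(sigma_grid = c(0.5, 2), n_trials = 25, n_networks = 3,
                   stim_set = ss, states = state_condition(-65))
  theta0 <- -50
  ds <- run_condition("fixed_eif", ss, cfg$states, cfg, theta_fixed = theta0)
  cal <- calibrate_fixed_threshold(cfg, ds, tol = 0.02)
  expect_lt(abs(cal$theta - theta0), 0.35)
  # zero-rate refusal
  empty <- ds
  empty$spikes <- rep(list(numeric(0)), nrow(ds))
  expect_error(calibrate_fixed_threshold(cfg, empty), "zero mean firing rate")
})
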