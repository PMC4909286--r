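test_that("EPSC kernel is causal, peaks at arrival and decays with tau", {
  expect_equal(epsc_kernel(0, 14, 5), 14)
  expect_equal(epsc_kernel(5, 14, 5), 14 / exp(1), tolerance = 1e-12)
  expect_equal(epsc_kernel(-1, 14, 5), 0)
  t <- seq(-2, 20, by = 0.1)
  k <- epsc_kernel(t, 14, 5)
  expect_true(all(k[t < 0] == 0))
  expect_true(all(diff(k[t >= 0]) <= 0))
})

test_that("network latencies follow the configured dispersion", {
  net0 <- build_network(100, 0, seed = 1)
  expect_true(all(net0$latencies == net0$latencies[1]))
  net <- build_network(100, 2.5, seed = 2)
  se <- 2.5 / sqrt(2 * (100 - 1))  # approx SE of a sample SD
  expect_lt(abs(sd(net$latencies) - 2.5), 3 * se * 2)
  expect_identical(build_network(100, 2.5, seed = 7)$latencies,
                   build_network(100, 2.5, seed = 7)$latencies)
  expect_error(build_network(100, -1, seed = 1), "non-negative")
})

test_that("trial synapse draws reproduce failure rate and amplitude CV", {
  net <- build_network(100, 1, seed = 3)
  draws <- unlist(lapply(1:1000, function(i) draw_trial_synapses(net, i)))
  n <- length(draws)
  fail_frac <- mean(draws == 0)
  expect_lt(abs(fail_frac - 0.03), 3 * sqrt(0.03 * 0.97 / n))
  ok <- draws[draws > 0]
  expect_lt(abs(sd(ok) / mean(ok) - 0.3), 0.3 * 0.02 + 3 * 0.3 / sqrt(n))
  expect_identical(draw_trial_synapses(net, 42), draw_trial_synapses(net, 42))
})

test_that("input current synthesis obeys superposition and peak placement", {
  cfg <- sim_config(dt = 0.1, duration = 100, V0 = -70)
  # deterministic synapse: no failures, no amplitude spread
  syn <- synapse_params(failure_rate = 0, amplitude_cv = 0)
  net <- build_network(100, 0, synapse = syn, seed = 5)
  # single synapse: peak 14 pA at 60 ms + latency (1 ms mean)
  I1 <- synthesize_input_current(net, 1, 60, noise_spec(0), cfg, trial_seed = 9)
  expect_equal(max(I1), 14, tolerance = 1e-9)
  expect_equal(which.max(I1), round(61 / 0.1) + 1)
  # empty set, no noise: identically zero
  I0 <- synthesize_input_current(net, integer(0), 60, noise_spec(0), cfg, 9)
  expect_true(all(I0 == 0))
  # superposition of disjoint active sets under identical draws
  Ia <- synthesize_input_current(net, 1:10, 60, noise_spec(0), cfg, 9)
  Ib <- synthesize_input_current(net, 11:25, 60, noise_spec(0), cfg, 9)
  Iab <- synthesize_input_current(net, 1:25, 60, noise_spec(0), cfg, 9)
  expect_equal(Iab, Ia + Ib, tolerance = 1e-9)
  expect_error(synthesize_input_current(net, 101, 60, noise_spec(0), cfg, 9),
               "n_pre")
})

test_that("mean summed charge matches active count x mean amplitude x tau", {
  cfg <- sim_config(dt = 0.1, duration = 300, V0 = -70)
  net <- build_network(100, 1, seed = 11)
  charges <- vapply(1:150, function(s) {
    I <- synthesize_input_current(net, 1:40, 60, noise_spec(0), cfg, s)
    sum(I) * cfg$dt
  }, numeric(1))
  expected <- 40 * (1 - 0.03) * 14 * 5
  # truncation of the decay tail and Monte-Carlo error allow a few percent
  expect_lt(abs(mean(charges) - expected) / expected, 0.05)
})

test_that("Poisson noise events arrive at the configured rate", {
  cfg <- sim_config(dt = 0.1, duration = 1000, V0 = -70)
  net <- build_network(100, 1, synapse = synapse_params(failure_rate = 0),
                       seed = 13)
  counts <- vapply(1:30, function(s) {
    I <- synthesize_input_current(net, integer(0), 60,
                                  noise_spec(5, c(0, 1000)), cfg, s)
    # each event deposits one impulse; count decay-filtered current jumps
    imp <- I - c(0, I[-length(I)]) * exp(-cfg$dt / 5)
    sum(imp > 1e-9)
  }, numeric(1))
  lam <- 100 * 5 * 1000 / 1000
  expect_lt(abs(mean(counts) - lam), 3 * sqrt(lam / 30) + 0.05 * lam)
})
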