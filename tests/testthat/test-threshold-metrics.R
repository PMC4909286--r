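test_that("preprocessing measures the resting potential correctly", {
  tt <- seq(0, 200, by = 0.2)
  sw <- preprocess(make_sweep(tt, rep(-70, length(tt)), onset = 100))
  expect_equal(sw$Vrest, -70)
  expect_equal(sw$Vm, rep(-70, length(tt)))  # smoothing is the identity
  # linear baseline: mean over [onset-40, onset) is the value at the
  # window midpoint
  v <- -70 + 0.01 * tt
  swl <- preprocess(make_sweep(tt, v, onset = 100))
  expect_equal(swl$Vrest, -70 + 0.01 * (100 - 20), tolerance = 1e-3)
  expect_error(preprocess(make_sweep(tt, v, onset = 20)), "baseline")
})

test_that("running-window smoothing reduces white-noise variance as 1/k", {
  tt <- seq(0, 300, by = 0.2)
  set.seed(5)
  v <- rnorm(length(tt))
  sw <- preprocess(make_sweep(tt, v, onset = 100), smooth_ms = 1)
  mid <- 200:1300
  ratio <- var(sw$Vm[mid]) / var(v[mid])
  expect_lt(abs(ratio - 1 / 5), 0.05)
})

test_that("state grouping bins resting potentials half-open", {
  g <- group_by_state(c(-71, -84, -56, -50, -86),
                      edges = seq(-85, -55, by = 10))
  expect_equal(as.numeric(as.character(g)), c(-70, -80, -60, NA, NA))
  g5 <- group_by_state(seq(-82, -58, by = 1), seq(-82.5, -57.5, by = 5))
  expect_equal(nlevels(g5), 5)
  expect_true(all(!is.na(g5)))
})

test_that("EPSP features recover ramp slopes and flag flat segments", {
  tt <- seq(0, 10, by = 0.1)
  f <- epsp_features(tt, -70 + 2 * tt, vrest = -70)
  expect_equal(f$Sl_EPSP, 2, tolerance = 1e-6)
  expect_equal(f$A_EPSP, 20, tolerance = 1e-9)
  flat <- epsp_features(tt, rep(-70, length(tt)), vrest = -70)
  expect_equal(flat$A_EPSP, 0)
  expect_true(flat$flagged)
})

test_that("curvature detection finds a constructed slope break", {
  # linear segment joined to an accelerating upstroke at a known time
  dt <- 0.2
  tt <- seq(0, 160, by = dt)
  t_star <- 120
  v <- -70 + 0.5 * pmax(0, tt - 100)
  on <- tt >= t_star
  v[on] <- v[tt == t_star] + 0.5 * (tt[on] - t_star) +
    8 * (tt[on] - t_star)^2
  v <- pmin(v, 20)
  est <- detect_spike_threshold(preprocess(make_sweep(tt, v, onset = 100)))
  expect_true(est$spiking)
  t_hat <- est$St + 100
  expect_lt(abs(t_hat - t_star), 1.25)
  # subthreshold sweep: explicit NS, no exception
  ns <- detect_spike_threshold(preprocess(make_sweep(tt, -70 + 0.2 * pmax(0, tt - 100),
                                                     onset = 100)))
  expect_false(ns$spiking)
  expect_true(is.na(ns$Vt))
})

test_that("detected thresholds track the adaptive model within 1.5 mV", {
  for (k in c(25, 40, 60, 90)) {
    cs <- ramp_threshold_case(k, "adaptive")
    expect_true(cs$est$spiking)
    expect_lt(abs(cs$est$Vt - cs$theta_at_spike), 1.5)
  }
})

test_that("re-estimated fixed-model thresholds are constant across slopes", {
  # matched 5-sample smoothing window for the 10 kHz simulated traces
  vt <- vapply(c(25, 40, 60, 90), function(k) {
    ramp_threshold_case(k, "fixed", theta = -50, smooth_ms = 0.5)$est$Vt
  }, numeric(1))
  expect_lt(sd(vt), 0.5)
})

test_that("threshold-vs-slope regressions separate adaptive from fixed", {
  runs <- lapply(c(25, 35, 50, 70, 90), function(k) {
    a <- ramp_threshold_case(k, "adaptive")
    f <- ramp_threshold_case(k, "fixed", theta = -50)
    c(a$est$Vt, a$est$slope_pre, f$est$Vt, f$est$slope_pre)
  })
  m <- do.call(rbind, runs)
  fa <- fit_threshold_vs_slope(data.frame(Vt = m[, 1], slope_pre = m[, 2]))
  ff <- fit_threshold_vs_slope(data.frame(Vt = m[, 3], slope_pre = m[, 4]))
  expect_lt(fa$slope, -1.5)
  expect_lt(abs(ff$slope), abs(fa$slope) / 3)
})

test_that("the sigmoid fit recovers known parameters in both orientations", {
  x <- seq(0, 4, by = 0.25)
  p_dec <- 0.02 + 0.9 / (1 + exp((x - 2.2) / 0.31))
  f <- fit_sigmoid(x, p_dec)
  expect_true(f$converged)
  expect_equal(f$midpoint, 2.2, tolerance = 1e-3)
  expect_equal(f$s, 0.31, tolerance = 1e-3)
  expect_equal(f$direction, "decreasing")
  xN <- seq(20, 60, by = 4)
  p_inc <- 1 / (1 + exp(-(xN - 37) / 2.5))
  g <- fit_sigmoid(xN, p_inc)
  expect_equal(g$midpoint, 37, tolerance = 1e-3)
  expect_equal(g$s, 2.5, tolerance = 1e-3)
  expect_equal(g$direction, "increasing")
  expect_warning(fit_sigmoid(x, rep(0, length(x))), "degenerate")
})

test_that("collinear threshold estimates give an exact regression", {
  d <- data.frame(slope_pre = c(1, 2, 3, 4), Vt = -40 - 0.8 * c(1, 2, 3, 4))
  fit <- fit_threshold_vs_slope(d)
  expect_equal(fit$slope, -0.8, tolerance = 1e-12)
  expect_equal(fit$r2, 1, tolerance = 1e-12)
  expect_error(fit_threshold_vs_slope(d[1:2, ]), "at least 3")
})
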