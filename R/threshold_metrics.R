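#' Intracellular voltage sweep
#'
#' Container for one recorded or simulated sweep: a uniformly sampled
#' membrane-potential trace with its stimulus metadata. The same metrology
#' is applied to simulated traces and (synthetic) recordings.
#'
#' @param times sample times (ms), uniformly spaced.
#' @param Vm membrane potential (mV).
#' @param stimulus_id stimulus identifier.
#' @param onset stimulus onset (ms), within the trace.
#' @param state optional holding-state label.
#' @return An object of class `sweep`.
#' @export
make_sweep <- function(times, Vm, stimulus_id = NA, onset, state = NA) {
  stopifnot(length(times) == length(Vm), length(times) >= 2)
  dt <- diff(times[1:2])
  if (max(abs(diff(times) - dt)) > 1e-6) stop("`times` must be uniform")
  if (onset < times[1] || onset > times[length(times)]) {
    stop("`onset` must lie within the trace")
  }
  structure(list(times = times, Vm = Vm, stimulus_id = stimulus_id,
                 onset = onset, state = state, dt = dt, smoothed = FALSE,
                 Vrest = NA_real_),
            class = "sweep")
}

#' @export
print.sweep <- function(x, ...) {
  cat(sprintf("<sweep> %d samples @ %g ms, onset %g ms%s\n",
              length(x$times), x$dt, x$onset,
              if (x$smoothed) sprintf(", Vrest %.2f mV", x$Vrest) else ""))
  invisible(x)
}

moving_average <- function(x, k) {
  if (k <= 1) return(x)
  sm <- as.numeric(stats::filter(x, rep(1 / k, k), sides = 2))
  sm[is.na(sm)] <- x[is.na(sm)]  # keep raw values at the edges
  sm
}

#' Smooth a sweep and measure its resting potential
#'
#' Applies a centered 1 ms running-window average and computes the resting
#' membrane potential as the mean over the 40 ms preceding stimulus onset.
#'
#' @param sweep a [make_sweep()] object with at least 40 ms of pre-stimulus
#'   baseline.
#' @param smooth_ms smoothing window (ms).
#' @param baseline_ms baseline window before onset (ms).
#' @return The sweep with smoothed `Vm`, `smoothed = TRUE` and `Vrest` set.
#' @export
preprocess <- function(sweep, smooth_ms = 1, baseline_ms = 40) {
  if (sweep$onset - sweep$times[1] < baseline_ms - 1e-9) {
    stop(sprintf("need %g ms of pre-stimulus baseline, have %g",
                 baseline_ms, sweep$onset - sweep$times[1]))
  }
  k <- max(1L, round(smooth_ms / sweep$dt))
  if (k %% 2 == 0) k <- k + 1L  # centered window
  sweep$Vm <- moving_average(sweep$Vm, k)
  sweep$smooth_ms <- k * sweep$dt
  base <- sweep$times >= sweep$onset - baseline_ms & sweep$times < sweep$onset
  sweep$Vrest <- mean(sweep$Vm[base])
  sweep$smoothed <- TRUE
  sweep
}

#' Detect the spike threshold of one sweep
#'
#' The spike threshold is the membrane potential at which the discrete
#' second derivative of the (smoothed) trace reaches its maximum during the
#' spike upstroke; ties are broken by the earliest sample. The upstroke is
#' located from the maximum of dV/dt inside the search window; a sweep
#' whose maximal slope stays below `min_upstroke` is reported as
#' non-spiking (NS) rather than raising an error.
#'
#' @param sweep a preprocessed [make_sweep()] (preprocessed automatically
#'   if not).
#' @param search numeric length-2 (ms): window to search, default from
#'   onset to end of trace.
#' @param min_upstroke minimal peak dV/dt (mV/ms) to call a spike.
#' @param pre_slope_ms window (ms) before the threshold point over which
#'   the preceding depolarization slope is fitted.
#' @return An object of class `threshold_estimate` with fields `Vt` (mV),
#'   `St` (spike latency from onset, ms), `slope_pre` (mV/ms) and
#'   `spiking`; for NS sweeps `spiking = FALSE` and the fields are `NA`.
#' @export
detect_spike_threshold <- function(sweep, search = NULL, min_upstroke = 8,
                                   pre_slope_ms = 2) {
  if (!sweep$smoothed) sweep <- preprocess(sweep)
  if (is.null(search)) search <- c(sweep$onset, sweep$times[length(sweep$times)])
  ns <- structure(list(Vt = NA_real_, St = NA_real_, slope_pre = NA_real_,
                       spiking = FALSE), class = "threshold_estimate")
  dt <- sweep$dt
  v <- sweep$Vm
  n <- length(v)
  dv <- c(NA, (v[3:n] - v[1:(n - 2)]) / (2 * dt), NA)
  d2v <- c(NA, (v[3:n] - 2 * v[2:(n - 1)] + v[1:(n - 2)]) / dt^2, NA)
  inwin <- which(sweep$times >= search[1] & sweep$times <= search[2])
  inwin <- inwin[!is.na(dv[inwin])]
  if (!length(inwin) || max(dv[inwin]) < min_upstroke) return(ns)
  i_slope <- inwin[which.max(dv[inwin])]
  # the threshold precedes the steepest point of the upstroke: search the
  # curvature maximum from shortly before the peak slope up to it
  i_lo <- max(min(inwin), i_slope - round(3 / dt))
  seg <- i_lo:i_slope
  seg <- seg[!is.na(d2v[seg])]
  i_thr <- seg[which.max(d2v[seg])]  # which.max returns the earliest tie
  Vt <- v[i_thr]
  St <- sweep$times[i_thr] - sweep$onset
  # under box smoothing the curvature maximum lands about half a smoothing
  # window after the true onset, and samples within another half window of
  # it mix in the upstroke; end the pre-slope window a full smoothing
  # window before the detected point
  offs <- if (!is.null(sweep$smooth_ms)) sweep$smooth_ms else 0
  pre <- which(sweep$times >= sweep$times[i_thr] - offs - pre_slope_ms &
                 sweep$times < sweep$times[i_thr] - offs)
  slope_pre <- if (length(pre) >= 2) {
    unname(stats::coef(stats::lm(v[pre] ~ sweep$times[pre]))[2])
  } else NA_real_
  structure(list(Vt = Vt, St = St, slope_pre = slope_pre, spiking = TRUE),
            class = "threshold_estimate")
}

#' @export
print.threshold_estimate <- function(x, ...) {
  if (!x$spiking) cat("<threshold_estimate> NS (no spike)\n")
  else cat(sprintf("<threshold_estimate> Vt = %.2f mV, St = %.2f ms, pre-slope = %.2f mV/ms\n",
                   x$Vt, x$St, x$slope_pre))
  invisible(x)
}

#' EPSP amplitude and slope of a depolarizing segment
#'
#' `A_EPSP` is the peak depolarization above the resting potential;
#' `Sl_EPSP` is the least-squares slope of the trace over the 20-80% rise
#' to that peak.
#'
#' @param times,Vm the segment samples (ms, mV).
#' @param vrest resting potential (mV) for the baseline.
#' @param rise_frac numeric length-2: fractional rise levels delimiting the
#'   slope window.
#' @return List with `A_EPSP` (mV) and `Sl_EPSP` (mV/ms); a
#'   non-depolarizing segment yields zero amplitude and `NA` slope with the
#'   `flagged` field set.
#' @export
epsp_features <- function(times, Vm, vrest, rise_frac = c(0.2, 0.8)) {
  stopifnot(length(times) == length(Vm))
  i_pk <- which.max(Vm)
  A <- Vm[i_pk] - vrest
  if (A <= 0) {
    return(list(A_EPSP = 0, Sl_EPSP = NA_real_, flagged = TRUE))
  }
  rise <- seq_len(i_pk)
  lo <- vrest + rise_frac[1] * A
  hi <- vrest + rise_frac[2] * A
  i0 <- rise[which(Vm[rise] >= lo)[1]]
  i1 <- rise[which(Vm[rise] >= hi)[1]]
  if (is.na(i0) || is.na(i1) || i1 <= i0) {
    sl <- NA_real_
  } else {
    w <- i0:i1
    sl <- unname(stats::coef(stats::lm(Vm[w] ~ times[w]))[2])
  }
  list(A_EPSP = A, Sl_EPSP = sl, flagged = FALSE)
}

#' Fit a four-parameter logistic to spike probabilities
#'
#' Least-squares fit of
#' \deqn{p(x) = lower + \frac{upper - lower}{1 + e^{\pm(x - mid)/s}}}
#' with the sign chosen by the observed trend, so both decreasing
#' transitions (spike probability vs the temporal dispersion sigma) and
#' increasing ones (vs the number of active inputs) are handled. `s` is the
#' positive scale parameter: smaller `s` means a steeper transition.
#'
#' @param x stimulus parameter values (at least 4 distinct).
#' @param p spike probabilities in `[0, 1]`.
#' @return An object of class `sigmoid_fit` with fields `s`, `midpoint`,
#'   `lower`, `upper`, `direction`, `rss` and `converged`.
#' @export
fit_sigmoid <- function(x, p) {
  stopifnot(length(x) == length(p), all(p >= -1e-9 & p <= 1 + 1e-9))
  if (length(unique(x)) < 4) stop("need at least 4 distinct x values")
  if (length(unique(round(p, 10))) == 1) {
    warning("degenerate probabilities (constant); no fit")
    return(structure(list(s = NA_real_, midpoint = NA_real_,
                          lower = NA_real_, upper = NA_real_,
                          direction = NA, rss = NA_real_, converged = FALSE),
                     class = "sigmoid_fit"))
  }
  decreasing <- stats::cor(x, p) < 0
  sgn <- if (decreasing) 1 else -1
  half <- (max(p) + min(p)) / 2
  m0 <- x[which.min(abs(p - half))]
  fit <- NULL
  for (s0 in diff(range(x)) / c(8, 3, 20, 1.5)) {  # multi-start on the scale
    start <- list(lower = max(0, min(p)), upper = min(1, max(p)),
                  mid = m0, s = s0)
    fit <- try(minpack.lm::nlsLM(
      p ~ lower + (upper - lower) / (1 + exp(sgn * (x - mid) / s)),
      start = start,
      lower = c(lower = 0, upper = 0, mid = min(x) - diff(range(x)),
                s = 1e-4),
      upper = c(lower = 1, upper = 1, mid = max(x) + diff(range(x)),
                s = diff(range(x)) * 10),
      control = minpack.lm::nls.lm.control(maxiter = 200)), silent = TRUE)
    if (inherits(fit, "try-error")) {
      # an exact fit with a parameter pinned at its box constraint makes
      # the bounded problem singular; retry unconstrained
      fit <- try(minpack.lm::nlsLM(
        p ~ lower + (upper - lower) / (1 + exp(sgn * (x - mid) / s)),
        start = start,
        control = minpack.lm::nls.lm.control(maxiter = 200)), silent = TRUE)
    }
    if (!inherits(fit, "try-error")) break
  }
  if (inherits(fit, "try-error")) {
    warning("sigmoid fit did not converge")
    return(structure(list(s = NA_real_, midpoint = NA_real_,
                          lower = NA_real_, upper = NA_real_,
                          direction = if (decreasing) "decreasing" else "increasing",
                          rss = NA_real_, converged = FALSE),
                     class = "sigmoid_fit"))
  }
  cf <- stats::coef(fit)
  structure(list(s = unname(cf["s"]), midpoint = unname(cf["mid"]),
                 lower = unname(cf["lower"]), upper = unname(cf["upper"]),
                 direction = if (decreasing) "decreasing" else "increasing",
                 rss = sum(stats::residuals(fit)^2), converged = TRUE),
            class = "sigmoid_fit")
}

#' @export
print.sigmoid_fit <- function(x, ...) {
  cat(sprintf("<sigmoid_fit> s = %.3f, midpoint = %.3f (%s)\n",
              x$s, x$midpoint, x$direction))
  invisible(x)
}

#' Linear regression of spike threshold on preceding slope
#'
#' Ordinary least squares `Vt ~ slope_pre` over a set of threshold
#' estimates; the fitted slope (in ms) quantifies threshold adaptation: it
#' is negative for adaptive-threshold neurons and near zero for
#' fixed-threshold ones.
#'
#' @param estimates a list of `threshold_estimate` objects, or a data frame
#'   with columns `Vt` and `slope_pre`. Non-spiking entries are dropped.
#' @return An object of class `regression_fit` with fields `slope` (ms),
#'   `intercept` (mV), `r2` and `n`.
#' @export
fit_threshold_vs_slope <- function(estimates) {
  if (is.data.frame(estimates)) {
    d <- estimates
  } else {
    d <- data.frame(
      Vt = vapply(estimates, `[[`, numeric(1), "Vt"),
      slope_pre = vapply(estimates, `[[`, numeric(1), "slope_pre"))
  }
  d <- d[is.finite(d$Vt) & is.finite(d$slope_pre), ]
  if (nrow(d) < 3) stop("need at least 3 spiking estimates")
  fit <- stats::lm(Vt ~ slope_pre, data = d)
  r2 <- summary(fit)$r.squared
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r2 = r2, n = nrow(d)),
            class = "regression_fit")
}

#' @export
print.regression_fit <- function(x, ...) {
  cat(sprintf("<regression_fit> slope = %.3f ms, intercept = %.2f mV, r2 = %.3f (n = %d)\n",
              x$slope, x$intercept, x$r2, x$n))
  invisible(x)
}

#' Group sweeps into membrane states by resting potential
#'
#' Half-open binning `[lo, hi)` of resting potentials on a monotone edge
#' grid, e.g. `seq(-85, -55, by = 10)` for 3 states or
#' `seq(-82.5, -57.5, by = 5)` for 5 states; out-of-range values are
#' excluded (`NA`).
#'
#' @param vrest resting potentials (mV).
#' @param edges monotone increasing bin edges (mV).
#' @return Factor of state labels (interval midpoints, mV); `NA` for
#'   out-of-range sweeps.
#' @export
group_by_state <- function(vrest, edges = seq(-85, -55, by = 10)) {
  stopifnot(length(edges) >= 2, all(diff(edges) > 0))
  idx <- findInterval(vrest, edges)
  idx[vrest >= edges[length(edges)]] <- NA  # right-open top edge
  idx[idx == 0] <- NA
  mids <- (edges[-length(edges)] + edges[-1]) / 2
  factor(mids[idx], levels = mids)
}
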