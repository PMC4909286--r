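#' Parameters for synthetic in-vitro-like recording sessions
#'
#' Describes an emulated whole-cell current-clamp dataset: cells held at
#' several resting states (set via the leak reversal potential), stimulated
#' with ramp currents of distinct rising slopes, with spike thresholds
#' obeying a configurable negative linear threshold-versus-slope law plus
#' trial noise. The defaults emulate 11 cells at -80/-70/-60 mV with 4
#' equiprobable ramp stimuli (2 bits of stimulus entropy) and a threshold
#' law of -0.95 ms slope with 1.5 mV residual SD.
#'
#' @param n_cells number of cells (replicate "networks" for decoding).
#' @param states_mV resting-state targets (mV), set via `E_L`.
#' @param ramp_slopes_mV_ms designed membrane-potential rising slopes of
#'   the ramp stimuli (mV/ms); must be distinct and at least 2.
#' @param trials_per_stimulus_per_state trials per (stimulus, state).
#' @param threshold_law list with `slope` (ms), `intercept` (mV) and
#'   `resid_sd` (mV): the per-trial spike threshold is
#'   `intercept + slope * (pre-spike Vm slope) + noise`.
#' @param onset_jitter_sd trial-to-trial jitter of the stimulus onset (ms).
#' @param noise_sd additive Gaussian measurement noise on Vm (mV).
#' @param dt_out sweep sampling interval (ms); 0.2 ms emulates 5 kHz
#'   digitization; finer grids suit noise-free traces.
#' @param seed integer master seed.
#' @return An object of class `recording_gen_params`.
#' @export
recording_gen_params <- function(n_cells = 11, states_mV = c(-80, -70, -60),
                                 ramp_slopes_mV_ms = c(2, 3, 4.5, 6.5),
                                 trials_per_stimulus_per_state = 15,
                                 threshold_law = list(slope = -0.95,
                                                      intercept = -38,
                                                      resid_sd = 1.5),
                                 onset_jitter_sd = 0.5, noise_sd = 0.3,
                                 dt_out = 0.2, seed = 1) {
  stopifnot(length(ramp_slopes_mV_ms) >= 2,
            !anyDuplicated(ramp_slopes_mV_ms),
            all(states_mV >= -90 & states_mV <= -50))
  structure(list(n_cells = as.integer(n_cells), states_mV = states_mV,
                 ramp_slopes_mV_ms = ramp_slopes_mV_ms,
                 trials_per_stimulus_per_state =
                   as.integer(trials_per_stimulus_per_state),
                 threshold_law = threshold_law,
                 onset_jitter_sd = onset_jitter_sd, noise_sd = noise_sd,
                 dt_out = dt_out, seed = as.integer(seed)),
            class = "recording_gen_params")
}

# Passive ramp response of the EIF membrane below threshold:
# V(t) = EL + S (t - tau (1 - exp(-t/tau))) for a designed Vm slope S.
ramp_voltage <- function(t, EL, S, tau) {
  EL + S * (t - tau * (1 - exp(-t / tau)))
}

# Per-(state, stimulus) sweep design, solved self-consistently: the
# threshold law is evaluated on the pre-spike slope the metrology will
# measure (mean dVm/dt over the 2 ms before the spike foot), the spike
# foot is placed where the passive ramp response reaches the
# instrument-inverted foot voltage, and the instantaneous ramp slope at
# the foot (`s_inst`) keeps the pasted upstroke slope-continuous.
design_ramp_sweep <- function(S, EL, law, tau = 5, pre_ms = 2) {
  s_law <- S
  s_inst <- S
  t_foot <- NA_real_
  for (i in 1:8) {
    theta <- law$intercept + law$slope * s_law
    vfoot <- ap_foot_for_target(theta, s_inst)
    f <- function(t) ramp_voltage(t, EL, S, tau) - vfoot
    if (f(500) < 0) {
      return(list(s_law = NA_real_, s_inst = NA_real_, t_foot = NA_real_))
    }
    t_foot <- stats::uniroot(f, c(1e-6, 500), tol = 1e-8)$root
    # the metrology measures the pre-spike slope over a 2 ms window ending
    # one smoothing window (about 1 ms) before its detection point, i.e.
    # about half a window before the foot
    t1 <- max(t_foot - 0.45, 1e-6)
    t0 <- max(t1 - pre_ms, 1e-6)
    s_law <- (ramp_voltage(t1, EL, S, tau) -
                ramp_voltage(t0, EL, S, tau)) / (t1 - t0)
    s_inst <- S * (1 - exp(-t_foot / tau))
  }
  list(s_law = s_law, s_inst = s_inst, t_foot = t_foot)
}

# Stereotyped action-potential waveform pasted onto the trace at the
# spike foot: the upstroke continues at the ongoing depolarization slope
# (`foot_slope`, keeping dV/dt continuous as in real spike initiation)
# plus a half-cosine acceleration to the peak over `rise_ms`, then linear
# repolarization to the reset potential. The half-cosine puts the maximum
# of the second derivative at the foot and makes it decay monotonically,
# so the curvature-based threshold metrology lands at a reproducible
# point. The rise is deliberately slower than a biological upstroke: with
# the 1 ms running average of the metrology, a faster rise would smear
# the curvature peak into a plateau and de-localize the detected
# threshold.
ap_waveform <- function(V_foot, dt, V_peak = 30, rise_ms = 3,
                        foot_slope = 0, fall_ms = 2, V_end = -70) {
  tr <- seq(dt, rise_ms, by = dt)
  amp <- V_peak - V_foot - foot_slope * rise_ms
  up <- V_foot + foot_slope * tr + amp * (1 - cos(pi * tr / rise_ms)) / 2
  tf <- seq(dt, fall_ms, by = dt)
  down <- V_peak + (V_end - V_peak) * tf / fall_ms
  c(V_foot, up, down)
}

# Instrument response of the curvature metrology applied to the pasted
# waveform: under a running average of half-width `w_half` the detected
# threshold lands about `w_half` after the spike foot, reading
# V_foot + s * w_half + amp * frac with frac the half-cosine fraction
# traversed. The generator inverts this mapping so that the *measured*
# threshold equals the law's target -- the threshold law, like the one
# reported for recordings, is a property of the analyzed sweeps.
ap_foot_for_target <- function(theta_target, s, V_peak = 30, rise_ms = 3,
                               w_half = 0.55) {
  frac <- (1 - cos(pi * w_half / rise_ms)) / 2
  (theta_target - s * w_half - (V_peak - s * rise_ms) * frac) / (1 - frac)
}

#' Generate a synthetic recording session
#'
#' Per sweep: the leak reversal is set to the state, a current ramp of the
#' stimulus' designed slope drives the EIF membrane, and the sweep's spike
#' threshold is drawn from the configured threshold-versus-slope law (plus
#' trial noise); the EIF is integrated with that threshold and a stereotyped
#' action-potential waveform is pasted at the spike foot (the bare
#' integrate-and-fire trace has no spike shape for the curvature-based
#' metrology to find), with the foot placed by inverting the metrology's
#' known instrument response so the *measured* threshold matches the law's
#' target; Gaussian measurement noise is added last. Ground truth (target
#' threshold, law-window slope, foot time) is stored per sweep.
#'
#' @param p a [recording_gen_params()] object.
#' @return An object of class `synthetic_session`: list with `sweeps` (list
#'   of [make_sweep()] objects), `ground_truth` (data frame) and `params`.
#' @export
generate_session <- function(p = recording_gen_params()) {
  eif <- eif_params()
  tau <- eif$Cm / eif$gL
  onset <- 100
  duration <- 200
  dt_sim <- 0.1
  law <- p$threshold_law
  n_stim <- length(p$ramp_slopes_mV_ms)

  # deterministic per-(state, stimulus) design: effective slope and mean
  # threshold under the law
  design <- expand.grid(state = p$states_mV, stim = seq_len(n_stim))
  des <- lapply(seq_len(nrow(design)), function(i) {
    S <- p$ramp_slopes_mV_ms[design$stim[i]]
    design_ramp_sweep(S, design$state[i], law, tau)
  })
  design$eff_slope <- vapply(des, `[[`, numeric(1), "s_law")
  design$s_inst <- vapply(des, `[[`, numeric(1), "s_inst")
  design$t_foot <- vapply(des, `[[`, numeric(1), "t_foot")

  cell_seeds <- derive_seeds(p$seed, p$n_cells)
  sweeps <- list()
  gt <- list()
  for (ci in seq_len(p$n_cells)) {
    rows <- with_seed(cell_seeds[ci], {
      out <- list()
      for (st in p$states_mV) {
        for (j in seq_len(n_stim)) {
          d <- design[design$state == st & design$stim == j, ]
          S <- p$ramp_slopes_mV_ms[j]
          for (tr in seq_len(p$trials_per_stimulus_per_state)) {
            jit <- rnorm(1, 0, p$onset_jitter_sd)
            theta <- law$intercept + law$slope * d$eff_slope +
              rnorm(1, 0, law$resid_sd)
            t_on <- onset + jit
            t_end <- t_on + d$t_foot + 5
            cfg <- sim_config(dt = dt_sim, duration = duration, V0 = st)
            tt <- seq(0, by = dt_sim, length.out = cfg$n_steps)
            I <- ifelse(tt >= t_on & tt <= t_end,
                        (tt - t_on) * S * eif$gL, 0)
            pp <- eif
            pp$EL <- st
            trace <- simulate_fixed_eif(I, pp, fixed_threshold_params(theta),
                                        cfg)
            Vm <- trace$Vm
            spike_t <- NA_real_
            if (!is.na(d$t_foot)) {
              vfoot <- ap_foot_for_target(theta, d$s_inst)
              after <- which(tt >= t_on)
              i_cross <- after[which(Vm[after] >= vfoot)[1]]
              if (!is.na(i_cross)) {
                spike_t <- tt[i_cross]
                wf <- ap_waveform(Vm[i_cross], dt_sim,
                                  foot_slope = d$s_inst,
                                  V_end = eif$Vreset)
                # after-spike tail: smooth relaxation from the reset back
                # to the resting state (no junction with the clamped
                # integrator trace)
                n_tail <- length(Vm) - (i_cross + length(wf) - 1)
                if (n_tail > 0) {
                  wf <- c(wf, st + (eif$Vreset - st) *
                            exp(-seq_len(n_tail) * dt_sim / tau))
                }
                i_hi <- min(length(Vm), i_cross + length(wf) - 1)
                Vm[i_cross:i_hi] <- wf[seq_len(i_hi - i_cross + 1)]
              }
            }
            Vm <- Vm + rnorm(length(Vm), 0, p$noise_sd)
            dec <- seq(1, length(Vm), by = max(1L, round(p$dt_out / dt_sim)))
            sw <- make_sweep(tt[dec], Vm[dec], stimulus_id = j,
                             onset = onset, state = st)
            out[[length(out) + 1L]] <- list(
              sweep = sw,
              gt = data.frame(cell = ci, state_mV = st, stimulus = j,
                              trial = tr, theta_true = theta,
                              eff_slope = d$eff_slope,
                              spike_time = spike_t - onset))
          }
        }
      }
      out
    })
    for (r in rows) {
      sweeps[[length(sweeps) + 1L]] <- r$sweep
      gt[[length(gt) + 1L]] <- r$gt
    }
  }
  structure(list(sweeps = sweeps, ground_truth = do.call(rbind, gt),
                 params = p),
            class = "synthetic_session")
}

#' @export
print.synthetic_session <- function(x, ...) {
  cat(sprintf("<synthetic_session> %d sweeps (%d cells x %d states x %d stimuli x %d trials)\n",
              length(x$sweeps), x$params$n_cells, length(x$params$states_mV),
              length(x$params$ramp_slopes_mV_ms),
              x$params$trials_per_stimulus_per_state))
  invisible(x)
}

#' Recover the threshold-versus-slope law from a session
#'
#' Runs the full trace metrology on every sweep (smoothing, resting
#' potential, curvature-based threshold detection, pre-spike slope), groups
#' sweeps into states by measured resting potential, fits the per-cell
#' linear regression of threshold on slope within each state, and
#' summarizes the fitted slopes against the configured ground-truth law.
#'
#' @param session a [generate_session()] result.
#' @param edges state-grouping edges (mV) for [group_by_state()].
#' @return Data frame with one row per state: `state`, `mean_slope`,
#'   `sd_slope` (across cells), `mean_r2`, `n_cells`; per-sweep estimates
#'   in the `estimates` attribute and the configured law in the `law`
#'   attribute.
#' @export
recover_threshold_law <- function(session, edges = seq(-85, -55, by = 10)) {
  est <- lapply(seq_along(session$sweeps), function(i) {
    sw <- preprocess(session$sweeps[[i]])
    th <- detect_spike_threshold(sw)
    data.frame(cell = session$ground_truth$cell[i], Vrest = sw$Vrest,
               Vt = th$Vt, slope_pre = th$slope_pre, spiking = th$spiking)
  })
  est <- do.call(rbind, est)
  est$state <- group_by_state(est$Vrest, edges)
  spk <- est[est$spiking & !is.na(est$state), ]
  if (!nrow(spk)) stop("no spiking sweeps in session")
  per_state <- lapply(levels(droplevels(spk$state)), function(s) {
    d <- spk[spk$state == s, ]
    fits <- lapply(split(d, d$cell), function(dc) {
      if (nrow(dc) < 3) return(NULL)
      fit_threshold_vs_slope(dc)
    })
    fits <- fits[!vapply(fits, is.null, logical(1))]
    if (!length(fits)) return(NULL)
    sl <- vapply(fits, `[[`, numeric(1), "slope")
    data.frame(state = as.numeric(s), mean_slope = mean(sl),
               sd_slope = stats::sd(sl),
               mean_r2 = mean(vapply(fits, `[[`, numeric(1), "r2")),
               n_cells = length(fits))
  })
  out <- do.call(rbind, per_state)
  attr(out, "estimates") <- est
  attr(out, "law") <- session$params$threshold_law
  out
}

#' Convert a session into a response dataset for decoding
#'
#' Extracts per-sweep spike times (ground truth or detected latencies)
#' relative to the nominal stimulus onset, yielding a `response_dataset`
#' whose "networks" are the recorded cells, ready for [mi_vs_sigma()],
#' [robustness_vs_sigma()] and [response_centered_realign()].
#'
#' @param session a [generate_session()] result.
#' @param use `"truth"` (generator spike times) or `"detected"`
#'   (curvature-based latencies from the metrology).
#' @param window decoding window (ms) after onset.
#' @return A `response_dataset`.
#' @export
session_response_dataset <- function(session, use = c("truth", "detected"),
                                     window = c(0, 30)) {
  use <- match.arg(use)
  gt <- session$ground_truth
  spikes <- if (use == "truth") {
    lapply(gt$spike_time, function(s) s[!is.na(s)])
  } else {
    lapply(session$sweeps, function(sw) {
      th <- detect_spike_threshold(preprocess(sw))
      if (th$spiking) th$St else numeric(0)
    })
  }
  out <- data.frame(sigma = 0, network = gt$cell, state = gt$state_mV,
                    stimulus = gt$stimulus, trial = gt$trial)
  out$spikes <- spikes
  structure(out, class = c("response_dataset", "data.frame"),
            origin = 100, window = window, model = "synthetic_recording",
            encoding = "ramp", seed = session$params$seed)
}
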