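#' Rate-encoded stimulus set
#'
#' In rate encoding a stimulus is the number of active presynaptic neurons
#' (`N_inputs`); on every trial a fresh random subset of that size is drawn,
#' so the temporal pattern carries no information. Equiprobable stimuli give
#' a stimulus entropy of `log2(n_stimuli)` bits, e.g. counts 40 to 60 in
#' steps of 2 give 11 stimuli and about 3.46 bits.
#'
#' @param n_min,n_max,step active-count range and increment.
#' @param n_pre presynaptic population size.
#' @return An object of class `stimulus_set`.
#' @export
make_rate_stimulus_set <- function(n_min, n_max, step = 2, n_pre = 100) {
  if (step <= 0) stop("`step` must be positive")
  stopifnot(n_min > 0, n_min <= n_max, n_max <= n_pre)
  counts <- seq(n_min, n_max, by = step)
  structure(list(encoding = "rate",
                 stimuli = lapply(counts, function(k) list(n_active = k)),
                 n_pre = as.integer(n_pre), spike_time = 60,
                 entropy_bits = log2(length(counts))),
            class = "stimulus_set")
}

#' Pattern-encoded stimulus set
#'
#' In pattern encoding all stimuli share one active count but each stimulus
#' is a distinct frozen subset of presynaptic neurons, identical across
#' trials; the decoder must rely on the temporal fingerprint of the
#' arriving EPSCs.
#'
#' @param n_stimuli number of stimuli (distinct subsets).
#' @param n_active active presynaptic count shared by all stimuli.
#' @param n_pre presynaptic population size.
#' @param seed integer seed freezing the subsets.
#' @return An object of class `stimulus_set`.
#' @export
make_pattern_stimulus_set <- function(n_stimuli, n_active, n_pre = 100, seed) {
  stopifnot(n_active <= n_pre, n_stimuli >= 1)
  if (choose(n_pre, n_active) < n_stimuli) {
    stop("fewer distinct subsets exist than stimuli requested")
  }
  subsets <- with_seed(seed, {
    out <- list(); keys <- character(0)
    while (length(out) < n_stimuli) {
      s <- sort(sample.int(n_pre, n_active))
      k <- paste(s, collapse = ",")
      if (!(k %in% keys)) {
        out[[length(out) + 1L]] <- s
        keys <- c(keys, k)
      }
    }
    out
  })
  structure(list(encoding = "pattern",
                 stimuli = lapply(subsets, function(s) list(active_set = s)),
                 n_pre = as.integer(n_pre), spike_time = 60,
                 entropy_bits = log2(n_stimuli)),
            class = "stimulus_set")
}

#' Membrane state conditions
#'
#' A membrane state is defined by the leak reversal potential `E_L`;
#' shifting `E_L` is mathematically equivalent to injecting a constant
#' current and emulates up/down or arousal-dependent resting regimes.
#'
#' @param EL_mV numeric vector of leak reversal potentials (mV), within the
#'   physiological range -90 to -50.
#' @return Numeric vector of class `state_condition`.
#' @export
state_condition <- function(EL_mV) {
  stopifnot(all(EL_mV >= -90 & EL_mV <= -50))
  structure(as.numeric(EL_mV), class = "state_condition")
}

#' Experiment configuration
#'
#' Bundles the simulation-scale knobs of a factorial experiment: the sigma
#' grid (temporal dispersion of synaptic latencies), trials per stimulus per
#' condition, replicate networks, Poisson noise rate, synapse statistics and
#' the master seed. The defaults mirror the study conditions (150 trials per
#' stimulus); `n_networks` defaults to a desk-scale 50 replicates (the
#' full-scale condition uses 500).
#'
#' @param stim_set a `stimulus_set` (optional convenience slot).
#' @param states a [state_condition()] vector (optional convenience slot).
#' @param sigma_grid latency dispersions (ms) to sweep.
#' @param n_trials trials per stimulus per condition.
#' @param n_networks replicate frozen networks.
#' @param noise_rate Poisson noise rate per presynaptic neuron (Hz).
#' @param synapse a [synapse_params()] object.
#' @param n_pre presynaptic population size.
#' @param duration,dt simulated time and step (ms).
#' @param spike_time presynaptic spike time (ms).
#' @param window decoding window (ms) relative to the analysis origin.
#' @param eif an [eif_params()] template (its `EL` is overridden per state).
#' @param adapt an [adaptive_threshold_params()] object.
#' @param hh an [hh_params()] template for HH experiments.
#' @param seed master integer seed.
#' @return An object of class `experiment_config`.
#' @export
experiment_config <- function(stim_set = NULL, states = state_condition(-70),
                              sigma_grid = seq(0.5, 4, by = 0.5),
                              n_trials = 150, n_networks = 50, noise_rate = 0,
                              synapse = synapse_params(), n_pre = 100,
                              duration = 100, dt = 0.1, spike_time = 60,
                              window = c(0, 30), eif = eif_params(),
                              adapt = adaptive_threshold_params(),
                              hh = hh_params(), seed = 1) {
  stopifnot(n_trials >= 1, n_networks >= 1, length(sigma_grid) >= 1)
  structure(list(stim_set = stim_set, states = states,
                 sigma_grid = sigma_grid, n_trials = as.integer(n_trials),
                 n_networks = as.integer(n_networks), noise_rate = noise_rate,
                 synapse = synapse, n_pre = as.integer(n_pre),
                 duration = duration, dt = dt, spike_time = spike_time,
                 window = window, eif = eif, adapt = adapt, hh = hh,
                 seed = as.integer(seed)),
            class = "experiment_config")
}

# Build the per-batch impulse matrix (n_steps x n_trials) for one
# (network, stimulus) pair: stimulus-evoked EPSC deposits plus Poisson
# noise deposits, all drawn under `batch_seed`.
batch_impulses <- function(net, stim, encoding, n_trials, noise_rate, cfg,
                           batch_seed) {
  n_steps <- as.integer(round(cfg$duration / cfg$dt))
  with_seed(batch_seed, {
    if (encoding == "rate") {
      sets <- replicate(n_trials, sample.int(net$n_pre, stim$n_active),
                        simplify = FALSE)
    } else {
      sets <- rep(list(stim$active_set), n_trials)
    }
    act <- unlist(sets)
    trial <- rep.int(seq_len(n_trials), lengths(sets))
    amps <- draw_amplitudes(length(act), net$synapse)
    arr <- cfg$spike_time + net$latencies[act]
    idx <- round(arr / cfg$dt) + 1
    if (noise_rate > 0) {
      lam <- net$n_pre * noise_rate * cfg$duration / 1000
      n_ev <- rpois(n_trials, lam)
      if (sum(n_ev) > 0) {
        t_ev <- runif(sum(n_ev), 0, cfg$duration)
        a_ev <- draw_amplitudes(sum(n_ev), net$synapse)
        idx <- c(idx, round(t_ev / cfg$dt) + 1)
        amps <- c(amps, a_ev)
        trial <- c(trial, rep.int(seq_len(n_trials), n_ev))
      }
    }
    keep <- idx >= 1 & idx <= n_steps & amps != 0
    imp <- numeric(n_steps * n_trials)
    if (any(keep)) {
      lin <- idx[keep] + (trial[keep] - 1L) * n_steps
      agg <- rowsum(amps[keep], group = lin)
      imp[as.numeric(rownames(agg))] <- agg
    }
    dim(imp) <- c(n_steps, n_trials)
    imp
  })
}

simulate_batch <- function(model, imp, EL, cfg, theta_fixed) {
  syn_decay <- exp(-cfg$dt / cfg$synapse$epsc_tau)
  p <- cfg$eif
  p$EL <- EL
  if (model == "adaptive_eif") {
    run_eif(imp, cfg$dt, syn_decay, p, TRUE, cfg$adapt, V0 = EL)$spikes
  } else if (model == "fixed_eif") {
    if (is.null(theta_fixed)) stop("fixed_eif requires `theta_fixed`")
    run_eif(imp, cfg$dt, syn_decay, p, FALSE, theta_fixed = theta_fixed,
            V0 = EL)$spikes
  } else if (model == "hh") {
    hp <- cfg$hh
    hp$EL <- EL
    I <- filter_epsc(imp, cfg$dt, cfg$synapse$epsc_tau)
    conv <- 1e-6 / hp$area
    lapply(seq_len(ncol(I)), function(j) {
      hh_integrate_cpp(I[, j], cfg$dt, hp$Cm, hp$gNa, hp$gK, hp$gL, hp$ENa,
                       hp$EK, hp$EL, hp$a, conv, EL)$spikes
    })
  } else {
    stop("unknown model: ", model)
  }
}

#' Run a full factorial simulation condition
#'
#' For every combination of sigma, replicate network, membrane state,
#' stimulus and trial: synthesize the input current, simulate the chosen
#' model with `E_L` set to the state, and record the evoked spike times
#' relative to the presynaptic population spike time (the analysis origin).
#' The master seed in `cfg` makes the whole dataset reproducible, and the
#' stochastic inputs are independent of the model choice, so adaptive and
#' fixed models can be compared on identical input ensembles.
#'
#' @param model one of `"adaptive_eif"`, `"fixed_eif"`, `"hh"`.
#' @param stim_set a `stimulus_set`; defaults to `cfg$stim_set`.
#' @param states a [state_condition()] vector; defaults to `cfg$states`.
#' @param cfg an [experiment_config()].
#' @param theta_fixed constant threshold (mV) for the fixed model.
#' @return A `response_dataset`: data frame with columns `sigma`, `network`,
#'   `state`, `stimulus`, `trial` and list-column `spikes` (ms relative to
#'   the analysis origin), plus metadata attributes.
#' @export
run_condition <- function(model, stim_set = NULL, states = NULL, cfg,
                          theta_fixed = NULL) {
  if (is.null(stim_set)) stim_set <- cfg$stim_set
  if (is.null(states)) states <- cfg$states
  stopifnot(inherits(stim_set, "stimulus_set"))
  n_sig <- length(cfg$sigma_grid)
  n_net <- cfg$n_networks
  n_st <- length(states)
  n_stim <- length(stim_set$stimuli)
  n_tr <- cfg$n_trials

  net_seeds <- matrix(derive_seeds(cfg$seed, n_sig * n_net), n_sig, n_net)
  batch_seeds <- array(derive_seeds(cfg$seed + 1L, n_sig * n_net * n_st * n_stim),
                       dim = c(n_sig, n_net, n_st, n_stim))

  n_batches <- n_sig * n_net * n_st * n_stim
  spikes <- vector("list", n_batches * n_tr)
  coords <- vector("list", n_batches)
  b <- 0L
  for (is in seq_len(n_sig)) {
    sig <- cfg$sigma_grid[is]
    for (k in seq_len(n_net)) {
      net <- build_network(cfg$n_pre, sig, cfg$synapse, net_seeds[is, k])
      for (ist in seq_len(n_st)) {
        EL <- as.numeric(states[ist])
        for (j in seq_len(n_stim)) {
          imp <- batch_impulses(net, stim_set$stimuli[[j]], stim_set$encoding,
                                n_tr, cfg$noise_rate, cfg,
                                batch_seeds[is, k, ist, j])
          sp <- simulate_batch(model, imp, EL, cfg, theta_fixed)
          b <- b + 1L
          idx <- ((b - 1L) * n_tr + 1L):(b * n_tr)
          spikes[idx] <- lapply(sp, function(s) s - cfg$spike_time)
          coords[[b]] <- data.frame(sigma = sig, network = k, state = EL,
                                    stimulus = j, trial = seq_len(n_tr))
        }
      }
    }
  }
  out <- do.call(rbind, coords)
  out$spikes <- spikes
  structure(out,
            class = c("response_dataset", "data.frame"),
            origin = cfg$spike_time, window = cfg$window, model = model,
            encoding = stim_set$encoding, seed = cfg$seed)
}

#' Spike probability as a function of temporal dispersion
#'
#' Runs a single-stimulus rate condition over the sigma grid and returns,
#' per sigma, the probability of at least one evoked spike in the decoding
#' window, pooled over networks and trials.
#'
#' @param model `"adaptive_eif"` or `"fixed_eif"`.
#' @param n_active number of active presynaptic inputs.
#' @param cfg an [experiment_config()].
#' @param theta_fixed threshold for the fixed model (mV).
#' @return Data frame with columns `sigma`, `p_spike`, `n`.
#' @export
spike_probability_vs_sigma <- function(model, n_active = 37, cfg,
                                       theta_fixed = NULL) {
  ss <- make_rate_stimulus_set(n_active, n_active, 1, cfg$n_pre)
  ds <- run_condition(model, ss, state_condition(cfg$eif$EL), cfg,
                      theta_fixed = theta_fixed)
  w <- attr(ds, "window")
  hit <- vapply(ds$spikes, function(s) any(s >= w[1] & s < w[2]), logical(1))
  agg <- tapply(hit, ds$sigma, mean)
  data.frame(sigma = as.numeric(names(agg)), p_spike = as.numeric(agg),
             n = as.integer(tapply(hit, ds$sigma, length)))
}

#' Sweep membrane and threshold time constants
#'
#' Re-parameterizes the adaptive EIF over a grid of membrane time constants
#' (varied via `gL` at fixed `Cm`, which preserves the charge-to-voltage
#' gain of the brief EPSCs so that longer membrane integration translates
#' into larger, longer-lasting EPSPs) and threshold time constants, reruns
#' the sigma sweep for each grid point and tabulates mean firing rate,
#' bias-corrected MI per sigma and the MI-weighted sigma center of mass.
#'
#' @param stim_set a `stimulus_set`.
#' @param tau_m_grid,tau_theta_grid time-constant grids (ms).
#' @param cfg an [experiment_config()].
#' @param bin_ms decoding bin size (ms).
#' @return Data frame with one row per (tau_m, tau_theta) and columns
#'   `rate` (spikes/trial), `sigma_cm` (ms) and a list-column `mi`
#'   (per-sigma MI in bits).
#' @export
sweep_time_constants <- function(stim_set, tau_m_grid, tau_theta_grid, cfg,
                                 bin_ms = 2) {
  if (!length(tau_m_grid) || !length(tau_theta_grid)) {
    stop("time-constant grids must be non-empty")
  }
  stopifnot(all(tau_m_grid > 0), all(tau_theta_grid > 0))
  grid <- expand.grid(tau_m = tau_m_grid, tau_theta = tau_theta_grid)
  res <- lapply(seq_len(nrow(grid)), function(i) {
    cfg_i <- cfg
    cfg_i$eif$gL <- cfg$eif$Cm / grid$tau_m[i]
    cfg_i$adapt$tau_theta <- grid$tau_theta[i]
    ds <- run_condition("adaptive_eif", stim_set, cfg$states, cfg_i)
    mi <- mi_vs_sigma(ds, binning_spec(bin_ms = bin_ms))
    list(rate = mean(lengths(ds$spikes)),
         sigma_cm = sigma_center_of_mass(mi$sigma, pmax(mi$mi_bits, 0)),
         mi = mi$mi_bits)
  })
  grid$rate <- vapply(res, `[[`, numeric(1), "rate")
  grid$sigma_cm <- vapply(res, `[[`, numeric(1), "sigma_cm")
  grid$mi <- I(lapply(res, `[[`, "mi"))
  grid
}

#' Sweep the input population size at constant total drive
#'
#' For each active-count range the single-EPSC amplitude is rescaled so
#' that (mean count x amplitude) is constant across regimes, isolating the
#' effect of population size from total input charge.
#'
#' @param model `"adaptive_eif"` or `"fixed_eif"`.
#' @param ranges list of numeric length-2 vectors (count ranges); each range
#'   is divided into `n_stimuli` equally spaced stimuli.
#' @param n_stimuli stimuli per range.
#' @param cfg an [experiment_config()].
#' @param encoding `"rate"` or `"pattern"`.
#' @param reference_drive reference (count x amplitude) product (pA).
#' @param theta_fixed threshold for the fixed model.
#' @param bin_ms decoding bin size (ms).
#' @return Data frame with columns `range`, `mean_count`, `amplitude`,
#'   `sigma`, `mi_bits`.
#' @export
sweep_population_size <- function(model, ranges, n_stimuli = 6, cfg,
                                  encoding = "rate",
                                  reference_drive = 50 * 14,
                                  theta_fixed = NULL, bin_ms = 2) {
  out <- lapply(ranges, function(rg) {
    counts <- unique(round(seq(rg[1], rg[2], length.out = n_stimuli)))
    mean_count <- mean(counts)
    cfg_i <- cfg
    cfg_i$synapse$amplitude_mean <- reference_drive / mean_count
    ss <- if (encoding == "rate") {
      s <- make_rate_stimulus_set(min(counts), min(counts), 1, cfg$n_pre)
      s$stimuli <- lapply(counts, function(k) list(n_active = k))
      s$entropy_bits <- log2(length(counts))
      s
    } else {
      make_pattern_stimulus_set(n_stimuli, round(mean_count), cfg$n_pre,
                                seed = cfg$seed + round(mean_count))
    }
    ds <- run_condition(model, ss, cfg$states, cfg_i,
                        theta_fixed = theta_fixed)
    mi <- mi_vs_sigma(ds, binning_spec(bin_ms = bin_ms))
    data.frame(range = paste(rg, collapse = "-"), mean_count = mean_count,
               amplitude = cfg_i$synapse$amplitude_mean,
               sigma = mi$sigma, mi_bits = mi$mi_bits)
  })
  do.call(rbind, out)
}
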