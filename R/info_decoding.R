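#' Response binning specification
#'
#' Spike trains are decoded as "response words": vectors of per-bin spike
#' counts in a window relative to the analysis origin (the presynaptic
#' population spike time). The default window is 0-30 ms, which brackets
#' all evoked spikes, with 2 ms bins. If the window length is not a
#' multiple of the bin size the last partial bin is dropped.
#'
#' @param window numeric length-2 (ms), half-open `[start, end)`.
#' @param bin_ms bin size (ms); 0.5, 1, 2, 5 and 30 are the standard
#'   choices.
#' @param max_spikes per-trial spike cap used for alphabet accounting.
#' @return An object of class `binning_spec` with an `n_bins` field.
#' @export
binning_spec <- function(window = c(0, 30), bin_ms = 2, max_spikes = 2) {
  stopifnot(length(window) == 2, window[2] > window[1], bin_ms > 0)
  n_bins <- floor((window[2] - window[1]) / bin_ms + 1e-9)
  stopifnot(n_bins >= 1)
  structure(list(window = window, bin_ms = bin_ms,
                 max_spikes = as.integer(max_spikes),
                 n_bins = as.integer(n_bins)),
            class = "binning_spec")
}

#' Bin a spike train into a response word
#'
#' Counts spikes per half-open bin `[k*bin, (k+1)*bin)` within the analysis
#' window; spikes outside the window are discarded. An all-zero word is the
#' legitimate code for a non-spiking (NS) trial.
#'
#' @param spikes spike times (ms) relative to the analysis origin.
#' @param spec a [binning_spec()].
#' @return Integer vector of per-bin counts, length `spec$n_bins`.
#' @export
bin_spike_train <- function(spikes, spec = binning_spec()) {
  lo <- spec$window[1]
  hi <- lo + spec$n_bins * spec$bin_ms
  s <- spikes[spikes >= lo & spikes < hi]
  if (!length(s)) return(integer(spec$n_bins))
  tabulate(floor((s - lo) / spec$bin_ms) + 1L, nbins = spec$n_bins)
}

#' Size of the binned-response alphabet
#'
#' Combinatorial accounting of the possible response words: at most one
#' spike per bin and at most `max_spikes` spikes per trial, giving
#' \eqn{\sum_{k=0}^{max} \binom{n_{bins}}{k}} patterns. For a 30 ms window
#' this yields 121 patterns at 2 ms bins and 466 at 1 ms bins.
#'
#' @param n_bins number of bins in the decoding window.
#' @param max_spikes maximum spikes per trial.
#' @return Number of possible response patterns.
#' @export
response_alphabet_size <- function(n_bins, max_spikes = 2) {
  stopifnot(n_bins >= 1, max_spikes >= 0)
  sum(choose(n_bins, 0:max_spikes))
}

#' Minimum trials per stimulus for reliable bias-corrected MI
#'
#' The shuffle plus Panzeri-Treves correction is accurate when the number
#' of trials per stimulus is at least one quarter of the response-alphabet
#' size.
#'
#' @param N_R response-alphabet size.
#' @return `ceiling(N_R / 4)`.
#' @export
min_trials_required <- function(N_R) {
  stopifnot(N_R >= 1)
  ceiling(N_R / 4)
}

# Estimate the number of relevant (nonzero-probability) responses from an
# observed count vector. "bayes" solves the occupancy relation
# R_obs = R (1 - (1 - 1/R)^N) for R, i.e. the number of equiprobable bins
# whose expected occupancy after N draws matches the observed distinct
# count; "naive" returns the observed distinct count.
bayescount <- function(counts, method = c("bayes", "naive")) {
  method <- match.arg(method)
  counts <- counts[counts > 0]
  R_obs <- length(counts)
  N <- sum(counts)
  if (method == "naive" || R_obs <= 1) return(R_obs)
  if (R_obs >= N) return(R_obs)  # every trial distinct: occupancy relation degenerate
  f <- function(R) R * (1 - (1 - 1 / R)^N) - R_obs
  if (f(R_obs) >= 0) return(R_obs)
  upper <- R_obs * 2
  while (f(upper) < 0 && upper < 1e9) upper <- upper * 2
  if (f(upper) < 0) return(R_obs)
  stats::uniroot(f, c(R_obs, upper), tol = 1e-6)$root
}

entropy_bits <- function(counts) {
  counts <- counts[counts > 0]
  if (!length(counts)) return(0)
  p <- counts / sum(counts)
  -sum(p * log2(p))
}

#' Panzeri-Treves bias of a plug-in MI estimate
#'
#' Analytic small-sample bias of the plug-in mutual information computed
#' from a words-by-stimuli count table:
#' \deqn{b = \frac{1}{2 N \ln 2}\left[\sum_s (\tilde R_s - 1) -
#'   (\tilde R - 1)\right],}
#' where \eqn{\tilde R} and \eqn{\tilde R_s} are the estimated numbers of
#' relevant responses overall and per stimulus. The bias is subtracted from
#' the plug-in MI.
#'
#' @param joint matrix of counts, rows = response words, columns = stimuli.
#' @param method `"bayes"` (occupancy-based estimate of the relevant
#'   response count) or `"naive"` (observed distinct count).
#' @return Bias in bits.
#' @export
pt_bias_correction <- function(joint, method = c("bayes", "naive")) {
  method <- match.arg(method)
  joint <- as.matrix(joint)
  N <- sum(joint)
  if (N == 0) stop("empty count table")
  Rt <- bayescount(rowSums(joint), method)
  Rts <- apply(joint, 2, bayescount, method = method)
  (sum(Rts - 1) - (Rt - 1)) / (2 * N * log(2))
}

# Internal MI engine on integer word/label ids. Returns plug-in MI, PT bias
# and (optionally) the mean bias-corrected MI of label-shuffled surrogates.
mi_engine <- function(word_id, lab_id, nW, nS, correction, n_shuffles,
                      shuffle_seed, pt_method = "bayes") {
  N <- length(word_id)
  joint <- matrix(tabulate(word_id + nW * (lab_id - 1L), nW * nS), nW, nS)
  wr <- rowSums(joint)
  ns <- colSums(joint)
  HR <- entropy_bits(wr)
  HRgS <- sum(vapply(seq_len(nS), function(s) {
    if (ns[s] == 0) 0 else ns[s] / N * entropy_bits(joint[, s])
  }, numeric(1)))
  plugin <- HR - HRgS
  bias <- if (correction == "plugin") 0 else {
    Rt <- bayescount(wr, pt_method)
    Rts <- apply(joint, 2, bayescount, method = pt_method)
    (sum(Rts - 1) - (Rt - 1)) / (2 * N * log(2))
  }
  shuffle <- 0
  if (correction == "pt_shuffle" && n_shuffles > 0) {
    Rt <- bayescount(wr, pt_method)
    sh <- with_seed(shuffle_seed, vapply(seq_len(n_shuffles), function(b) {
      lab_b <- sample(lab_id)
      jb <- matrix(tabulate(word_id + nW * (lab_b - 1L), nW * nS), nW, nS)
      HRgS_b <- sum(vapply(seq_len(nS), function(s) {
        if (ns[s] == 0) 0 else ns[s] / N * entropy_bits(jb[, s])
      }, numeric(1)))
      Rts_b <- apply(jb, 2, bayescount, method = pt_method)
      bias_b <- (sum(Rts_b - 1) - (Rt - 1)) / (2 * N * log(2))
      (HR - HRgS_b) - bias_b
    }, numeric(1)))
    shuffle <- mean(sh)
  }
  list(plugin = plugin, bias = bias, shuffle = shuffle,
       mi = plugin - bias - shuffle, joint = joint)
}

encode_words <- function(words) {
  if (is.matrix(words)) {
    key <- do.call(paste, c(as.data.frame(words), sep = ","))
  } else {
    key <- as.character(words)
  }
  f <- factor(key)
  list(id = as.integer(f), n = nlevels(f))
}

#' Mutual information between stimuli and binned responses
#'
#' Plug-in mutual information \eqn{I(S;R) = H(R) - H(R|S)} from the
#' empirical joint distribution of response words and stimulus labels, with
#' optional bias correction: `"pt"` subtracts the analytic Panzeri-Treves
#' bias, `"pt_shuffle"` (default) additionally subtracts the mean
#' bias-corrected MI of label-shuffled surrogates, which centers the
#' estimate on zero for independent words and labels.
#'
#' @param words response words: a trials-by-bins count matrix (from
#'   [bin_spike_train()]), or any vector of word identifiers.
#' @param labels stimulus label per trial.
#' @param correction `"pt_shuffle"`, `"pt"` or `"plugin"`.
#' @param n_shuffles label shuffles for the shuffle term.
#' @param shuffle_seed seed for the shuffles.
#' @param pt_method relevant-response counting, `"bayes"` or `"naive"`.
#' @param n_possible optional response-alphabet size; if supplied, a
#'   warning is issued when trials per stimulus fall below
#'   [min_trials_required()].
#' @param state_labels optional state per trial; when supplied the word is
#'   augmented with the state (state-aware MI, `I(S; R, state)`).
#' @return An object of class `mi_estimate` with fields `mi_bits`,
#'   `plugin_bits`, `bias_bits`, `shuffle_bits`, `n_trials_per_stimulus`,
#'   `state_aware`.
#' @export
mutual_information <- function(words, labels, correction = c("pt_shuffle", "pt", "plugin"),
                               n_shuffles = 100, shuffle_seed = 1,
                               pt_method = c("bayes", "naive"),
                               n_possible = NULL, state_labels = NULL) {
  correction <- match.arg(correction)
  pt_method <- match.arg(pt_method)
  lf <- factor(labels)
  ew <- encode_words(words)
  if (!is.null(state_labels)) {
    sf <- factor(state_labels)
    key <- paste(ew$id, as.integer(sf), sep = "|")
    f <- factor(key)
    ew <- list(id = as.integer(f), n = nlevels(f))
  }
  stopifnot(length(ew$id) == length(lf))
  n_per_stim <- tabulate(as.integer(lf), nlevels(lf))
  if (!is.null(n_possible) && correction != "plugin" &&
      min(n_per_stim) < min_trials_required(n_possible)) {
    warning(sprintf("only %d trials per stimulus; at least %d recommended for alphabet size %g",
                    min(n_per_stim), min_trials_required(n_possible), n_possible))
  }
  if (nlevels(lf) < 2) {
    res <- list(plugin = 0, bias = 0, shuffle = 0, mi = 0)
  } else {
    res <- mi_engine(ew$id, as.integer(lf), ew$n, nlevels(lf), correction,
                     n_shuffles, shuffle_seed, pt_method)
  }
  structure(list(mi_bits = res$mi, plugin_bits = res$plugin,
                 bias_bits = res$bias, shuffle_bits = res$shuffle,
                 n_trials_per_stimulus = n_per_stim,
                 n_words = ew$n, correction = correction,
                 state_aware = !is.null(state_labels)),
            class = "mi_estimate")
}

#' @export
print.mi_estimate <- function(x, ...) {
  cat(sprintf("<mi_estimate> %.4f bit (%s%s; plugin %.4f, bias %.4f, shuffle %.4f)\n",
              x$mi_bits, x$correction,
              if (x$state_aware) ", state-aware" else "",
              x$plugin_bits, x$bias_bits, x$shuffle_bits))
  invisible(x)
}

#' State-aware mutual information
#'
#' Mutual information between the stimulus and the response augmented with
#' the membrane state as an additional dimension, `I(S; R, state)`. By the
#' data-processing inequality this is at least the state-blind `I(S; R)`
#' up to estimation error.
#'
#' @param words,labels as in [mutual_information()].
#' @param state_labels state per trial.
#' @param ... passed to [mutual_information()].
#' @return An `mi_estimate` with `state_aware = TRUE`.
#' @export
mi_with_state <- function(words, labels, state_labels, ...) {
  mutual_information(words, labels, state_labels = state_labels, ...)
}

#' Robustness index
#'
#' `RI = I(S;R) / I(S;R,state)`: close to 1 when decoding needs no state
#' knowledge, low when knowing the state adds substantial information.
#' Values can exceed 1 by a small margin through estimation noise; the
#' overshoot is reported, not silently clipped.
#'
#' @param mi_blind state-blind MI (an `mi_estimate` or a number, bits).
#' @param mi_state state-aware MI (an `mi_estimate` or a number, bits).
#' @return An object of class `robustness_index` with fields `ri`,
#'   `mi_blind`, `mi_state`, `overshoot`.
#' @export
robustness_index <- function(mi_blind, mi_state) {
  b <- if (inherits(mi_blind, "mi_estimate")) mi_blind$mi_bits else mi_blind
  s <- if (inherits(mi_state, "mi_estimate")) mi_state$mi_bits else mi_state
  if (!is.finite(s) || s <= 0) {
    warning("state-aware MI is not positive; RI undefined")
    ri <- NA_real_
  } else {
    ri <- b / s
  }
  structure(list(ri = ri, mi_blind = b, mi_state = s,
                 overshoot = max(0, ri - 1, na.rm = TRUE)),
            class = "robustness_index")
}

#' @export
print.robustness_index <- function(x, ...) {
  cat(sprintf("<robustness_index> RI = %.3f (blind %.4f / state %.4f bit)\n",
              x$ri, x$mi_blind, x$mi_state))
  invisible(x)
}

#' Peristimulus time histogram
#'
#' Average spike count per trial per bin over a slice of a response
#' dataset (subset the data frame first to select states/stimuli).
#'
#' @param dataset a `response_dataset` (or subset thereof).
#' @param bin_ms PSTH bin size (ms).
#' @param window analysis window; defaults to the dataset's.
#' @return An object of class `psth` with `centers` (ms), `rate`
#'   (spikes/trial/bin) and `n_trials`.
#' @export
compute_psth <- function(dataset, bin_ms = 1, window = NULL) {
  if (is.null(window)) window <- attr(dataset, "window")
  if (is.null(window)) window <- c(0, 30)
  spec <- binning_spec(window, bin_ms, max_spikes = 2L)
  all_sp <- unlist(dataset$spikes)
  counts <- bin_spike_train(all_sp, spec)
  n <- nrow(dataset)
  structure(list(centers = window[1] + (seq_len(spec$n_bins) - 0.5) * bin_ms,
                 rate = counts / n, n_trials = n, bin_ms = bin_ms),
            class = "psth")
}

#' Correlation between two PSTHs
#'
#' Pearson correlation across matched bins; a flat (zero-variance) PSTH
#' makes the coefficient undefined (returned as `NA` with a warning).
#'
#' @param a,b `psth` objects with identical binning.
#' @return Correlation coefficient.
#' @export
cc_psth <- function(a, b) {
  stopifnot(length(a$rate) == length(b$rate), a$bin_ms == b$bin_ms)
  if (stats::sd(a$rate) == 0 || stats::sd(b$rate) == 0) {
    warning("zero-variance PSTH; correlation undefined")
    return(NA_real_)
  }
  stats::cor(a$rate, b$rate)
}

#' MI-weighted center of mass of the sigma axis
#'
#' Summarizes a model's preferred temporal integration scale as
#' \eqn{\sigma_{cm} = \sum_i \sigma_i MI_i / \sum_i MI_i}.
#'
#' @param sigmas sigma values (ms).
#' @param mi_values non-negative MI values aligned with `sigmas`.
#' @return Center of mass (ms); `NA` with a warning if all MI are zero.
#' @export
sigma_center_of_mass <- function(sigmas, mi_values) {
  stopifnot(length(sigmas) == length(mi_values), all(mi_values >= 0))
  if (sum(mi_values) <= 0) {
    warning("all MI values are zero; center of mass undefined")
    return(NA_real_)
  }
  sum(sigmas * mi_values) / sum(mi_values)
}

#' Realign a dataset to the population's average response time
#'
#' Implements the "response-centered" (internal) time reference: per
#' membrane state, the reference is the average evoked spike time pooled
#' over stimuli, networks and trials (under the flat-tuning assumption the
#' population-average response time is stimulus independent). Each trial's
#' spike times are shifted so the decoding window starts a fixed `offset`
#' before the reference, i.e. `t' = t - ref + offset`.
#'
#' @param dataset a `response_dataset`.
#' @param offset position (ms) of the reference inside the decoding window.
#' @param per_stimulus if `TRUE`, compute a separate reference per
#'   (state, stimulus) for sensitivity analysis.
#' @return The realigned `response_dataset`; the applied shifts are
#'   recorded in the `realignment` attribute. States with no evoked spikes
#'   are left unshifted and flagged with an `NA` reference.
#' @export
response_centered_realign <- function(dataset, offset = 10,
                                      per_stimulus = FALSE) {
  w <- attr(dataset, "window")
  if (is.null(w)) w <- c(0, 30)
  grp <- if (per_stimulus) {
    interaction(dataset$state, dataset$stimulus, drop = TRUE)
  } else {
    factor(dataset$state)
  }
  refs <- vapply(levels(grp), function(g) {
    sp <- unlist(dataset$spikes[grp == g])
    sp <- sp[sp >= w[1] & sp < w[2]]
    if (!length(sp)) NA_real_ else mean(sp)
  }, numeric(1))
  if (anyNA(refs)) {
    warning("state(s) with no evoked spikes; realignment undefined there")
  }
  shift <- refs[as.integer(grp)] - offset
  shift[is.na(shift)] <- 0
  dataset$spikes <- mapply(function(s, d) s - d, dataset$spikes, shift,
                           SIMPLIFY = FALSE)
  attr(dataset, "realignment") <- data.frame(group = levels(grp),
                                             reference = refs,
                                             offset = offset)
  dataset
}

#' Bin every trial of a response dataset into words
#'
#' @param dataset a `response_dataset` (or subset).
#' @param spec a [binning_spec()].
#' @return Integer matrix, trials by bins.
#' @export
response_words <- function(dataset, spec = binning_spec()) {
  t(vapply(dataset$spikes, bin_spike_train, integer(spec$n_bins),
           spec = spec))
}

dataset_words <- response_words

#' Per-sigma mutual information of a response dataset
#'
#' Computes the bias-corrected MI between stimulus and binned response for
#' every (sigma, network) cell, pooling trials over states (state-blind) or
#' augmenting words with the state (state-aware), then averages over
#' replicate networks.
#'
#' @param dataset a `response_dataset` from [run_condition()].
#' @param spec a [binning_spec()].
#' @param state_aware augment responses with the state label.
#' @param correction,n_shuffles,shuffle_seed passed to
#'   [mutual_information()].
#' @return Data frame with columns `sigma`, `mi_bits` (network average),
#'   `se` (standard error across networks), `n_networks`.
#' @export
mi_vs_sigma <- function(dataset, spec = binning_spec(), state_aware = FALSE,
                        correction = "pt_shuffle", n_shuffles = 100,
                        shuffle_seed = 1) {
  cells <- split(seq_len(nrow(dataset)),
                 list(sigma = dataset$sigma, network = dataset$network),
                 drop = TRUE)
  per_cell <- lapply(cells, function(ix) {
    d <- dataset[ix, ]
    words <- dataset_words(d, spec)
    mi <- mutual_information(words, d$stimulus, correction = correction,
                             n_shuffles = n_shuffles,
                             shuffle_seed = shuffle_seed,
                             state_labels = if (state_aware) d$state else NULL)
    c(sigma = d$sigma[1], mi = mi$mi_bits)
  })
  m <- do.call(rbind, per_cell)
  agg_mean <- tapply(m[, "mi"], m[, "sigma"], mean)
  agg_se <- tapply(m[, "mi"], m[, "sigma"],
                   function(x) stats::sd(x) / sqrt(length(x)))
  data.frame(sigma = as.numeric(names(agg_mean)),
             mi_bits = as.numeric(agg_mean), se = as.numeric(agg_se),
             n_networks = as.integer(tapply(m[, "mi"], m[, "sigma"], length)))
}

#' Robustness index across a sigma grid
#'
#' For each sigma, computes the network-averaged state-blind and
#' state-aware MI and their ratio (the robustness index). The summary `ri`
#' attribute averages RI over the sigma values whose state-aware MI exceeds
#' `min_mi` (a guard against ratios of near-zero quantities).
#'
#' @param dataset a `response_dataset` covering at least two states.
#' @param spec a [binning_spec()].
#' @param correction,n_shuffles,shuffle_seed passed to
#'   [mutual_information()].
#' @param min_mi minimum state-aware MI (bits) for a sigma to enter the
#'   grid-averaged RI.
#' @return Data frame with columns `sigma`, `mi_blind`, `mi_state`, `ri`;
#'   the grid-averaged RI is in the `ri` attribute.
#' @export
robustness_vs_sigma <- function(dataset, spec = binning_spec(),
                                correction = "pt_shuffle", n_shuffles = 100,
                                shuffle_seed = 1, min_mi = 0.05) {
  blind <- mi_vs_sigma(dataset, spec, state_aware = FALSE,
                       correction = correction, n_shuffles = n_shuffles,
                       shuffle_seed = shuffle_seed)
  aware <- mi_vs_sigma(dataset, spec, state_aware = TRUE,
                       correction = correction, n_shuffles = n_shuffles,
                       shuffle_seed = shuffle_seed)
  out <- data.frame(sigma = blind$sigma, mi_blind = blind$mi_bits,
                    mi_state = aware$mi_bits,
                    ri = blind$mi_bits / aware$mi_bits)
  keep <- out$mi_state > min_mi
  attr(out, "ri") <- if (any(keep)) mean(out$ri[keep]) else NA_real_
  out
}
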