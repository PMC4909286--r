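test_that("spike trains are binned on half-open windows", {
  spec <- binning_spec(c(0, 30), 2)
  expect_equal(spec$n_bins, 15L)
  expect_equal(bin_spike_train(numeric(0), spec), integer(15))
  w <- bin_spike_train(c(0.1, 29.9), spec)
  expect_equal(w[1], 1L)
  expect_equal(w[15], 1L)
  expect_equal(sum(w), 2L)
  expect_equal(sum(bin_spike_train(31, spec)), 0L)       # outside the window
  expect_equal(sum(bin_spike_train(c(-0.5, 30), spec)), 0L)
  expect_equal(bin_spike_train(c(1, 1.2), binning_spec(c(0, 30), 2))[1], 2L)
})

test_that("alphabet accounting and trial requirements match the combinatorics", {
  expect_equal(response_alphabet_size(15, 2), 121)
  expect_equal(response_alphabet_size(30, 2), 466)
  expect_equal(response_alphabet_size(1, 1), 2)
  expect_equal(min_trials_required(121), 31)
  expect_equal(min_trials_required(466), 117)
  expect_equal(min_trials_required(4), 1)
})

test_that("plug-in MI matches a brute-force hand computation", {
  # joint table {(s1,w1):3, (s1,w2):1, (s2,w1):1, (s2,w2):3}
  words <- c(rep("w1", 3), "w2", "w1", rep("w2", 3))
  labels <- rep(c("s1", "s2"), each = 4)
  # oracle: direct summation over the empirical joint distribution
  joint <- table(words, labels) / 8
  pw <- rowSums(joint); ps <- colSums(joint)
  mi_oracle <- sum(joint * log2(joint / outer(pw, ps)))
  est <- mutual_information(words, labels, correction = "plugin")
  expect_equal(est$mi_bits, mi_oracle, tolerance = 1e-12)
  expect_equal(est$plugin_bits, 1 - (-0.75 * log2(0.75) - 0.25 * log2(0.25)),
               tolerance = 1e-12)
})

test_that("Panzeri-Treves bias follows the count-table formula", {
  # N = 8, naive R = 3 overall, per-stimulus R_s = {2, 2}: zero net bias
  joint <- cbind(s1 = c(3, 1, 0), s2 = c(0, 2, 2))
  expect_equal(pt_bias_correction(joint, method = "naive"), 0)
  # R = 4 overall with the same per-stimulus counts: negative net bias
  joint2 <- cbind(s1 = c(3, 1, 0, 0), s2 = c(0, 0, 2, 2))
  b2 <- pt_bias_correction(joint2, method = "naive")
  expect_equal(b2, (2 - 3) / (2 * 8 * log(2)), tolerance = 1e-12)
  # replicating the table k-fold shrinks the bias as 1/N
  b_k <- pt_bias_correction(joint2 * 5, method = "naive")
  expect_equal(b_k, b2 / 5, tolerance = 1e-12)
  expect_error(pt_bias_correction(matrix(0, 2, 2)), "empty")
})

test_that("deterministic distinct responses saturate the stimulus entropy", {
  labels <- rep(1:11, each = 150)
  words <- as.character(labels)
  est <- mutual_information(words, labels, correction = "pt_shuffle",
                            n_shuffles = 50, shuffle_seed = 3)
  expect_equal(est$mi_bits, log2(11), tolerance = 0.01)
})

test_that("corrected MI centers on zero for independent words and labels", {
  set.seed(17)
  words <- sample(letters[1:8], 600, replace = TRUE)
  labels <- sample(1:6, 600, replace = TRUE)
  est <- mutual_information(words, labels, n_shuffles = 50, shuffle_seed = 5)
  expect_lt(abs(est$mi_bits), 0.02)
  # and the plug-in estimate alone is biased upward
  plug <- mutual_information(words, labels, correction = "plugin")
  expect_gt(plug$mi_bits, est$mi_bits)
})

test_that("MI is invariant under relabeling of stimuli and words", {
  set.seed(31)
  words <- sample(letters[1:5], 300, replace = TRUE,
                  prob = c(0.4, 0.3, 0.15, 0.1, 0.05))
  labels <- ifelse(words %in% c("a", "b"), sample(1:2, 300, TRUE), 3)
  m1 <- mutual_information(words, labels, correction = "plugin")$mi_bits
  m2 <- mutual_information(chartr("abcde", "vwxyz", words),
                           c("x", "y", "z")[labels],
                           correction = "plugin")$mi_bits
  expect_equal(m1, m2, tolerance = 1e-12)
})

test_that("state-aware MI recovers information hidden by state mixing", {
  # within each state a perfect code, with supports swapped across states:
  # state-blind decoding sees nothing, state-aware decoding is perfect
  n <- 80
  labels <- rep(c("s1", "s2"), each = 2 * n)
  states <- rep(c("up", "down", "up", "down"), each = n)
  words <- c(rep("a", n), rep("b", n), rep("b", n), rep("a", n))
  blind <- mutual_information(words, labels, correction = "plugin")
  aware <- mi_with_state(words, labels, states, correction = "plugin")
  expect_lt(blind$mi_bits, 0.01)
  expect_equal(aware$mi_bits, 1, tolerance = 1e-9)
  # identically distributed across states: no gain from the state
  words2 <- rep(c("a", "b"), times = 2 * n)
  labels2 <- rep(c("s1", "s2"), times = 2 * n)
  b2 <- mutual_information(words2, labels2, correction = "plugin")
  a2 <- mi_with_state(words2, labels2, states, correction = "plugin")
  expect_equal(a2$mi_bits, b2$mi_bits, tolerance = 1e-9)
  # data processing: state-augmented MI is never below the state-blind MI
  set.seed(7)
  w <- sample(letters[1:4], 400, TRUE)
  l <- sample(1:3, 400, TRUE)
  s <- sample(c("u", "d"), 400, TRUE)
  expect_gte(mi_with_state(w, l, s, correction = "plugin")$mi_bits,
             mutual_information(w, l, correction = "plugin")$mi_bits - 1e-9)
})

test_that("robustness index is the MI ratio with flagged edge cases", {
  ri <- robustness_index(0.45, 0.9)
  expect_equal(ri$ri, 0.5)
  expect_warning(r0 <- robustness_index(0.2, 0), "not positive")
  expect_true(is.na(r0$ri))
  over <- robustness_index(1.02, 1.0)
  expect_gt(over$overshoot, 0)
})

test_that("PSTH correlation behaves on hand-made histograms", {
  mk <- function(rate) structure(list(centers = 1:3, rate = rate,
                                      n_trials = 10, bin_ms = 1),
                                 class = "psth")
  expect_equal(cc_psth(mk(c(1, 2, 3)), mk(c(1, 2, 3))), 1)
  expect_equal(cc_psth(mk(c(1, 2, 3)), mk(c(3, 2, 1))), -1)
  expect_warning(flat <- cc_psth(mk(c(1, 1, 1)), mk(c(1, 2, 3))), "zero-variance")
  expect_true(is.na(flat))
})

test_that("PSTH accounts for every in-window spike", {
  ds <- data.frame(x = 1:4)
  ds$spikes <- list(c(1.2, 5.5), numeric(0), 29.9, c(14, 31))
  attr(ds, "window") <- c(0, 30)
  p <- compute_psth(ds, bin_ms = 2)
  expect_equal(sum(p$rate) * p$n_trials, 4)  # the 31 ms spike is outside
  expect_equal(p$centers[1], 1)
})

test_that("sigma center of mass is the MI-weighted mean", {
  expect_equal(sigma_center_of_mass(2, 1.3), 2)
  expect_equal(sigma_center_of_mass(1:3, rep(0.5, 3)), 2)
  expect_equal(sigma_center_of_mass(c(1, 3), c(1, 3)), 2.5)
  expect_warning(cm <- sigma_center_of_mass(1:3, c(0, 0, 0)), "undefined")
  expect_true(is.na(cm))
})

test_that("response-centered realignment is translation invariant", {
  ds <- data.frame(sigma = 0, network = 1, state = rep(c(-62, -72), each = 6),
                   stimulus = rep(1:2, 6), trial = 1:12)
  ds$spikes <- c(lapply(seq(4, 9, by = 1), function(t) t),
                 lapply(seq(14, 19, by = 1), function(t) t))
  attr(ds, "window") <- c(0, 30)
  class(ds) <- c("response_dataset", "data.frame")
  al <- response_centered_realign(ds, offset = 10)
  re <- attr(al, "realignment")
  expect_equal(re$reference[match(c("-62", "-72"), re$group)],
               c(mean(4:9), mean(14:19)), ignore_attr = TRUE)
  # shifting every spike by a constant leaves realigned words unchanged
  ds2 <- ds
  ds2$spikes <- lapply(ds$spikes, function(s) s + 3)
  al2 <- response_centered_realign(ds2, offset = 10)
  spec <- binning_spec(c(0, 30), 2)
  expect_identical(response_words(al, spec), response_words(al2, spec))
  # a state with no evoked spikes is flagged
  ds3 <- ds
  ds3$spikes[ds3$state == -72] <- list(numeric(0))
  expect_warning(response_centered_realign(ds3), "no evoked spikes")
})

test_that("a single stimulus carries zero information by construction", {
  est <- mutual_information(sample(letters[1:3], 50, TRUE), rep(1, 50))
  expect_equal(est$mi_bits, 0)
})
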