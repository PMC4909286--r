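---
title: "Models and methods: adaptive spike thresholds and state-robust decoding"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: adaptive spike thresholds and state-robust decoding}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(adathresh)
```

## The scientific question

Cortical neurons do not spike at a fixed membrane potential: the threshold
tracks the recent voltage history, so fast depolarizations trigger spikes at
lower voltages than slow ones. `adathresh` provides the simulation and
analysis machinery to ask what this buys a neuron computationally: how an
adaptive threshold shapes the information a single neuron transmits about
its presynaptic input, how sharply it selects for input synchrony, and how
robust its code is to shifts of the resting membrane potential ("state"
changes, as between cortical up/down or arousal regimes).

## Neuron models

The workhorse is the exponential integrate-and-fire (EIF) neuron

$$C_m \dot V_m = -g_L (V_m - E_L) + g_L \Delta_T
  e^{(V_m - \theta)/\Delta_T} + I,$$

with $C_m = 50$ pF, $g_L = 10$ nS ($\tau_m = 5$ ms), $E_L = -70$ mV and
spike-initiation sharpness $\Delta_T = 1$ mV. Units are mV/ms/pA/pF/nS
throughout, under which the equation is dimensionally consistent. A spike is
registered at the first sample with $V_m > \theta + 3$ mV; the membrane is
clamped at $-70$ mV for a 0.5 ms refractory period.

For the *adaptive* model the threshold relaxes toward a voltage-dependent
steady state with time constant $\tau_\theta = 6$ ms:

$$\tau_\theta \dot\theta = \theta_\infty(V_m) - \theta, \qquad
  \theta_\infty(V) = \alpha (V - V_i) + V_T +
  k_a \log\!\left(1 + e^{(V - V_i)/k_i}\right),$$

with $\alpha = 0.3$, $k_a = 7$ mV, $k_i = 8.75$ mV, $V_T = -50$ mV,
$V_i = -55$ mV and the natural logarithm (implemented with an overflow-safe
softplus). At rest $\theta_\infty(-70) \approx -53.3$ mV; for depolarized
potentials $\theta_\infty$ rises with asymptotic slope
$\alpha + k_a/k_i = 1.1$, which is why slowly rising inputs meet an escaping
threshold while fast inputs are caught at a low one. The threshold keeps
integrating its relaxation law during and after spikes — there is no
spike-triggered jump — and trials start at the threshold's steady state for
the initial voltage. The *fixed* model is the same membrane with constant
$\theta$; [calibrate_fixed_threshold()] sets $\theta$ by bisection so the
overall mean firing rate matches an adaptive-model run across all conditions
of an experiment.

A Hodgkin–Huxley point-conductance model (Na, delayed-rectifier K and leak;
$g_L$ set so $\tau_m = 5$ ms) serves as the biophysical control. Its rate
constants use the standard forms with removable singularities filled by
their limits; the parameter `a` shifts Na inactivation, whose
half-inactivation voltage is $\approx -46$ mV at `a = 0` (a Boltzmann fit of
the inactivation curve over $-50..-36$ mV, reproduced in the test suite).
Inputs given in pA are converted to current density through a membrane area
of $5\times10^{-5}$ cm², which makes the total capacitance 50 pF and hence
the passive HH response identical to the EIF's — a parameter-free way to
put the two models on the same input scale. HH spikes are upward 0 mV
crossings with a 1 ms dead time. Integration is forward Euler, 0.1 ms for
the EIF models and 0.01 ms for HH (halving the step moves EIF spike times by
less than one step).

## Feedforward network and stimuli

One hundred presynaptic neurons project onto the modeled cell with identical
synapses: EPSC peak 14 pA with instantaneous rise and 5 ms exponential
decay, release failure probability 0.03, amplitude CV 0.3 (negative normal
draws are truncated at zero, a sub-0.05% event). Synaptic latencies are
drawn once per network instance from a normal law with SD $\sigma$ (0–4 ms)
around a 1 ms mean — frozen latencies make pattern-encoded stimuli repeat
their arrival times exactly across trials, while replicate "neurons" are new
instances. Active presynaptic neurons all fire once, 60 ms after trial
onset, so arrival dispersion is purely synaptic; that 60 ms mark is the
analysis origin. Optional background noise inserts independent Poisson
spike trains (rate per presynaptic neuron) spanning the whole trial, with
fresh synaptic amplitudes. Summed EPSC traces are synthesized exactly by
depositing per-synapse charge impulses on the grid and applying the
recursive exponential decay filter.

Two encodings define the stimulus ensembles: *rate* stimuli differ in how
many presynaptic neurons fire (a fresh random subset each trial; e.g. 40 to
60 in steps of 2, $\log_2 11 \approx 3.46$ bits of stimulus entropy), and
*pattern* stimuli differ in which frozen subset fires at a constant count.
Membrane state is set through $E_L$ (equivalent to constant current
injection). The study-scale conditions are 150 trials per stimulus per
condition; replicate-network counts default to a desk-scale 50 (the
full-scale condition is 500), and the test suite runs reduced presets
(typically 6–12 networks, 50–150 trials) chosen so every qualitative
comparison is made well away from its sampling error.

## Information pipeline

Spike trains are decoded as response words: per-bin counts in the 0–30 ms
window after the analysis origin (bins of 0.5/1/2/5/30 ms; 2 ms is the
default). Non-spiking trials are the all-zero word and are legitimate
symbols. The response alphabet under the at-most-one-spike-per-bin
accounting is $\sum_{k\le2}\binom{n_{bins}}{k}$ — 121 words at 2 ms bins,
466 at 1 ms — and reliable bias correction wants at least a quarter of that
many trials per stimulus (31 and 117 respectively).

Mutual information $I(S;R) = H(R) - H(R|S)$ is estimated from the empirical
joint table with two corrections applied to the plug-in value: the analytic
Panzeri–Treves small-sample bias
$\frac{1}{2N\ln 2}\left[\sum_s (\tilde R_s - 1) - (\tilde R - 1)\right]$,
with the relevant-response counts $\tilde R$ estimated by the occupancy
(Bayesian counting) relation $R_{obs} = \tilde R(1 - (1 - 1/\tilde
R)^N)$ (a naive distinct-count fallback is available), and a shuffle term:
the mean bias-corrected MI of label-shuffled surrogates (100 shuffles by
default, seeded), subtracted after the analytic correction. On label-random
data the corrected estimate centers on zero. State-aware information
$I(S;R,\text{state})$ augments the word with the state label; the
robustness index $RI = I(S;R)/I(S;R,\text{state})$ is near 1 when decoding
needs no state knowledge. $RI$ can exceed 1 by estimation noise; the
overshoot is reported rather than clipped. Grid summaries use the
MI-weighted center of mass of the $\sigma$ axis, and across-state response
similarity is the Pearson correlation of PSTHs. When averaging $RI$ over a
$\sigma$ grid, entries whose state-aware MI falls below 0.05 bit are
excluded — a guard against ratios of near-zero estimates, fixed before any
grid is run.

*Response-centered* decoding re-references spike times to the population's
average evoked spike time: per state, the mean in-window spike time pooled
over stimuli, networks and trials (the flat-tuning argument makes the
reference stimulus-independent; a per-stimulus variant exists for
sensitivity analysis), with the decoding window opening a fixed 10 ms
before the reference. Realignment is exactly translation invariant.

## Threshold metrology

Sweeps (recorded-like or simulated) are smoothed with a centered 1 ms
running average and the resting potential is the mean over the 40 ms before
stimulus onset. The spike threshold is the voltage at the maximum of the
discrete second derivative during the upstroke — located from the peak of
dV/dt and searched backward from it, since the threshold precedes the
steepest point; ties break earliest. Two instrument properties of this
estimator matter and are compensated where they are known: under a box
smoothing window of width $w$ the curvature maximum lands about $w/2$ after
the spike onset, so the pre-spike slope (least-squares fit over a 2 ms
window) is taken ending a full window before the detected sample, keeping
upstroke samples out of the slope estimate even when the landing jitters.
EPSP features are the peak depolarization above rest and the least-squares
slope over the 20–80% rise. Spike probabilities are fitted with a
4-parameter logistic whose orientation adapts to rising (input count) or
falling ($\sigma$) transitions; `s` is the positive scale. On simulated
fixed-threshold ramps the re-estimated threshold is constant across input
slopes when the smoothing window is matched in *samples* to the recording
case (five samples — 1 ms at 5 kHz equals 0.5 ms at the simulation's
10 kHz); on adaptive ramps it tracks the model's threshold at the crossing
within 1.5 mV and yields the expected strongly negative
threshold-versus-slope regression.

## Synthetic recording sessions

Because the in vitro dataset the analysis path was designed for is not
distributable, `generate_session()` fabricates one with known ground truth:
11 cells held near $-80/-70/-60$ mV (via $E_L$), four ramp stimuli of
distinct designed rising slopes (2–6.5 mV/ms, 2 bits of stimulus entropy),
15 trials per stimulus per state, and a per-trial spike threshold drawn
from a configurable linear threshold-versus-slope law (default slope
$-0.95$ ms, intercept $-38$ mV, residual SD 1.5 mV) with 0.5 ms onset
jitter and 0.3 mV measurement noise at a 5 kHz sampling emulation.

Three design choices deserve explanation. First, sweeps are passive EIF
ramp responses with the threshold *imposed* per sweep rather than emergent
from the adaptive model: the module's purpose is parameter recovery against
a configurable law (including a flat law as the fixed-threshold null),
which an emergent threshold cannot provide. Second, a stereotyped spike
waveform is pasted at the spike foot, because an integrate-and-fire trace
is truncated at detection and offers no upstroke for curvature-based
metrology; the waveform rises as a slow half-cosine (3 ms to +30 mV) whose
second derivative is maximal at the foot and decays monotonically — a
biologically fast upstroke would, under the 1 ms smoothing of the analysis,
smear into a curvature plateau with no well-defined maximum. Third, the
generator *inverts the estimator's instrument response*: the known landing
offset (half a smoothing window past the foot) and waveform fraction are
solved for the foot voltage that makes the *measured* threshold equal the
law's target. This mirrors what the law means for real recordings — a
property of analyzed sweeps, not of an unobservable latent variable.

What recovery achieves, and what it does not: noise-free densely sampled
sessions recover the law slope to within a few percent; at the default
noise and 5 kHz sampling the hyperpolarized states ($-80$, $-70$ mV)
recover clearly negative slopes around $-0.7$ to $-1.0$ ms, while at
$-60$ mV the spike foot sits only ~10 mV above rest where the ramp's
charging transient is still strong, and jitter of the curvature landing
couples to it, attenuating the fitted slope toward zero. Per-state $r^2$
at the default noise is well below the mid-range seen in recordings —
the imposed 1.5 mV trial noise plus the landing jitter outweigh the
3–4 mV law signal. These are documented limits of the emulation, not of
the metrology interface.

## Numerical and design notes

- Inputs are generated identically for both neuron models under a given
  master seed (per-batch sub-seeds are model-independent), so adaptive
  versus fixed comparisons are paired on the same input ensembles.
- Membrane time-constant sweeps vary $\tau_m$ through $g_L$ at fixed
  $C_m$. Varying $C_m$ instead would scale the voltage response of the
  brief EPSCs as $1/C_m$ and so conflate integration time with input
  strength; at fixed $C_m$ the charge-to-voltage gain of a fast EPSC is
  preserved and longer $\tau_m$ genuinely means longer integration.
- Spike times are reported at the first grid sample beyond threshold (no
  sub-step interpolation); at 0.1 ms this is far below the finest 0.5 ms
  analysis bin. The voltage trace records the pre-reset crossing value at
  the spike sample so the upstroke has a defined top.
- The population-size sweep rescales the single-EPSC amplitude so that
  (mean active count × amplitude) is constant across regimes.
- Default $\sigma$ grids cover 0–4 ms in 0.5 ms steps; the Poisson noise
  grid defaults to 0, 1, 2, 5, 10 Hz per presynaptic neuron.
- With the printed synaptic strength (14 pA, 0.52 mV unitary EPSP) the
  neuron's input-output transition in active-count lies near 45–60 inputs
  at rest; single-stimulus probes far below that range (e.g. 37 active
  inputs at $E_L = -70$ mV) are subthreshold for the adaptive model, and
  sigmoid fits there degenerate. The state-dependence experiments
  (depolarized states, 50–60 active inputs) operate squarely in the
  responsive regime, with mostly one and at most two spikes per trial.
- Problem sizes in the shipped tests are reduced relative to the
  full-scale study (tens of networks, 50–150 trials) — chosen as the
  smallest sizes at which each effect is comfortably outside its sampling
  error, so the suite demonstrates the phenomena rather than re-running
  the full study.

## What the synthetic data do and do not show

The generators emulate the *structure* of the study's inputs — frozen
synaptic latency patterns, trial-to-trial synaptic weight noise, Poisson
background, state shifts through the leak reversal, ramp-driven sweeps
with a threshold law — under exactly known ground truth, which is what
makes estimator validation meaningful. They do not emulate conductance
synapses, short-term plasticity, recurrence, dendritic geometry,
electrode artifacts or slow drifts of real recordings; passing tests
certify the pipeline's correctness and the model-level phenomena, not
quantitative transfer to any particular biological dataset.
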