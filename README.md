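# adathresh

Simulation and analysis toolkit for studying how an **adaptive spike
threshold** shapes single-neuron information transmission. Cortical neurons
spike at a threshold that tracks the recent membrane potential — fast
depolarizations fire at lower voltages than slow ones. `adathresh`
implements the model ecosystem around that observation: exponential
integrate-and-fire (EIF) neurons with an adaptive or fixed threshold and a
Hodgkin–Huxley point-conductance control, a stochastic 100→1 feedforward
synaptic network with rate- or pattern-encoded presynaptic stimuli, spike
threshold metrology for intracellular sweeps, and a bias-corrected
mutual-information pipeline that quantifies what the neuron's spike train
tells an ideal observer about the stimulus — with or without knowledge of
the neuron's resting "state", in stimulus-centered or population-referenced
(response-centered) time.

## The models in brief

Membrane with exponential spike initiation,

$$C_m \dot V_m = -g_L (V_m - E_L) + g_L \Delta_T e^{(V_m-\theta)/\Delta_T} + I,$$

with an adaptive threshold relaxing toward a voltage-dependent steady state,

$$\tau_\theta \dot\theta = \theta_\infty(V_m) - \theta,\qquad
\theta_\infty(V) = \alpha (V - V_i) + V_T + k_a \log(1 + e^{(V-V_i)/k_i}).$$

Information is measured on binned response words in a 0–30 ms window,
$I(S;R) = H(R) - H(R|S)$, with shuffle plus Panzeri–Treves bias correction,
and the **robustness index** $RI = I(S;R)/I(S;R,\mathrm{state})$ summarizes
how much of the code survives ignorance of the membrane state. See the
methods vignette (`vignettes/adaptive-threshold-methods.Rmd`) for the full
account, parameter tables and design decisions.

## Worked example

Measure a spike threshold from a simulated adaptive-EIF ramp response the
same way one would from a recorded sweep:

```r
library(adathresh)
cfg <- sim_config(dt = 0.1, duration = 200, V0 = -70)
tt  <- seq(0, by = 0.1, length.out = cfg$n_steps)
tr  <- simulate_adaptive_eif(pmax(0, tt - 100) * 40, cfg = cfg)  # 4 mV/ms ramp
sw  <- preprocess(make_sweep(tt, tr$Vm, onset = 100))
detect_spike_threshold(sw, search = c(100, tr$spikes[1]), min_upstroke = 3)
#> <threshold_estimate> Vt = -46.29 mV, St = 10.10 ms, pre-slope = 3.23 mV/ms
```

The threshold is detected at −46.3 mV after a 3.2 mV/ms depolarization —
well above the resting threshold of −53.3 mV, because the adaptive
threshold rose while the ramp climbed; steeper ramps are caught lower.

State-robust decoding at a small state difference (−62 vs −65 mV), rate
stimuli of 50–60 active inputs, reduced replicate count:

```r
ss  <- make_rate_stimulus_set(50, 60, 2, 100)
cfg <- experiment_config(stim_set = ss, states = state_condition(c(-62, -65)),
                         sigma_grid = c(1, 2), n_trials = 60, n_networks = 4,
                         seed = 1)
da <- run_condition("adaptive_eif", ss, cfg$states, cfg)
df <- run_condition("fixed_eif",    ss, cfg$states, cfg, theta_fixed = -42.5)
ra <- robustness_vs_sigma(da, binning_spec(bin_ms = 2), n_shuffles = 20)
rf <- robustness_vs_sigma(df, binning_spec(bin_ms = 2), n_shuffles = 20)
round(rf, 3)
#>   sigma mi_blind mi_state    ri
#> 1     1    0.193    0.299 0.646
#> 2     2    0.240    0.343 0.700
c(adaptive = attr(ra, "ri"), fixed = attr(rf, "ri"))
#> adaptive    fixed
#>     0.94     0.67
```

Knowing the state adds ~35% information for the fixed-threshold neuron but
almost nothing for the adaptive one: the adaptive threshold absorbs small
resting-potential shifts, keeping spike timing — and hence the code —
state-invariant.

A thin command-line wrapper for the common experiments lives at
`inst/scripts/run_experiment.R`.

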