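# smfret

Automated analysis of camera-based single-molecule FRET (smFRET)
intensity trajectories, for labs running TIRF or confocal experiments
with one, two or three dyes and (millisecond) alternating laser
excitation. The package replaces the slowest, most subjective steps of
trajectory analysis — sorting thousands of traces by hand, locating
photobleaching steps, picking correction windows, assigning states —
with trainable per-frame classifiers plus fully automatic corrections
and kinetics, and ships the simulator that generates the labeled
training data.

## What it does

* **Simulation** (`sim_config()`, `generate_dataset()`): labeled traces
  for 1-color, 2-color CW/ALEX and 3-color ALEX modalities. Kinetics
  are an exact continuous-time Markov jump process (mean dwell of state
  *i* is −1/k<sub>ii</sub>); frames record fractional state occupancy,
  so sub-frame transitions yield realistically mixed frames. Per-dye
  exponential photobleaching, crosstalk α, direct excitation δ,
  detection efficiency γ, additive Gaussian noise, and junk categories
  (noisy / aggregate / artifact) complete the forward model.
* **Per-frame classification** (`build_model()`, `train_model()`,
  `classify_frames()`, `classify_states()`, `predict_n_states()`):
  multi-scale temporal convolution networks with global (mean+max
  pooled) context and per-frame softmax heads, trained by
  backpropagation implemented in the package. The trace classifier
  labels every frame as dynamic, static, a photoactive subset (e.g.
  donor-only after acceptor bleaching) or junk; state classifiers
  assign per-frame kinetic states on the kinetically informative
  channels; a number-of-states classifier routes segments to the right
  state model.
* **Corrections** (`correction_factors()`, `corrected_fret_2c()`,
  `corrected_fret_3c()`, `fret_to_distance()`): α from donor-only
  frames, δ from acceptor-only frames, γ across acceptor bleach steps;
  accurate FRET E = F/(F + γ·I<sub>DD</sub>) with
  F = I<sub>DA</sub> − α·I<sub>DD</sub> − δ·I<sub>AA</sub>; the exact
  three-color cascade inversion with state-averaged E<sub>YR</sub>;
  distances R = R₀·(1/E − 1)^(1/6).
* **Kinetics** (`extract_transitions()`, `build_tdp()`, `gate_tdp()`,
  `fit_dwell_cdf()`, `compare_cdfs()`): transition density plots,
  serializable TDP gates, censoring-aware mono-exponential dwell-time
  CDF fits with Jacobian-based 95% CIs.
* **HMM baseline** (`fit_local_hmm()`, `fit_global_hmm()`,
  `hmm_transitions()`, `benchmark_vs_hmm()`): Gaussian-emission
  Baum-Welch (tolerance 1e-9) with Viterbi decoding, per trace or with
  globally shared parameters, under the same transition-table contract
  as the classifier route.
* **Pipeline & I/O** (`run_pipeline()`, `write_traces()`,
  `read_traces()`): classify → segment → correct → states → TDP →
  dwell fits with per-trace failure isolation; CSV + JSON trace
  containers; a thin CLI at `inst/cli/smfret`.

## Worked example

```r
library(smfret)
set.seed(1)

## two-state molecules: E = 0.81 / 0.08, dwells 1.75 s / 2.65 s, 50 ms frames
km <- kinetic_model(matrix(c(0, 1/1.75, 1/2.65, 0), 2, 2, byrow = TRUE),
                    cbind(YR = c(0.81, 0.08)))
pm <- photophysics_model(c(Y = 150, R = 150), c(Y = 0.004, R = 0.004))
dm <- detection_model("2c_alex", alpha = 0.05, delta = 0.08,
                      gamma = 1.3, snr = 15)
traces <- lapply(1:40, function(i)
  render_trace(sample_state_path(km, 2000, 0.05), km, pm, dm, 0.05))

## kinetics from the ground-truth paths (classifier-free view)
tabs <- lapply(traces, function(tr)
  extract_transitions(tr$states, 0.05,
                      observable = apparent_fret(tr)[, "YR"]))
tt <- bind_transitions(tabs)
fit_dwell_cdf(tt$dwell_s[tt$interior & tt$from_state == 1])  # high-FRET state
#> dwell_fit: tau = 1.646 s (95% CI 1.639-1.652), n = 542, R2 = 0.9978
fit_dwell_cdf(tt$dwell_s[tt$interior & tt$from_state == 2])  # low-FRET state
#> dwell_fit: tau = 2.423 s (95% CI 2.41-2.436), n = 539, R2 = 0.9966

## corrected FRET and distances
ft <- corrected_fret_2c(traces[[1]], c(alpha = 0.05, delta = 0.08, gamma = 1.3))
round(mean(ft$corrected[traces[[1]]$states == 1, "YR"], na.rm = TRUE), 2)
#> [1] 0.82
round(fret_to_distance(c(0.81, 0.14), R0 = 68))
#> [1] 53 92
```

The dwell fits land within a few percent of the programmed 1.75 s and
2.65 s residence times at this sample size — across repeat simulations
the estimates scatter with a standard deviation of roughly
τ/√(n dwells), noticeably wider than the formal Jacobian CI of the CDF
fit, so pool more traces (the shipped end-to-end check uses 1000) when
percent-level kinetics matter. The corrected efficiency returns the
programmed 0.81, and the distance conversion reproduces the familiar
53 Å / 92 Å pair at R₀ = 68 Å.

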