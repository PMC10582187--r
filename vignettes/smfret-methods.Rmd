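---
title: "Models and methods behind smfret"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind smfret}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# Scope

`smfret` automates the analysis of camera-based single-molecule FRET
(smFRET) intensity trajectories: every frame of a trace is classified
into a category (dynamic, static, photoactive subsets after individual
photobleaching events, or one of the junk classes noisy / aggregate /
artifact), usable segments are corrected for crosstalk, direct
excitation and detection efficiency using the photobleached frames,
kinetic states are assigned per frame, and state residence times are
extracted via transition density plots (TDPs) and mono-exponential
dwell-time fits. A Gaussian-emission Baum-Welch hidden Markov model is
included as the reference kinetic analysis. Because supervised training
needs ground truth, the package ships a first-class simulator that
generates labeled traces for all supported modalities (one-color,
two-color CW, two-color ALEX, three-color ALEX).

# The forward model

## Kinetics

Conformational dynamics are a continuous-time Markov jump process: a
`kinetic_model` holds a rate matrix `Q` (1/s; the mean dwell in state
*i* is `-1/Q[i,i]`) and the observable each state emits — per-state FRET
efficiencies `E` for each dye pair, or a normalized intensity level for
one-color (quencher) data. Paths are sampled exactly (exponential
waiting times), and each camera frame records the *fraction of frame
time* spent in every state. We deliberately do not simulate a per-frame
Markov chain: sub-frame transitions produce mixed frames, and those
mixed frames are precisely the hard cases a per-frame classifier must
survive, because real detectors integrate over the exposure.

## Emission, detection and noise

With donor brightness `B_D` (counts/frame under its own excitation) a
two-color ALEX frame has noise-free expectations

    I_DD = B_D (1 - E)
    I_DA = gamma B_D E + alpha I_DD + delta I_AA
    I_AA = B_A

where `alpha` is donor crosstalk into the acceptor channel, `delta`
direct acceptor excitation normalized to the acceptor-excitation
signal, and `gamma` the detection-efficiency ratio of the pair. For
three-color ALEX the blue-excitation block follows the FRET cascade

    I_B  ~ B_B (1 - E_BY - E_BR)
    I_Y  ~ B_B E_BY (1 - E_YR)
    I_R  ~ B_B (E_BR + E_BY E_YR)

with crosstalk (B emission into the Y and R channels, Y emission into
R), direct excitation (blue laser exciting Y and R, yellow laser
exciting R, each normalized to the dye's own-excitation channel) and
per-pair `gamma` scaling applied on top; the yellow block is the
two-color model for the YR pair. The correction module implements the
exact algebraic inverse of this mixing, and the package's hardest
self-check is the round trip: render noise-free, correct, and recover
the programmed efficiencies to 1e-10.

Photobleaching is single-step and exponential per dye, independent
between dyes; a per-state efficiency is zeroed once its acceptor is
dark, and a dye's emission vanishes once it bleaches. Blinking is not
modeled (the artifact junk class contains blinking-like jumps instead).
Noise is additive Gaussian per channel. The SNR of a trace is defined
as (total brightness of the dyes) / (per-channel noise sigma); the
definition is a package convention — reported SNRs are only comparable
within it — and a Poisson component can be emulated by widening sigma.

## The simulation envelope and junk classes

`sim_config()` defaults reproduce the training envelope used
throughout: per-state efficiencies uniform in [0.01, 0.99], mean dwell
times log-uniform between 1 and 100 frames, SNR between 0.3 and 50,
2000 frames per trace, 50 ms frame time. States of one molecule must
differ by at least `min_contrast = 0.1` in some observable so that the
*number* of states is well defined; degenerate draws are rejected.

The junk classes are generative recipes of this package (quantitative
definitions of these categories are not standardized): *noisy* traces
are ordinary molecules rendered below an SNR floor of 1; *aggregates*
superimpose two independent molecules, with bleach expectations
shortened so that the double bleach steps and above-unit stoichiometry
actually appear inside the trace; *artifacts* add uncorrelated level
jumps per channel and a linear (non-exponential) decay ramp. Simulated
junk approximates, but cannot exhaust, the failure modes of real
measurements — passing benchmarks on simulated junk shows the
classifier separates these *kinds* of defects, not every defect a real
camera produces.

# Per-frame classifiers

All classifiers share one sequence architecture, trained entirely
within the package: a bank of 1-D convolutions with odd kernel sizes
{1, 3, 7, 15, 31, 63} ("omni-scale" coverage of temporal scales up to
roughly twice the longest expected dwell), a mixing convolution, and a
per-frame softmax head. Two mechanisms supply context beyond the
convolutional receptive field:

* the input channels are augmented with their forward and backward
  cumulative means, giving every frame a summary of its past and
  future (where a bleach step lies relative to the frame);
* a global branch averages the deepest features over the whole trace,
  transforms them, and broadcasts the result to every frame, so
  trace-global evidence (a second bleach step anywhere, artifact jumps
  elsewhere) informs per-frame decisions.

This pooled-context design plays the role a recurrent layer plays in
hybrid CNN-RNN sequence labelers; we chose it because it trains with
plain batched GEMMs, has no sequential state to optimize, and its
gradients are exactly checkable (a finite-difference test is part of
the suite). Backpropagation, Adam and the masked per-frame
cross-entropy are implemented in R on BLAS matrix products.

Inputs are normalized per trace by a single global intensity scale (the
0.99 quantile of the per-frame channel total). We found per-channel
min-max scaling — superficially attractive — destroys exactly the
information several categories rest on: it erases the background level
(bleach detection), inter-channel ratios (stoichiometry) and the
noise-to-signal scale, making a clean static trace and a hopelessly
noisy one literally identical after scaling. A single shared scale
removes only absolute brightness.

The trace classifier consumes all channels; state classifiers consume
only the kinetically informative channels (the acceptor signal under
direct acceptor excitation is constant while the acceptor is alive and
is excluded). Classifier state labels are reported in canonical order —
ascending mean observable (apparent FRET, or intensity for one-color
data) — so state indices are comparable across traces and between the
classifier and the HMM; this also makes TDPs invariant to label
permutations at training time.

The per-trace confidence is the mean winning probability over frames
not classified as photobleached; traces below a user-set threshold
(default 0.9) are flagged for discard. Before segmentation, labels pass
a 3-frame majority filter that absorbs single-frame flicker.

# Corrections

Crosstalk is estimated on donor-only stretches (acceptor bleached),
direct excitation on acceptor-only stretches, and `gamma` across an
acceptor bleach step as the drop in sensitized emission over the rise
in donor emission. Numerical guards: 2 frames on each side of every
bleach step are excluded (mixed frames otherwise bias window means —
without this trim the recovered crosstalk is several percent high);
windows need at least 10 frames; backgrounds are per-channel means of
all-bleached stretches (zero if absent); sign-invalid `gamma` windows
return nothing. Trace-wise values are used where obtainable, dataset
medians otherwise.

Corrected efficiencies are deliberately not clipped to [0, 1] and the
histograms span [-0.2, 1.2] (bin width 0.02), so miscorrection stays
visible. For three-color data the `1/(1 - E_YR)` factor in the
blue-block inversion amplifies noise; we therefore use the
*state-averaged* corrected YR efficiency of each frame's state, clamped
at 0.95 (the division is singular as `E_YR -> 1`), and flag frames
whose state mean exceeds the clamp.

# Kinetics

Maximal constant runs of a state path are dwells. Dwells truncated by
the segment boundaries are excluded from dwell statistics (truncation
biases residence times downward) but their transitions still enter the
TDP. The dwell-time CDF is fitted with a mono-exponential by least
squares, with the 95% CI from the Jacobian-based covariance of the fit.
One numerical choice matters here: dwells shorter than one frame are
unobservable in per-frame paths, and sub-half-frame excursions merge
their neighbours. Fitting `1 - exp(-(t - t_min)/tau)` with `t_min` the
shortest observed dwell — exact for an exponential by memorylessness —
removes most of this quantization bias: on frame-quantized ground-truth
paths the plain fit overestimates `tau` by 15-19% at 9 frames per
dwell, the shifted fit stays within about 4% across the 9-62
frames-per-dwell span, and below ~3 frames per dwell the remaining
under/over-estimation is documented behaviour, not a defect. One-frame
dwells are retained by default (a minimum-dwell filter exists but is
off). TDP gates are serializable rectangles; overlapping gates warn and
assign first-match.

# HMM baseline

The reference analysis is a Gaussian-emission HMM fitted by Baum-Welch
(absolute log-likelihood tolerance 1e-9, iteration cap 1e8) and decoded
by Viterbi, on the normalized intensity (one-color) or apparent FRET
(two-color). The observable itself is guarded: proximity ratios are
clamped to [-0.5, 1.5], because a noise-collapsed denominator produces
arbitrarily large ratios that otherwise capture one Gaussian state
outright (we measured single-trace accuracies dropping to ~0.55 from
this alone). Initialization, which EM theory leaves open, is
multi-start: a k-means split and a spread-quantile split each seed one
EM run (sticky uniform transition matrix, 0.95 self-transition) and the
better final likelihood wins. Variances are floored at 1e-6 (on the
normalized observable scale) and flagged when the floor engages; if the
floor or the empty-row guard would ever decrease the likelihood, the
fit stops at the previous parameters, so the reported log-likelihood
trajectory is monotone by construction as EM promises. A global variant shares one parameter set across traces; it is
stronger on homogeneous data and predictably misses transitions in
outlier traces when FRET levels scatter — both behaviours are asserted
in the suite. The forward-backward and Viterbi recursions are the only
compiled code in the package.

# Problem sizes used by the checks

The shipped test suite and the acceptance script run everything at
sizes a single CPU handles comfortably, chosen once as the package's
regression-guard conditions: classifier benchmarks train on 2000
simulated traces of 300 frames with separable parameters (state
contrast at least 0.4 / 0.35 for the two-/three-state models, SNR 8-35,
dwells 8-50 frames) and validate on held-out traces from fresh seeds;
correction-factor recovery uses 500 traces at SNR 10; dwell-recovery
checks use ~6000 interior dwells per state at 9, 25 and 62 frames per
dwell; the end-to-end check simulates 1000 two-state ALEX traces of
2000 frames at 50 ms with residence times 1.75 s and 2.65 s and demands
both pipeline routes (classifier and HMM) recover them within 5%.
Full-envelope training (hundreds of thousands of traces, SNR down to
0.3) uses the same code paths and is a matter of budget, not design.

# Known limitations

* Simulated junk and artifact classes are stand-ins; real defect
  distributions differ per setup, and the trace classifier should be
  retrained (or at least re-validated) against lab-specific data.
* The excitation-flux/stoichiometry factor `beta` and lifetime-based
  corrections are out of scope; the correction set is crosstalk, direct
  excitation and detection efficiency.
* Blinking is not in the forward model; heavy blinking will surface as
  spurious bleach/artifact labels.
* One-color analysis carries less information per frame; at very low
  SNR its confidence saturates low, which is expected behaviour.
* The CW two-color modality has no acceptor-excitation channel, so
  direct excitation can be neither estimated nor corrected there.
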