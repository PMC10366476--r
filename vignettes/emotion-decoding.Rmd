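---
title: "Decoding emotional EEG with a self-backpropagation spiking network"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding emotional EEG with a self-backpropagation spiking network}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sbpsnn)
```

## The problem

Emotional state modulates the scalp EEG in band-limited, spatially
structured ways: negative affect (fear, sadness) elevates beta-band
(12–30 Hz) power over parietal electrodes, while positive affect
modulates alpha (8–12 Hz) over frontal-central and frontal-temporal
sites. `sbpsnn` implements a complete analysis chain that (i) decodes
emotion from multichannel EEG with a biologically motivated spiking
neural network, (ii) mines which electrodes carry the signal, (iii)
attributes the decoding to frequency bands, and (iv) maps directed
interactions among the informative electrodes with spectral Granger
causality.

Because no public recordings accompany this analysis style, the package
ships a first-class synthetic generator that reproduces the statistical
structure the chain assumes — pink-noise background, class-conditional
band-power effects on chosen electrode subsets, directed lagged coupling
between channels, and blink artifacts — so every stage is testable end
to end with known ground truth.

## The decoder

The decoder is a three-layer spiking network: 100 input neurons, 200
hidden leaky integrate-and-fire (LIF) neurons (half excitatory, half
inhibitory — a strict 1:1 Dale constraint re-imposed after every weight
update), and 1 output LIF neuron for binary tasks or 4 for the
four-class task.

**Spike coding.** Continuous signals become spikes by cumulative
temporal contrast (send-on-delta): a per-channel accumulator integrates
sample-to-sample change and emits an ON (OFF) spike whenever it reaches
`+theta` (`-theta`), subtracting the threshold and keeping the
remainder. The threshold is `k` times the standard deviation of the
first difference. Crucially, at the dataset level `theta` is pooled
across all trials of a channel (label-free): a per-trial threshold
would normalize away exactly the between-trial amplitude differences
that carry the class signal. The dataset-level default is `k = 1`,
which puts typical spike rates in the sensitive range of the hidden
layer; the per-call default of `encode_threshold()` is `k = 0.5`.

**Spatial scaffold.** Electrodes and hidden neurons live on a fixed
471-node, 1 cm lattice clipped to an ellipsoidal head volume (the 471
lattice points of smallest ellipsoidal norm). Input-to-hidden weights
are initialized by a distance-based small-world rule: nodes within a
60 mm radius connect with small random weights, 80% of them positive;
longer-range pairs connect with probability 0.05. The input layer is a
fixed 100-neuron pool: each electrode's ON and OFF streams are dealt
round-robin over the 100 slots, so the printed layer size is preserved
for any mined electrode subset.

**Dynamics.** Forward simulation is clocked at the encoder's time step.
Synapses are delta-current: a presynaptic spike deposits
`r_m * w * u * R` on the postsynaptic membrane, where `u` and `R` are
the Tsodyks–Markram short-term facilitation and depression variables.
Hidden neurons use `tau_m` = 20 ms, threshold 1, reset 0, 2 ms
refractory period, and `r_m` = 8 (the membrane resistance doubles as
the synaptic gain; 8 places background-driven hidden activity just
below threshold so class-dependent rate differences are expressed).
The output layer uses the same parameters except a long membrane time
constant (`tau_m` = 0.5 s): a near-integrator, so the output spike
count reflects the accumulated weighted hidden activity of the whole
trial rather than moment-to-moment fluctuations of the excitatory/
inhibitory balance.

Short-term plasticity uses `U` = 0.2, `tau_f` = 200 ms, and `tau_d` =
100 ms. The depression recovery constant matters more than it looks:
strong depression (`tau_d` of several hundred ms) makes synaptic
throughput nearly rate-invariant and thereby cancels rate-coded class
differences. 100 ms preserves about two thirds of the input-rate
contrast at the firing rates the encoder produces.

**Learning.** Training is teacher-driven. For each trial the true
class's output neuron is assigned a regular teaching spike train
(default 100 Hz, capped at the refractory-limited output rate). The
hidden-to-output adjustment is error-driven STDP: at each step the
difference between the teaching train and the realized output spike
train is correlated with the presynaptic hidden spike trace
(exponential, `tau` = 20 ms), accumulated over a batch (default 20
trials), scaled by the STDP amplitudes (`a` = 0.01) and the learning
rate (`eta` = 0.01).

Self-backpropagation (SBP) then mirrors these output adjustments one
layer down: for every hidden neuron, the potentiating part of its
aggregate outgoing adjustment is applied to its *active* incoming
synapses scaled by `rho_ltp` = 0.9, the depressing part scaled by
`rho_ltd` = 0.6; a synapse is active when its input neuron spiked
within the STDP window of a postsynaptic hidden spike during the batch.
The mirrored amount is distributed over the active synapses (a lone
active synapse receives the full amount), which keeps the total
adjustment mass bounded — replicating it onto every active synapse
instead makes the hidden drive grow without bound.

Two stabilizers complete the loop. A small multiplicative weight decay
(5e-4 per batch, active only while learning) prevents the teacher-
driven drift from pinning weights at the `[-1, 1]` clip bounds, where
discrimination degrades. Homeostasis scales each hidden neuron's
threshold by `1 + gamma * (rate - target)/target` per batch (`gamma` =
0.005, target 10 Hz), bounded to `[0.5, 2]` times the initial
threshold; at this gain it stabilizes late training without erasing
between-class rate differences (a much larger gain does erase them).

**Decision rule.** Multi-class prediction is arg-max output count with
ties to the lowest class index. Binary prediction compares the single
output count to a threshold. The natural threshold — half the teaching
count — assumes the trained network actually attains the teaching rate
for positives and silence for negatives; in practice the learned
equilibrium sits wherever potentiation and depression balance, which
depends on trace correlations. The decoder therefore calibrates the
threshold at the end of training as the midpoint of the class-
conditional mean output counts on the training set, falling back to the
half-teaching-count rule if calibration is degenerate.

A rate-based two-layer sigmoid network trained by exact backpropagation
of the same mean-square loss (`rbm_*` functions) serves as the
differentiable reference; its analytic gradients are verified against
central finite differences to 1e-5 relative error.

## Subnetwork mining, fusion, biomarkers, connectivity

The montage is partitioned into seven scalp subnetworks by label prefix
with longest-prefix matching (Fp/AF, F, FC/FT, C/T, CP/TP, P, PO/O).
Within a subnetwork, `mine_subnetwork()` trains a fresh decoder on the
current electrode set (stratified 80/20 split), records accuracy and
F1, scores each electrode's contribution, and eliminates the lowest
contributor until one electrode remains or accuracy stays below
chance + 5 points for three consecutive steps (our quantification of
"performance continued to be poor").

The contribution metric is deliberately pluggable because it is
underdetermined by the procedure it implements: the default is
*occlusion*, which combines two probes of the trained decoder's
standardized class separation — the drop when an electrode's input
neurons are silenced (unique information, but blind to redundancy:
silencing one of two equally informative electrodes barely hurts) and
the separation retained when only that electrode is left active
(standalone information, redundancy-proof). Input-weight mass and full
drop-one retraining remain available as alternatives. In planted-subset
experiments the weight-mass reading is nearly flat — SBP spreads
adjustment over all active synapses — while the combined occlusion
probes reliably keep informative electrodes in the model, so they drive
the elimination.

Per-subnetwork best models (max accuracy, ties broken by F1 then by
fewer electrodes) and simplest models (the terminal step) feed the
fusion analysis: performances are standardized and clustered by
two-cluster K-means (Lloyd iterations, 10 seeded restarts, explicit
objective trace), the higher-performing cluster's electrode sets are
pooled, and best/simplest fusion models are trained on the pooled
channels and ranked against the best single-subnetwork model.

Band biomarkers are found two ways and cross-checked: (i) decoding each
band's wavelet power frames with the same spiking pipeline under
stratified k-fold cross-validation (default 5 folds, pooling the
held-out predictions), and (ii)
EasyMKL over one trace-normalized linear kernel per band, whose learned
convex combination weights are reported as percent contributions
(summing to 100 by construction; regularizer `lambda` = 0.2;
multi-class handled one-vs-rest with averaging).

Directed connectivity uses pairwise Geweke spectral Granger causality
from OLS-fitted VAR models (default order 20, evaluated at integer
frequencies 1–48 Hz, with a companion-matrix stability check). Edges
are kept when the band-averaged causality exceeds the 95th percentile
of a trial-shuffle surrogate null that breaks cross-channel alignment
while preserving each channel's autostructure. A Welch magnitude-
squared coherence table summarizes undirected band-limited synchrony;
its value on independent noise approaches the known 1/K segment-count
bias, which the tests verify.

## The synthetic generator

`generate_emotion_eeg()` emulates: 1/f^1 background (10 µV), additive
band-limited components calibrated by matched Welch in-band power so a
configured multiplier is what an independent spectral estimator
recovers, directed lagged mixing for coupled channel pairs, and 300 ms
biphasic blinks (80 µV at the frontal pole, exponential spatial decay,
4/min by default) with the clean signal retained as ground truth for
the ICA tests. The default class effect map doubles beta power on
P1/P2/P5/P6/P7 for fear, on P1/P5/Pz/P7/P8 for sadness, and doubles
alpha on FC1/FC2/FT7/FT8 for happiness. Defaults are 250 Hz sampling
(1,000 Hz supported), 20 s trials with 0.5 s pre-onset baseline, and a
single integer seed fixing every random draw.

What it does *not* emulate: forward-modeled source-to-scalp projection
(channel correlations come only from explicit coupling and blinks),
non-stationary emotional dynamics within a trial, subject-level
variability in effect topography, and muscle or line-noise artifacts.
Passing tests therefore demonstrate that the chain recovers planted
band/electrode/direction structure of realistic magnitude under
realistic noise — not that it attains any particular accuracy on human
recordings.

## Preprocessing choices

Butterworth bandpass 0.5–48 Hz of order 4, applied forward–backward
(zero phase; the 48 Hz edge already excludes 50 Hz mains, so no
separate notch). Infomax ICA is implemented in-package (natural-
gradient logistic nonlinearity on PCA-whitened data, deterministic
identity initialization); components whose activation correlates with
the mean of the frontal-pole channels above 0.7 in absolute value are
zeroed — an automated stand-in for visual identification of ocular
components. Average re-reference subtracts the instantaneous channel
mean; baseline correction subtracts the mean of the 500 ms pre-onset
window. Time-frequency power uses a 6-cycle Morlet bank on a log grid
(8 voices per octave) spanning 0.5–48 Hz; per-wavelet weights flatten
the bank's Littlewood–Paley sum so the five band powers (delta
0.5–4, theta 4–8, alpha 8–12, beta 12–30, gamma 30–48 Hz) tile the
total in-band power to within 10%. Band-power frames default to a
100 ms hop. Note the gamma band sits against the 48 Hz low-pass edge
and is slightly attenuated; this bias is documented rather than
corrected.

## Problem sizes and numerical conventions

The test-suite experiments run the generator at 128 Hz with 2 s trials
(5 s where delta-band resolution is needed) and 12–25 trials per class,
training for 20–40 epochs — sizes at which the planted effects are
recoverable and a full suite run completes on a laptop. The
separable-fixture and teaching-signal experiments use the paper-scale
100 epochs and batch 20. Degenerate inputs are handled explicitly:
constant channels encode to silence with a warning; rank-deficient data
make ICA return its input with a warning flag; unstable VAR fits and
insufficient samples are errors; all-identical K-means inputs are
flagged as a single effective cluster. Ties break deterministically
(lowest class index, alphabetical electrode, lowest node index).

## Known limitations

The decoder's accuracy on these synthetic tasks (roughly 75–90% binary
at desk scale) reflects the planted effect size and trial counts, not a
ceiling of the method. Pairwise (not fully conditional) Granger
causality will report indirect paths (x→z for a chain x→y→z); the
chain tests assert only direct-edge recovery and the absence of
reverse edges. The EasyMKL solver is a projected-gradient
implementation adequate for the few hundred trials used here; very
large kernels would want a dedicated QP solver. Four-class training is
supported by the same machinery but the shipped experiments exercise
the binary emotion-vs-neutral tasks that the mining procedure is
defined on.
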