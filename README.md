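# sbpsnn — emotional EEG decoding with a self-backpropagation spiking network

`sbpsnn` is an R package for decoding emotional state (fear, sadness,
happiness vs. neutral) from multichannel scalp EEG with a biologically
motivated spiking neural network, and for explaining the decoding: which
electrodes carry the signal, which frequency band is the biomarker, and
how the informative electrodes influence one another.

It is aimed at computational-neuroscience and affective-computing
researchers who want a fully testable, reference implementation of this
analysis style — including a synthetic EEG generator with known ground
truth, so every stage can be validated without access to human
recordings.

## The model

The decoder is a three-layer spiking network, 100 input / 200 hidden /
1 or 4 output neurons:

* **Spike coding.** Each channel is converted to ON/OFF spike trains by
  cumulative temporal contrast: an accumulator integrates the signed
  signal change and fires when it reaches ±θ, with θ = k·sd(Δx) pooled
  per channel across trials.
* **Neurons.** Leaky integrate-and-fire,
  dv/dt = (−(v − v_rest) + R_m·I)/τ_m, with threshold reset and a 2 ms
  refractory period. Hidden neurons are half excitatory, half
  inhibitory (Dale's sign constraint enforced after every update);
  they sit on a 471-node, 1 cm spatial lattice and are wired by a
  distance-based small-world rule (80% positive local connections).
* **Plasticity.** Tsodyks–Markram short-term facilitation/depression on
  every synapse; teacher-driven STDP at the output synapses, where the
  difference between a teaching spike train u_k and the realized output
  train is correlated with the presynaptic trace; multiplicative
  homeostatic threshold control on hidden neurons.
* **Self-backpropagation (SBP).** The output-synapse adjustments are
  mirrored one layer down with separate proportions for the
  potentiating (ρ_LTP = 0.9) and depressing (ρ_LTD = 0.6) parts,
  applied to synapses whose inputs were active around hidden spikes.
  Training minimizes C = ½Σ_k(u_k − o_k)², tracked per epoch; a
  rate-based network trained by exact backpropagation
  (W ← W − η·∂C/∂W, verified against finite differences) serves as the
  differentiable reference.

Around the decoder the package provides: standard EEG preprocessing
(order-4 zero-phase Butterworth 0.5–48 Hz, Infomax ICA blink removal,
average re-reference, 500 ms baseline correction, Morlet band power for
δ/θ/α/β/γ), seven-way scalp subnetwork partitioning and
contribution-ranked electrode elimination, two-cluster K-means fusion of
subnetwork models (BFM/SFM/BSM comparison), per-band decoding plus
EasyMKL kernel attribution of band contributions, and directed
connectivity by pairwise Geweke spectral Granger causality with
trial-shuffle surrogate thresholds.

## Worked example

```r
library(sbpsnn)

## a fear-vs-neutral task with doubled beta power on parietal electrodes
set <- standard_emotion_task("fear", n_trials_per_class = 20,
                             fs = 128, duration_s = 2, seed = 1)
#> <labeled_eeg_set> 40 trials (fear:20, neutral:20), 62 channels @ 128 Hz

## encode the parietal electrodes and train/evaluate the decoder
ds  <- encode_dataset(set, c("P1", "P2", "P5", "P6", "P7"))
fit <- fit_and_score(ds, train_config(epochs = 40, seed = 1),
                     montage = set$montage)
fit$report
#> <eval_report> binary: accuracy 75.00% (chance 50.00%), F1 0.750
#>           fear neutral
#>   fear       3       1
#>   neutral    1       3

## which band carries the signal?
mkl <- easymkl_contributions(
  standard_emotion_task("fear", n_trials_per_class = 12, fs = 128,
                        duration_s = 5, seed = 2),
  electrodes = c("P1", "P2", "P5", "P6", "P7"))
mkl
#> <mkl_result> band contributions (%):
#> delta theta alpha  beta gamma
#> 10.23 11.56 12.27 53.24 12.69

## directed influence on a known coupled pair
xy <- generate_var_pair(a = 0.5, order = 1, n = 20000, seed = 3)
g  <- spectral_granger(xy, order = 20, freqs = 1:48, fs = 250)
round(c(x_to_y = mean(g$values[1, 2, ]), y_to_x = mean(g$values[2, 1, ])), 4)
#> x_to_y y_to_x
#> 0.4774 0.0010
```

The decoder beats chance on the held-out trials (75% vs 50%), EasyMKL
attributes the bulk of the class information to the planted beta band
(53% of the kernel weight), and spectral Granger causality recovers the
planted x→y coupling direction (0.477 vs 0.001 in the reverse
direction).

`mine_subnetwork()`, `kmeans_2()`/`build_fusion()`/`rank_models()`, and
`directed_network()` continue from here; `run_pipeline(run_config(...))`
executes the whole chain and writes per-stage CSVs with a provenance
log. The methods vignette (`vignettes/emotion-decoding.Rmd`) documents
the model, every tunable parameter, and the design decisions.

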