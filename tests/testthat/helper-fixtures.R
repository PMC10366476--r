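# Fixtures shared across the suite. Everything is generated in code and
# seeded; sizes are chosen so the whole suite stays fast.

# Binary emotion-vs-neutral set at desk scale.
small_task <- function(seed = 1L, emotion = "fear", n = 12L, fs = 128,
                       duration_s = 2) {
  standard_emotion_task(emotion, n_trials_per_class = n, fs = fs,
                        duration_s = duration_s, seed = seed)
}

# Two informative electrodes (P1, P2) among five parietal ones.
planted_pair_set <- function(seed = 1L, n = 20L, fs = 128, duration_s = 2) {
  cfg <- synth_config(
    n_trials_per_class = n, classes = c("fear", "neutral"), fs = fs,
    duration_s = duration_s, artifact_rate = 0,
    effect_map = list(list(class = "fear", electrodes = c("P1", "P2"),
                           band = "beta", multiplier = 2)),
    seed = seed)
  generate_emotion_eeg(cfg)
}

# Trivially separable spike fixture: input neurons 1-20 fire densely for
# class A, everything else is sparse background.
separable_spike_data <- function(seed = 1L, n_per_class = 20L, T = 250L,
                                 dt = 0.004) {
  with_seed(seed, {
    labs <- rep(c("A", "B"), each = n_per_class)
    spikes <- lapply(labs, function(cls) {
      s <- matrix(rbinom(100 * T, 1, 0.02), 100, T)
      if (cls == "A") s[1:20, ] <- matrix(rbinom(20 * T, 1, 0.35), 20, T)
      s
    })
    list(spikes = spikes, labels = factor(labs, c("A", "B")), dt = dt)
  })
}

# Three-channel chain x -> y -> z with AR(1) own dynamics.
chain_var_trials <- function(n_trials = 8L, n = 1500L, seed = 1L) {
  lapply(seq_len(n_trials), function(i) {
    with_seed(seed * 1000L + i, {
      x <- numeric(n); y <- numeric(n); z <- numeric(n)
      ex <- rnorm(n); ey <- rnorm(n); ez <- rnorm(n)
      for (t in 2:n) {
        x[t] <- 0.5 * x[t - 1] + ex[t]
        y[t] <- 0.4 * y[t - 1] + 0.5 * x[t - 1] + ey[t]
        z[t] <- 0.4 * z[t - 1] + 0.5 * y[t - 1] + ez[t]
      }
      cbind(x = x, y = y, z = z)
    })
  })
}
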