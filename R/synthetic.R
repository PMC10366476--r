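#' Configuration for the synthetic emotional-EEG generator
#'
#' The generator emulates the statistical structure the downstream
#' analysis assumes: pink-noise (1/f) background EEG on every channel,
#' class-conditional band-power elevation on designated electrode
#' subsets, directed lagged coupling between chosen channel pairs, and
#' stereotyped blink artifacts on the frontal electrodes.
#'
#' @param n_subjects Number of subjects.
#' @param n_trials_per_class Trials per class per subject.
#' @param classes Class labels.
#' @param fs Sampling rate in Hz; must exceed twice the top analysis
#'   band edge (48 Hz), i.e. `fs > 96`.
#' @param duration_s Post-onset trial duration in seconds. Each trial
#'   additionally carries `baseline_s` seconds of pre-onset signal.
#' @param baseline_s Pre-onset baseline length in seconds.
#' @param effect_map List of effects, each a list with fields `class`,
#'   `electrodes` (character vector), `band` (name from [eeg_bands()]),
#'   and `multiplier` (> 0): trials of that class have the band power on
#'   those electrodes scaled by the multiplier.
#' @param coupling List of directed couplings, each a list with fields
#'   `src`, `sink` (electrode labels) and `coefs` (lag coefficients):
#'   the sink channel receives `sum_l coefs[l] * src[t - l]`.
#' @param artifact_rate Blink rate, events per minute.
#' @param noise_exponent Spectral slope of the background: power ~
#'   1/f^noise_exponent.
#' @param amplitude_uV Background standard deviation per channel, uV.
#' @param seed Integer seed fixing all randomness.
#' @return A `synth_config` list.
#' @export
synth_config <- function(n_subjects = 1L,
                         n_trials_per_class = 10L,
                         classes = c("fear", "sad", "happy", "neutral"),
                         fs = 250,
                         duration_s = 20,
                         baseline_s = 0.5,
                         effect_map = default_effect_map(),
                         coupling = list(),
                         artifact_rate = 4,
                         noise_exponent = 1,
                         amplitude_uV = 10,
                         seed = 1L) {
  cfg <- list(n_subjects = as.integer(n_subjects),
              n_trials_per_class = as.integer(n_trials_per_class),
              classes = classes, fs = fs, duration_s = duration_s,
              baseline_s = baseline_s, effect_map = effect_map,
              coupling = coupling, artifact_rate = artifact_rate,
              noise_exponent = noise_exponent, amplitude_uV = amplitude_uV,
              seed = as.integer(seed))
  class(cfg) <- "synth_config"
  validate_synth_config(cfg)
  cfg
}

validate_synth_config <- function(cfg) {
  if (cfg$fs <= 96) stop("fs must exceed 96 Hz (twice the 48 Hz top band edge)")
  if (cfg$n_trials_per_class < 1L) stop("need at least one trial per class")
  for (e in cfg$effect_map) {
    if (!all(c("class", "electrodes", "band", "multiplier") %in% names(e))) {
      stop("effect_map entries need fields class, electrodes, band, multiplier")
    }
    if (length(e$electrodes) == 0L) stop("empty electrode set in effect_map")
    if (e$multiplier <= 0) stop("effect multipliers must be > 0")
    if (!e$band %in% names(eeg_bands())) stop("unknown band: ", e$band)
  }
  invisible(cfg)
}

#' Default class-conditional effect map
#'
#' Beta-band elevation on parietal electrodes for the negative classes
#' (fear, sad) and alpha-band modulation on frontal-central /
#' frontal-temporal electrodes for the positive class (happy), mirroring
#' the electrode sets of the best single-subnetwork models for each
#' emotion. The default multiplier doubles band power.
#'
#' @param multiplier Band-power multiplier applied by each effect.
#' @return A list suitable for `synth_config(effect_map = ...)`.
#' @export
default_effect_map <- function(multiplier = 2) {
  list(
    list(class = "fear", electrodes = c("P1", "P2", "P5", "P6", "P7"),
         band = "beta", multiplier = multiplier),
    list(class = "sad", electrodes = c("P1", "P5", "Pz", "P7", "P8"),
         band = "beta", multiplier = multiplier),
    list(class = "happy", electrodes = c("FC1", "FC2", "FT7", "FT8"),
         band = "alpha", multiplier = multiplier)
  )
}

# 1/f^alpha noise of length n, unit variance, via spectral shaping.
pink_noise <- function(n, alpha) {
  nfft <- n
  w <- stats::rnorm(nfft)
  W <- stats::fft(w)
  f <- c(1, seq_len(nfft - 1))  # avoid DC blow-up
  f <- pmin(f, nfft - f + 1)    # mirror for negative frequencies
  W <- W * f^(-alpha / 2)
  x <- Re(stats::fft(W, inverse = TRUE)) / nfft
  as.numeric(scale(x))
}

# Band-limited zero-mean noise with unit variance.
band_noise <- function(n, fs, band) {
  ny <- fs / 2
  bf <- signal::butter(4, c(max(band[1], 0.01), min(band[2], ny * 0.99)) / ny,
                       type = "pass")
  x <- signal::filtfilt(bf, stats::rnorm(n + 2 * fs))
  x <- x[(fs + 1):(fs + n)]
  as.numeric(scale(x))
}

# Biphasic blink template of the given duration (seconds).
blink_template <- function(fs, dur = 0.3) {
  t <- seq(0, dur, by = 1 / fs)
  # positive lobe followed by a shallower negative lobe
  w <- sin(2 * pi * t / dur) * sin(pi * t / dur)^2
  w / max(abs(w))
}

#' Generate a labeled synthetic emotional-EEG set
#'
#' Produces one recording per trial on the standard 62-channel montage.
#' Each trial holds `baseline_s` seconds of pre-onset background plus
#' `duration_s` seconds of post-onset signal, with an event marker at
#' the onset. Band-power effects are injected additively: for each
#' configured (class, electrodes, band, multiplier) the generator adds
#' band-limited noise whose variance equals `(multiplier - 1)` times the
#' background's variance in that band, so an independent spectral
#' estimator recovers the configured power ratio.
#'
#' Ground truth needed by downstream tests is retained: each recording
#' carries attributes `clean` (the pre-artifact data matrix) and
#' `blink_onsets` (sample indices).
#'
#' @param cfg A [synth_config()].
#' @param montage Montage to simulate on (default [standard_montage_62()]).
#' @return A `labeled_eeg_set`: list with `recordings`, `labels`
#'   (factor), `subject` (integer), and `montage`.
#' @export
generate_emotion_eeg <- function(cfg, montage = standard_montage_62()) {
  validate_synth_config(cfg)
  with_seed(cfg$seed, {
    n_ch <- nrow(montage)
    n_pre <- round(cfg$baseline_s * cfg$fs)
    n_post <- round(cfg$duration_s * cfg$fs)
    n <- n_pre + n_post
    trials <- expand.grid(trial = seq_len(cfg$n_trials_per_class),
                          class = cfg$classes, subject = seq_len(cfg$n_subjects),
                          stringsAsFactors = FALSE)
    # blink spatial profile: exponential decay from the Fp midpoint
    coords <- as.matrix(montage[, c("x", "y", "z")])
    fp_idx <- match(c("Fp1", "Fp2"), montage$label)
    origin <- colMeans(coords[fp_idx[!is.na(fp_idx)], , drop = FALSE])
    d <- sqrt(rowSums(sweep(coords, 2, origin)^2))
    blink_profile <- 80 * exp(-d / 40)  # uV at the frontal pole
    tmpl <- blink_template(cfg$fs)

    recs <- vector("list", nrow(trials))
    for (i in seq_len(nrow(trials))) {
      cls <- trials$class[i]
      X <- matrix(0, n_ch, n)
      for (ch in seq_len(n_ch)) {
        X[ch, ] <- cfg$amplitude_uV * pink_noise(n, cfg$noise_exponent)
      }
      post <- (n_pre + 1):n
      for (e in cfg$effect_map) {
        if (e$class != cls || abs(e$multiplier - 1) < 1e-12) next
        band <- eeg_bands()[[e$band]]
        for (lab in e$electrodes) {
          ch <- match(lab, montage$label)
          if (is.na(ch)) stop("effect electrode not in montage: ", lab)
          p_bg <- band_power_welch(X[ch, post], cfg$fs, band)
          comp <- band_noise(length(post), cfg$fs, band)
          p_comp <- band_power_welch(comp, cfg$fs, band)
          X[ch, post] <- X[ch, post] +
            comp * sqrt(max(e$multiplier - 1, 0) * p_bg / p_comp)
        }
      }
      for (cp in cfg$coupling) {
        src <- match(cp$src, montage$label)
        sink <- match(cp$sink, montage$label)
        if (is.na(src) || is.na(sink)) stop("coupling electrode not in montage")
        for (l in seq_along(cp$coefs)) {
          X[sink, (l + 1):n] <- X[sink, (l + 1):n] +
            cp$coefs[l] * X[src, 1:(n - l)]
        }
      }
      clean <- X
      n_blinks <- stats::rpois(1, cfg$artifact_rate * (n / cfg$fs) / 60)
      onsets <- integer(0)
      if (n_blinks > 0) {
        onsets <- sort(sample.int(n - length(tmpl), n_blinks))
        for (o in onsets) {
          idx <- o:(o + length(tmpl) - 1L)
          X[, idx] <- X[, idx] + outer(blink_profile, tmpl)
        }
      }
      rec <- eeg_recording(X, cfg$fs, montage$label,
                           events = data.frame(onset = n_pre + 1L, code = cls))
      attr(rec, "clean") <- clean
      attr(rec, "blink_onsets") <- onsets
      recs[[i]] <- rec
    }
    structure(list(recordings = recs,
                   labels = factor(trials$class, levels = cfg$classes),
                   subject = trials$subject,
                   montage = montage,
                   config = cfg),
              class = "labeled_eeg_set")
  })
}

# Bandpass-filtered copy of a series (order-4 Butterworth, zero phase).
band_component <- function(x, fs, band) {
  ny <- fs / 2
  bf <- signal::butter(4, c(max(band[1], 0.01), min(band[2], ny * 0.99)) / ny,
                       type = "pass")
  as.numeric(signal::filtfilt(bf, x))
}

#' @export
print.labeled_eeg_set <- function(x, ...) {
  cat(sprintf("<labeled_eeg_set> %d trials (%s), %d channels @ %g Hz\n",
              length(x$recordings),
              paste(sprintf("%s:%d", levels(x$labels), table(x$labels)),
                    collapse = ", "),
              nrow(x$montage), x$recordings[[1]]$fs))
  invisible(x)
}

#' Two-channel VAR fixture with known directed coupling
#'
#' Generates a pair of series in which `y` depends on lagged `x` with
#' coefficient `a` at each of `order` lags, while `x` is an autonomous
#' AR(1) with coefficient 0.5 and `y` has own-lag coefficient 0.4.
#' Innovations are unit-variance white noise. The implied bivariate VAR
#' must be stable (companion-matrix spectral radius < 1).
#'
#' @param a Coupling coefficient from `x` to `y`.
#' @param order Number of coupled lags (>= 1).
#' @param n Number of samples (> 0).
#' @param seed Integer seed.
#' @return Numeric matrix with columns `x` and `y`.
#' @export
generate_var_pair <- function(a, order = 1L, n, seed = 1L) {
  if (n <= 0) stop("n must be positive")
  if (order < 1L) stop("order must be >= 1")
  if (abs(a) >= 1) stop("|a| must be < 1 for stability")
  p <- max(order, 1L)
  A <- array(0, c(2, 2, p))
  A[1, 1, 1] <- 0.5
  A[2, 2, 1] <- 0.4
  for (l in seq_len(order)) A[2, 1, l] <- a
  if (companion_radius(A) >= 1) stop("unstable coefficient set (spectral radius >= 1)")
  with_seed(seed, {
    burn <- 200L
    m <- n + burn
    x <- numeric(m); y <- numeric(m)
    ex <- stats::rnorm(m); ey <- stats::rnorm(m)
    for (t in (p + 1):m) {
      x[t] <- 0.5 * x[t - 1] + ex[t]
      y[t] <- 0.4 * y[t - 1] + sum(A[2, 1, ] * x[t - seq_len(p)]) + ey[t]
    }
    cbind(x = x[(burn + 1):m], y = y[(burn + 1):m])
  })
}

# Spectral radius of the VAR companion matrix for a k x k x p array.
companion_radius <- function(A) {
  k <- dim(A)[1]; p <- dim(A)[3]
  C <- matrix(0, k * p, k * p)
  for (l in seq_len(p)) C[1:k, ((l - 1) * k + 1):(l * k)] <- A[, , l]
  if (p > 1) C[(k + 1):(k * p), 1:(k * (p - 1))] <- diag(k * (p - 1))
  max(Mod(eigen(C, only.values = TRUE)$values))
}

#' Canonical binary emotion task
#'
#' Convenience wrapper building the standard synthetic task used by the
#' experiments: one emotion versus neutral, with the default effect map
#' restricted to those classes.
#'
#' @param emotion One of "fear", "sad", "happy".
#' @param n_trials_per_class Trials per class.
#' @param fs,duration_s,multiplier,seed Passed to [synth_config()] /
#'   [default_effect_map()].
#' @return A `labeled_eeg_set` with two classes.
#' @export
standard_emotion_task <- function(emotion = "fear", n_trials_per_class = 20L,
                                  fs = 250, duration_s = 20,
                                  multiplier = 2, seed = 1L) {
  stopifnot(emotion %in% c("fear", "sad", "happy"))
  cfg <- synth_config(
    n_trials_per_class = n_trials_per_class,
    classes = c(emotion, "neutral"),
    fs = fs, duration_s = duration_s,
    effect_map = Filter(function(e) e$class == emotion, default_effect_map(multiplier)),
    artifact_rate = 0,
    seed = seed
  )
  generate_emotion_eeg(cfg)
}

#' Write a labeled EEG set to a directory of delimited files
#'
#' One TSV matrix per trial (channels in columns), a `labels.tsv`
#' sidecar (trial, subject, onset, class) and a `montage.tsv`.
#'
#' @param set A `labeled_eeg_set`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_eeg_set <- function(set, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_along(set$recordings)) {
    rec <- set$recordings[[i]]
    m <- t(rec$data)
    colnames(m) <- rec$labels
    utils::write.table(m, file.path(dir, sprintf("trial_%03d.tsv", i)),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  }
  sidecar <- data.frame(
    trial = seq_along(set$recordings),
    subject = set$subject,
    onset = vapply(set$recordings, function(r) r$events$onset[1], numeric(1)),
    class = as.character(set$labels)
  )
  utils::write.table(sidecar, file.path(dir, "labels.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  write_montage(set$montage, file.path(dir, "montage.tsv"))
  invisible(dir)
}
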