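make_tone <- function(freq, fs = 250, dur = 10, amp = 1) {
  t <- seq(0, dur, by = 1 / fs)
  eeg_recording(matrix(amp * sin(2 * pi * freq * t), 1), fs, "Cz")
}

test_that("bandpass attenuates out-of-band tones and passes 10 Hz", {
  fs <- 250
  keep <- seq(fs, 9 * fs)  # trim filter edge transients
  r60 <- bandpass(make_tone(60, fs))
  att_db <- 20 * log10(sqrt(mean(r60$data[1, keep]^2)) / sqrt(0.5))
  expect_lt(att_db, -20)
  rdc <- make_tone(10, fs)
  rdc$data <- rdc$data + 100
  out <- bandpass(rdc)
  expect_lt(abs(mean(out$data[1, keep])), 1)
  r10 <- bandpass(make_tone(10, fs))
  amp10 <- sqrt(2 * mean(r10$data[1, keep]^2))
  expect_gt(amp10, 0.95)
  expect_lt(amp10, 1.05)
})

test_that("bandpass validates its inputs", {
  expect_error(bandpass(make_tone(10, fs = 80)), "too low")
  expect_error(bandpass(make_tone(10), order = 0), "order")
})

test_that("average reference zeroes every sample mean and is idempotent", {
  set.seed(1)
  rec <- eeg_recording(matrix(rnorm(5 * 100), 5), 100, paste0("c", 1:5))
  ref <- rereference_average(rec)
  expect_lt(max(abs(colMeans(ref$data))), 1e-9)
  expect_equal(rereference_average(ref)$data, ref$data, tolerance = 1e-12)
  pair <- eeg_recording(rbind(rec$data[1, ], -rec$data[1, ]), 100, c("a", "b"))
  expect_equal(rereference_average(pair)$data, pair$data, tolerance = 1e-12)
  expect_error(rereference_average(eeg_recording(matrix(1, 1, 10), 100, "a")),
               ">= 2 channels")
})

test_that("filtering and re-referencing commute", {
  set.seed(2)
  rec <- eeg_recording(matrix(rnorm(4 * 2000), 4), 250, paste0("c", 1:4))
  a <- rereference_average(bandpass(rec))
  b <- bandpass(rereference_average(rec))
  expect_lt(max(abs(a$data - b$data)) / max(abs(a$data)), 1e-6)
})

test_that("ICA removes injected blinks but spares clean data", {
  cfg <- synth_config(n_trials_per_class = 1, classes = "neutral", fs = 128,
                      duration_s = 20, artifact_rate = 20, effect_map = list(),
                      seed = 5)
  rec <- generate_emotion_eeg(cfg)$recordings[[1]]
  clean <- attr(rec, "clean")
  onsets <- attr(rec, "blink_onsets")
  expect_gt(length(onsets), 1)
  out <- remove_artifacts_ica(rec)
  expect_gt(attr(out, "n_removed"), 0)
  idx <- unlist(lapply(onsets, function(o) o:(o + round(0.3 * rec$fs))))
  fp1 <- match("Fp1", rec$labels)
  rms <- function(x) sqrt(mean(x^2))
  before <- rms(rec$data[fp1, idx] - clean[fp1, idx])
  after <- rms(out$data[fp1, idx] - clean[fp1, idx])
  expect_lt(after, 0.5 * before)

  cfg0 <- synth_config(n_trials_per_class = 1, classes = "neutral", fs = 128,
                       duration_s = 10, artifact_rate = 0, effect_map = list(),
                       seed = 6)
  rec0 <- generate_emotion_eeg(cfg0)$recordings[[1]]
  out0 <- remove_artifacts_ica(rec0, corr_threshold = 0.9)
  expect_equal(attr(out0, "n_removed"), 0L)
  expect_error(remove_artifacts_ica(rec0, corr_threshold = 0), "> 0")
})

test_that("ICA failure on rank-deficient data returns input with a warning", {
  x <- sin(2 * pi * 3 * seq(0, 5, by = 1 / 100))
  rec <- eeg_recording(rbind(x, x, x, x), 100,
                       c("Fp1", "Fp2", "Cz", "Pz"))
  expect_warning(out <- remove_artifacts_ica(rec, n_comp = 4L), "ICA failed")
  expect_true(attr(out, "ica_failed"))
  expect_equal(out$data, rec$data)
})

test_that("epoching subtracts the pre-onset baseline", {
  fs <- 100
  rec <- eeg_recording(matrix(5, 2, 500), fs, c("a", "b"),
                       events = data.frame(onset = 200L, code = "x"))
  eps <- epoch_and_baseline(rec, 200L, baseline_s = 0.5, duration_s = 1)
  expect_length(eps, 1L)
  expect_lt(max(abs(eps[[1]]$data)), 1e-12)
  set.seed(3)
  rec2 <- eeg_recording(matrix(rnorm(1000), 2), fs, c("a", "b"))
  ep2 <- epoch_and_baseline(rec2, 300L, baseline_s = 0.5, duration_s = 1)[[1]]
  base <- ep2$data[, 1:50]
  expect_lt(max(abs(rowMeans(base))), 1e-9)
  expect_error(epoch_and_baseline(rec2, 10L, baseline_s = 0.5), "baseline")
})

test_that("wavelet band power localizes tones to the right bands", {
  bp10 <- wavelet_band_power(make_tone(10, dur = 6))
  frac <- rowMeans(bp10$power[1, , ]) / sum(rowMeans(bp10$power[1, , ]))
  expect_gt(frac["alpha"], 0.8)
  bp20 <- wavelet_band_power(make_tone(20, dur = 6))
  expect_equal(names(which.max(rowMeans(bp20$power[1, , ]))), "beta")
  z <- eeg_recording(matrix(0, 1, 1500), 250, "Cz")
  expect_lt(max(wavelet_band_power(z)$power), 1e-20)
  expect_true(all(bp10$power >= 0))
  short <- eeg_recording(matrix(rnorm(200), 1), 250, "Cz")
  expect_error(wavelet_band_power(short), "support")
})

test_that("band powers tile the 0.5-48 Hz range", {
  set.seed(4)
  fs <- 250
  x <- signal::filtfilt(signal::butter(4, c(0.5, 48) / (fs / 2), "pass"),
                        rnorm(10 * fs))
  x <- as.numeric(scale(x))
  bp <- wavelet_band_power(eeg_recording(matrix(x, 1), fs, "Cz"))
  total <- sum(rowMeans(bp$power[1, , ]))
  expect_gt(total, 0.9)   # total in-band power of the unit-variance input
  expect_lt(total, 1.1)
})

test_that("ERSP reports baseline-normalized dB correctly", {
  fs <- 250
  t_pre <- seq(-1, 0, by = 1 / fs)[-1]
  t_post <- seq(0, 2, by = 1 / fs)[-1]
  x <- c(sin(2 * pi * 20 * t_pre), sqrt(2) * sin(2 * pi * 20 * t_post))
  ep <- eeg_recording(matrix(x, 1), fs, "Cz",
                      events = data.frame(onset = length(t_pre) + 1L,
                                          code = "onset"))
  r <- ersp(list(ep))
  fi <- which.min(abs(r$freqs - 20))
  mid <- r$times > 0.5 & r$times < 1.5
  expect_equal(median(r$db[fi, mid]), 3, tolerance = 0.5)
  # stationary tone vs its own baseline: ~0 dB away from edges
  x0 <- sin(2 * pi * 20 * c(t_pre, t_post))
  ep0 <- eeg_recording(matrix(x0, 1), fs, "Cz",
                       events = data.frame(onset = length(t_pre) + 1L,
                                           code = "onset"))
  r0 <- ersp(list(ep0))
  expect_lt(max(abs(r0$db[fi, mid])), 0.2)
  expect_error(ersp(list(ep), baseline_power = rep(0, length(r$freqs))),
               "zero baseline")
  expect_error(ersp(list()), "at least one")
})
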