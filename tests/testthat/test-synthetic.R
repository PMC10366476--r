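test_that("configs are validated", {
  expect_error(synth_config(fs = 96), "96 Hz")
  expect_error(synth_config(effect_map = list(
    list(class = "fear", electrodes = character(0), band = "beta",
         multiplier = 2))), "empty electrode")
  expect_error(synth_config(effect_map = list(
    list(class = "fear", electrodes = "P1", band = "beta",
         multiplier = 0))), "multipliers")
  expect_error(synth_config(effect_map = list(
    list(class = "fear", electrodes = "P1", band = "sigma",
         multiplier = 2))), "unknown band")
})

test_that("generation is bit-identical under a fixed seed", {
  cfg <- synth_config(n_trials_per_class = 2, classes = c("fear", "neutral"),
                      fs = 128, duration_s = 2, seed = 42)
  a <- generate_emotion_eeg(cfg)
  b <- generate_emotion_eeg(cfg)
  for (i in seq_along(a$recordings)) {
    expect_identical(a$recordings[[i]]$data, b$recordings[[i]]$data)
  }
  expect_identical(a$labels, b$labels)
})

test_that("null effect map leaves class band powers comparable", {
  cfg <- synth_config(n_trials_per_class = 4, classes = c("fear", "neutral"),
                      fs = 128, duration_s = 20, artifact_rate = 0,
                      effect_map = list(), seed = 7)
  set <- generate_emotion_eeg(cfg)
  beta <- eeg_bands()$beta
  bp <- vapply(set$recordings, function(r) {
    x <- r$data[match("P1", r$labels), ]
    p <- welch_psd(x, r$fs)
    mean(p$psd[p$freq >= beta[1] & p$freq <= beta[2]])
  }, numeric(1))
  ratio <- mean(bp[set$labels == "fear"]) / mean(bp[set$labels == "neutral"])
  expect_gt(ratio, 0.8)
  expect_lt(ratio, 1.25)
})

test_that("a 2x beta effect is recovered by an independent Welch estimator", {
  # ~600 s of signal split across classes
  cfg <- synth_config(n_trials_per_class = 5, classes = c("fear", "neutral"),
                      fs = 250, duration_s = 60, artifact_rate = 0,
                      effect_map = list(list(class = "fear", electrodes = "P1",
                                             band = "beta", multiplier = 2)),
                      seed = 3)
  set <- generate_emotion_eeg(cfg)
  beta <- eeg_bands()$beta
  bp <- vapply(set$recordings, function(r) {
    x <- r$data[match("P1", r$labels), r$events$onset[1]:ncol(r$data)]
    p <- welch_psd(x, r$fs)
    mean(p$psd[p$freq >= beta[1] & p$freq <= beta[2]])
  }, numeric(1))
  ratio <- mean(bp[set$labels == "fear"]) / mean(bp[set$labels == "neutral"])
  expect_gt(ratio, 1.7)
  expect_lt(ratio, 2.3)
})

test_that("background follows the configured 1/f spectral slope", {
  cfg <- synth_config(n_trials_per_class = 1, classes = "neutral", fs = 250,
                      duration_s = 60, artifact_rate = 0, effect_map = list(),
                      noise_exponent = 1, seed = 9)
  rec <- generate_emotion_eeg(cfg)$recordings[[1]]
  p <- welch_psd(rec$data[1, ], rec$fs)
  sel <- p$freq >= 2 & p$freq <= 40
  slope <- stats::coef(stats::lm(log(p$psd[sel]) ~ log(p$freq[sel])))[2]
  expect_lt(abs(slope - (-1)), 0.3)
})

test_that("VAR pair fixture is directional, stationary, and validated", {
  expect_error(generate_var_pair(0.5, 1, 0), "positive")
  expect_error(generate_var_pair(1.2, 1, 100), "< 1")
  expect_error(generate_var_pair(0.5, 0, 100), "order")
  xy <- generate_var_pair(0.5, 1, 8000, seed = 5)
  expect_equal(colnames(xy), c("x", "y"))
  # stationarity: no variance drift beyond 2x between first/last quarters
  q <- nrow(xy) %/% 4
  for (cc in 1:2) {
    v1 <- stats::var(xy[1:q, cc]); v4 <- stats::var(xy[(3 * q):(4 * q), cc])
    expect_lt(max(v1 / v4, v4 / v1), 2)
  }
  # y variance exceeds x (driven), deterministic given seed
  expect_identical(xy, generate_var_pair(0.5, 1, 8000, seed = 5))
})

test_that("labeled sets serialize to delimited files", {
  set <- small_task(seed = 2, n = 2)
  dir <- withr::local_tempdir()
  write_eeg_set(set, dir)
  expect_true(file.exists(file.path(dir, "labels.tsv")))
  expect_true(file.exists(file.path(dir, "montage.tsv")))
  expect_length(list.files(dir, pattern = "^trial_"), length(set$recordings))
  sidecar <- utils::read.table(file.path(dir, "labels.tsv"), header = TRUE,
                               sep = "\t")
  expect_equal(as.character(sidecar$class), as.character(set$labels))
})

test_that("blink artifacts are stereotyped, frontal-dominant, and logged", {
  cfg <- synth_config(n_trials_per_class = 1, classes = "neutral", fs = 128,
                      duration_s = 20, artifact_rate = 30, effect_map = list(),
                      seed = 8)
  rec <- generate_emotion_eeg(cfg)$recordings[[1]]
  onsets <- attr(rec, "blink_onsets")
  expect_gt(length(onsets), 0)
  clean <- attr(rec, "clean")
  art <- rec$data - clean
  fp1 <- match("Fp1", rec$labels); oz <- match("Oz", rec$labels)
  expect_gt(max(abs(art[fp1, ])), 10 * max(abs(art[oz, ])))
})
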