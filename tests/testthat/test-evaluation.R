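test_that("accuracy and F1 match hand-computed confusion matrices", {
  expect_equal(evaluate(c("a", "b"), c("a", "b"), "binary")$accuracy, 100)
  expect_equal(evaluate(c("a", "b"), c("a", "b"), "binary")$f1, 1)
  # TP=3, FP=1, FN=1, TN=5 with positive class "p"
  preds <- c(rep("p", 3), "n", rep("n", 5), "p")
  labels <- c(rep("p", 3), "p", rep("n", 5), "n")
  r <- evaluate(preds, labels, "binary", classes = c("p", "n"))
  expect_equal(r$accuracy, 80)
  expect_equal(r$f1, 0.75)
  expect_equal(unname(rowSums(r$confusion)), c(4, 6))  # class counts
  expect_equal(sum(diag(r$confusion)) / sum(r$confusion) * 100, r$accuracy)
  # all-positive predictions in balanced binary
  r2 <- evaluate(rep("p", 10), rep(c("p", "n"), 5), "binary",
                 classes = c("p", "n"))
  expect_equal(r2$accuracy, 50)
  expect_equal(r2$f1, 2 / 3)
  expect_equal(r2$chance, 50)
})

test_that("four-class F1 is the unweighted macro mean", {
  classes <- c("fear", "sad", "happy", "neutral")
  preds <- c("fear", "sad", "happy", "neutral", "fear", "sad")
  labels <- c("fear", "sad", "happy", "neutral", "sad", "fear")
  r <- evaluate(preds, labels, "multiclass", classes = classes)
  f1_of <- function(cl) {
    tp <- sum(preds == cl & labels == cl)
    if (tp == 0) return(0)
    p <- tp / sum(preds == cl); rec <- tp / sum(labels == cl)
    2 * p * rec / (p + rec)
  }
  expect_equal(r$f1, mean(vapply(classes, f1_of, numeric(1))))
})

test_that("evaluation rejects malformed input", {
  expect_error(evaluate(character(), character(), "binary"), "empty")
  expect_error(evaluate("a", c("a", "b"), "binary"), "length")
  expect_error(evaluate("z", "a", "binary", classes = c("a", "b")),
               "class set")
})

test_that("run configs validate and round-trip through YAML", {
  cfg <- run_config(emotion = "sad", n_trials_per_class = 4, epochs = 3,
                    seed = 9)
  path <- withr::local_tempfile(fileext = ".yaml")
  write_run_config(cfg, path)
  cfg2 <- read_run_config(path)
  expect_equal(unclass(cfg2), unclass(cfg))
  expect_error(run_config(emotion = NULL), "emotion")
})

test_that("the pipeline runs end to end and rewrites identical metrics", {
  cfg <- run_config(n_trials_per_class = 4, epochs = 3, subnetworks = 1L,
                    bands = "beta", duration_s = 5, fs = 128, seed = 2)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  run_pipeline(cfg, d1)
  expected <- c("mine_subnetwork_1.csv", "fusion_points.csv",
                "band_decoding.csv", "mkl_contributions.csv",
                "granger_edges.csv", "provenance.log")
  expect_true(all(file.exists(file.path(d1, expected))))
  run_pipeline(cfg, d2)
  for (f in setdiff(expected, "provenance.log")) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     info = f)
  }
  # provenance embeds the config hash at every stage
  log1 <- readLines(file.path(d1, "provenance.log"))
  expect_true(all(grepl(sbpsnn:::config_hash(cfg), log1)))
})

test_that("a failing stage is reported with its name", {
  cfg <- run_config(n_trials_per_class = 4, epochs = 3, subnetworks = 1L,
                    bands = "beta", duration_s = 2, fs = 128, seed = 2)
  # 2 s trials are too short for the slowest wavelet: the bands stage fails
  expect_error(run_pipeline(cfg, withr::local_tempdir()), "stage 'bands'")
})
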