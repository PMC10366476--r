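test_that("weight contributions normalize to 100 with sensible edge cases", {
  dec <- decoder_new(c("P1", "P2", "P5"), c("A", "B"), seed = 1)
  pct <- electrode_contribution(dec)
  expect_equal(sum(pct), 100, tolerance = 1e-9)
  expect_setequal(names(pct), c("P1", "P2", "P5"))
  # zeroed electrode gets 0%
  dec2 <- dec
  dec2$W_ih[dec2$map$channel == "P5", ] <- 0
  expect_equal(electrode_contribution(dec2, "P5"), 0)
  # single-electrode decoder concentrates everything
  dec1 <- decoder_new("P1", c("A", "B"), seed = 2)
  expect_equal(unname(electrode_contribution(dec1)), 100)
  expect_error(electrode_contribution(dec, "Oz"), "absent")
})

test_that("contributions are near-uniform for identically distributed weights", {
  dec <- decoder_new(c("P1", "P2", "P5", "P6"), c("A", "B"), seed = 3)
  # replace weights by an exchangeable draw across input neurons
  with_seed(4, dec$W_ih[] <- rnorm(length(dec$W_ih)))
  pct <- electrode_contribution(dec)
  expect_true(all(abs(pct - 25) < 5))
})

test_that("mining produces a strictly shrinking, conserving trace", {
  set <- planted_pair_set(seed = 5, n = 10, duration_s = 1)
  trace <- mine_subnetwork(set, c("P1", "P2", "P5", "P6", "P7"),
                           train_config(epochs = 8, seed = 6))
  sizes <- vapply(trace$steps, function(s) length(s$electrodes), integer(1))
  expect_equal(sizes[1], 5L)
  expect_true(all(diff(sizes) == -1))
  for (s in trace$steps) {
    expect_equal(sum(s$contributions), 100, tolerance = 0.1)
    expect_true(s$accuracy >= 0 && s$accuracy <= 100)
    expect_true(s$f1 >= 0 && s$f1 <= 1)
  }
  # every eliminated electrode was the arg-min contribution of its step
  for (s in trace$steps[-length(trace$steps)]) {
    expect_equal(s$eliminated,
                 names(which.min(s$contributions[sort(s$electrodes)])))
  }
  df <- mining_trace_df(trace)
  expect_equal(nrow(df), length(trace$steps))
  expect_true(all(c("electrodes", "eliminated", "accuracy", "f1") %in%
                    names(df)))
})

test_that("a single-electrode subnetwork yields a one-step trace", {
  set <- planted_pair_set(seed = 7, n = 8, duration_s = 1)
  trace <- mine_subnetwork(set, "P1", train_config(epochs = 5, seed = 8))
  expect_length(trace$steps, 1L)
  sel <- select_best_simplest(trace)
  expect_equal(sel$best$index, 1L)
  expect_equal(sel$simplest$index, 1L)
  expect_error(mine_subnetwork(set, character(0)), "empty")
})

test_that("best/simplest selection breaks ties by F1 then model size", {
  mk_step <- function(n_el, acc, f1) {
    list(electrodes = paste0("E", seq_len(n_el)),
         contributions = stats::setNames(rep(100 / n_el, n_el),
                                         paste0("E", seq_len(n_el))),
         eliminated = "E1", accuracy = acc, f1 = f1)
  }
  trace <- structure(list(steps = list(
    mk_step(5, 59, 0.59), mk_step(4, 73, 0.74), mk_step(3, 70, 0.70),
    mk_step(2, 68, 0.70), mk_step(1, 73, 0.74)), subnetwork = NULL),
    class = "mining_trace")
  sel <- select_best_simplest(trace)
  expect_equal(sel$best$index, 5L)      # tie on acc and F1 -> fewer electrodes
  expect_equal(sel$simplest$index, 5L)
  dec_trace <- structure(list(steps = list(
    mk_step(3, 80, 0.8), mk_step(2, 70, 0.7), mk_step(1, 60, 0.6)),
    subnetwork = NULL), class = "mining_trace")
  expect_equal(select_best_simplest(dec_trace)$best$index, 1L)
  expect_error(select_best_simplest(structure(list(steps = list()),
                                              class = "mining_trace")),
               "empty")
})
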