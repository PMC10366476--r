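test_that("VAR fitting recovers known coefficients", {
  xy <- generate_var_pair(0.5, 1, 20000, seed = 1)
  fit <- sbpsnn:::var_fit(xy, 1)
  expect_equal(fit$A[1, 1, 1], 0.5, tolerance = 0.05)
  expect_equal(fit$A[2, 2, 1], 0.4, tolerance = 0.05)
  expect_equal(fit$A[2, 1, 1], 0.5, tolerance = 0.05)
  expect_equal(fit$A[1, 2, 1], 0, tolerance = 0.05)
  expect_lt(fit$radius, 1)
  # independent oracle: stats::ar.ols on the same data
  ar <- stats::ar.ols(xy, order.max = 1, aic = FALSE, demean = TRUE,
                      intercept = FALSE)
  expect_equal(unname(fit$A[, , 1]), unname(ar$ar[1, , ]), tolerance = 0.02)
})

test_that("spectral GC is non-negative and strongly directional on coupled pairs", {
  xy <- generate_var_pair(0.5, 1, 20000, seed = 2)
  g <- spectral_granger(xy, order = 20, freqs = 1:48, fs = 250)
  expect_true(all(g$values[!is.na(g$values)] >= 0))
  expect_true(all(is.na(diag(g$values[, , 1]))))
  ratio <- mean(g$values[1, 2, ]) / mean(g$values[2, 1, ])
  expect_gte(ratio, 5)
})

test_that("independent channels show near-zero GC", {
  with_seed(3, wn <- cbind(rnorm(10000), rnorm(10000)))
  g <- spectral_granger(wn, order = 20, freqs = 1:48, fs = 250)
  expect_lt(mean(g$values[1, 2, ]), 0.02)
  expect_lt(mean(g$values[2, 1, ]), 0.02)
})

test_that("GC is equivariant under channel permutation", {
  trials <- chain_var_trials(n_trials = 1, n = 6000, seed = 4)
  X <- trials[[1]]
  g1 <- spectral_granger(X, order = 10, freqs = 1:30, fs = 250)
  g2 <- spectral_granger(X[, c(3, 1, 2)], order = 10, freqs = 1:30, fs = 250)
  # pair (x -> y) in g1 is pair (col2 -> col3) in the permuted data
  expect_equal(unname(g1$values[1, 2, ]), unname(g2$values[2, 3, ]),
               tolerance = 1e-9)
  expect_equal(unname(g1$values[3, 1, ]), unname(g2$values[1, 2, ]),
               tolerance = 1e-9)
})

test_that("GC rejects undersized or unstable inputs", {
  expect_error(spectral_granger(matrix(rnorm(60), 30, 2), order = 20, fs = 100),
               "insufficient")
  with_seed(9, {
    ex <- numeric(300); ey <- numeric(300)
    for (t in 2:300) {  # explosive AR(1) pair
      ex[t] <- 1.02 * ex[t - 1] + rnorm(1)
      ey[t] <- 1.02 * ey[t - 1] + rnorm(1)
    }
  })
  expect_error(spectral_granger(cbind(ex, ey), order = 2, freqs = 1:10,
                                fs = 100),
               "unstable")
})

test_that("surrogate-thresholded network recovers a planted chain", {
  trials <- chain_var_trials(n_trials = 8, n = 1200, seed = 5)
  g <- spectral_granger(trials, order = 10, freqs = 1:48, fs = 250)
  net <- directed_network(g, "beta", trials, n_surrogates = 20, seed = 6)
  edges <- paste(net$edges$source, net$edges$sink, sep = ">")
  expect_true("x>y" %in% edges)
  expect_true("y>z" %in% edges)
  expect_false("z>x" %in% edges)
  expect_false(any(net$edges$source == net$edges$sink))
  expect_true(all(net$edges$strength > net$edges$threshold))
  expect_error(directed_network(g, "beta", trials, n_surrogates = 0),
               "required")
  expect_error(directed_network(g, "beta", trials[1], n_surrogates = 5),
               ">= 2 trials")
  expect_error(gc_band_average(g, c(200, 300)), "outside")
})

test_that("coherence is 1 for identical channels and ~1/K for noise", {
  x <- with_seed(7, rnorm(5000))
  rec <- eeg_recording(rbind(a = x, b = x), 250, c("a", "b"))
  cs <- coherence_summary(rec)
  expect_true(all(cs$coherence > 0.99))
  noise <- with_seed(8, eeg_recording(rbind(a = rnorm(10000), b = rnorm(10000)),
                                      250, c("a", "b")))
  cs0 <- coherence_summary(noise)
  K <- attr(cs0, "n_segments")
  expect_true(all(cs0$coherence >= 0 & cs0$coherence <= 1))
  expect_lt(mean(cs0$coherence), 3 / K)
  expect_gt(mean(cs0$coherence), 1 / (3 * K))
  expect_error(coherence_summary(noise, electrodes = "a"), "at least 2")
  expect_error(coherence_summary(noise, seg_len = 1e6), "exceeds")
})
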