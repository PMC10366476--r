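# OLS fit of a VAR(p): X is samples x channels, or a list of trials
# (each samples x channels) pooled into one regression. Returns
# coefficient array A (k x k x p), innovation covariance Sigma, and the
# companion-matrix spectral radius.
var_fit <- function(X, p) {
  trials <- if (is.list(X)) X else list(X)
  trials <- lapply(trials, as.matrix)
  k <- ncol(trials[[1]])
  YZ <- lapply(trials, function(M) {
    n <- nrow(M)
    if (n <= p) stop("trial shorter than the VAR order")
    Y <- M[(p + 1):n, , drop = FALSE]
    Z <- do.call(cbind, lapply(1:p, function(l) M[(p + 1 - l):(n - l), , drop = FALSE]))
    list(Y = Y, Z = Z)
  })
  Y <- do.call(rbind, lapply(YZ, `[[`, "Y"))
  Z <- do.call(rbind, lapply(YZ, `[[`, "Z"))
  if (nrow(Y) < ncol(Z) * 2) stop("insufficient samples for VAR order ", p)
  fit <- stats::lm.fit(Z, Y)
  B <- as.matrix(fit$coefficients)
  res <- Y - Z %*% B
  Sigma <- crossprod(res) / (nrow(Y) - ncol(Z))
  A <- array(0, c(k, k, p))
  for (l in 1:p) A[, , l] <- t(B[((l - 1) * k + 1):(l * k), , drop = FALSE])
  list(A = A, Sigma = Sigma, radius = companion_radius(A))
}

# Geweke spectral GC for one ordered channel pair from a fitted
# bivariate VAR: f_{x->y}(f) = ln(S_yy / (S_yy - (S_xx - S_xy^2/S_yy)|H_yx|^2)).
geweke_pair_gc <- function(fit, freqs, fs) {
  A <- fit$A; S <- fit$Sigma
  p <- dim(A)[3]
  gc <- matrix(0, 2, length(freqs),
               dimnames = list(c("x->y", "y->x"), freqs))
  for (i in seq_along(freqs)) {
    z <- exp(-2i * pi * freqs[i] / fs * (1:p))
    Af <- diag(2) - apply(A, c(1, 2), function(a) sum(a * z))
    H <- solve(Af)
    Sf <- H %*% S %*% Conj(t(H))
    s22 <- Re(Sf[2, 2])
    s11 <- Re(Sf[1, 1])
    num_xy <- (S[1, 1] - S[1, 2]^2 / S[2, 2]) * Mod(H[2, 1])^2
    num_yx <- (S[2, 2] - S[1, 2]^2 / S[1, 1]) * Mod(H[1, 2])^2
    gc[1, i] <- max(log(s22 / max(s22 - num_xy, .Machine$double.eps)), 0)
    gc[2, i] <- max(log(s11 / max(s11 - num_yx, .Machine$double.eps)), 0)
  }
  gc
}

#' Pairwise spectral Granger causality
#'
#' For every directed channel pair, fits a bivariate VAR of the given
#' order by OLS (with a companion-matrix stability check) and evaluates
#' the Geweke spectral decomposition at the requested frequencies:
#' the causal contribution of the source to the sink's power spectrum,
#' `ln(S_yy(f) / S~_yy(f))`, which is non-negative everywhere.
#'
#' @param data Samples x channels matrix, a channels x samples matrix
#'   with row labels, or a list of trial matrices (samples x channels)
#'   pooled into one fit.
#' @param order VAR model order (default 20).
#' @param freqs Frequencies to evaluate, Hz (default the integers
#'   1-48).
#' @param fs Sampling rate, Hz.
#' @param labels Channel labels (defaults to column names).
#' @return A `gc_matrix`: list with `values` (source x sink x frequency
#'   array, diagonal NA), `freqs`, `order`, `labels`.
#' @export
spectral_granger <- function(data, order = 20L, freqs = 1:48, fs,
                             labels = NULL) {
  trials <- if (is.list(data)) data else list(data)
  trials <- lapply(trials, function(M) {
    M <- as.matrix(M)
    # accept channels x samples with labelled rows
    if (!is.null(rownames(M)) && is.null(colnames(M))) M <- t(M)
    M
  })
  k <- ncol(trials[[1]])
  if (is.null(labels)) labels <- colnames(trials[[1]])
  if (is.null(labels)) labels <- paste0("ch", seq_len(k))
  n_tot <- sum(vapply(trials, nrow, integer(1)))
  if (n_tot < 10 * order) stop("insufficient samples for VAR order ", order)
  vals <- array(NA_real_, c(k, k, length(freqs)),
                dimnames = list(labels, labels, freqs))
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    fit <- var_fit(lapply(trials, function(M) M[, c(i, j), drop = FALSE]), order)
    if (fit$radius >= 1) stop("unstable VAR fit (spectral radius ",
                              round(fit$radius, 3), ")")
    g <- geweke_pair_gc(fit, freqs, fs)
    vals[i, j, ] <- g[1, ]  # i -> j
    vals[j, i, ] <- g[2, ]  # j -> i
  }
  structure(list(values = vals, freqs = freqs, order = order,
                 labels = labels, fs = fs),
            class = "gc_matrix")
}

#' Band-averaged GC per directed pair
#'
#' @param gc A `gc_matrix`.
#' @param band Band name from [eeg_bands()] or a `c(low, high)` pair.
#' @return Source x sink matrix of band-averaged GC (diagonal NA).
#' @export
gc_band_average <- function(gc, band) {
  if (is.character(band)) band <- eeg_bands()[[band]]
  sel <- gc$freqs >= band[1] & gc$freqs <= band[2]
  if (!any(sel)) stop("band outside the evaluated frequencies")
  apply(gc$values[, , sel, drop = FALSE], c(1, 2), mean)
}

#' Directed network from band-averaged GC with surrogate thresholding
#'
#' Averages GC over the requested band per directed pair and keeps
#' edges whose strength exceeds the 95th percentile of a trial-shuffle
#' surrogate null: for each surrogate, the source channel's trials are
#' permuted relative to the rest, destroying cross-channel temporal
#' alignment while preserving each channel's autostructure.
#'
#' @param gc A `gc_matrix` computed from `trials`.
#' @param band Band name or `c(low, high)` Hz.
#' @param trials List of trial matrices (samples x channels) that
#'   produced `gc`; required for the surrogate null.
#' @param n_surrogates Number of surrogates (default 100).
#' @param quantile_ Null quantile retained as threshold (default 0.95).
#' @param seed Integer seed.
#' @return A `directed_network`: list with `edges` (data.frame source,
#'   sink, band, strength, threshold), `threshold` matrix, `band`.
#' @export
directed_network <- function(gc, band, trials, n_surrogates = 100L,
                             quantile_ = 0.95, seed = 1L) {
  if (n_surrogates < 1L) stop("surrogates are required for thresholding")
  if (length(trials) < 2L) stop("trial-shuffle surrogates need >= 2 trials")
  strength <- gc_band_average(gc, band)
  k <- length(gc$labels)
  null_vals <- array(NA_real_, c(k, k, n_surrogates))
  with_seed(seed, {
    for (s in seq_len(n_surrogates)) {
      perm <- sample(length(trials))
      # re-pair source trials with unshifted sink trials
      for (src in seq_len(k)) {
        sh_trials <- lapply(seq_along(trials), function(ti) {
          M <- trials[[ti]]
          M[, src] <- trials[[perm[ti]]][, src]
          M
        })
        g_s <- tryCatch(
          spectral_granger(sh_trials, order = gc$order, freqs = gc$freqs,
                           fs = gc$fs, labels = gc$labels),
          error = function(e) NULL)
        if (!is.null(g_s)) {
          null_vals[src, , s] <- gc_band_average(g_s, band)[src, ]
        }
      }
    }
  })
  threshold <- apply(null_vals, c(1, 2), stats::quantile, probs = quantile_,
                     na.rm = TRUE)
  band_name <- if (is.character(band)) band else paste(band, collapse = "-")
  keep <- which(!is.na(strength) & strength > threshold, arr.ind = TRUE)
  edges <- data.frame(
    source = gc$labels[keep[, 1]], sink = gc$labels[keep[, 2]],
    band = rep(band_name, nrow(keep)),
    strength = strength[keep], threshold = threshold[keep],
    stringsAsFactors = FALSE
  )
  edges <- edges[order(-edges$strength), , drop = FALSE]
  rownames(edges) <- NULL
  structure(list(edges = edges, strength = strength, threshold = threshold,
                 band = band_name),
            class = "directed_network")
}

#' Band-limited magnitude-squared coherence table
#'
#' Welch cross-spectral coherence `|S_xy|^2 / (S_xx S_yy)` averaged
#' within each canonical band, for every unordered electrode pair.
#' Values lie in [0, 1]; for independent noise they approach the
#' segment-count bias floor of about 1/K for K averaged segments.
#'
#' @param data Channels x samples matrix with row labels, or an
#'   [eeg_recording()].
#' @param electrodes Electrodes to include (>= 2).
#' @param bands Named list of band edges (default [eeg_bands()]).
#' @param fs Sampling rate (taken from the recording when given).
#' @param seg_len Welch segment length, samples.
#' @return Data frame: electrode_a, electrode_b, band, coherence;
#'   attribute `n_segments`.
#' @export
coherence_summary <- function(data, electrodes = NULL, bands = eeg_bands(),
                              fs = NULL, seg_len = NULL) {
  if (inherits(data, "eeg_recording")) {
    fs <- data$fs
    M <- data$data
  } else {
    M <- as.matrix(data)
    if (is.null(fs)) stop("fs is required for plain matrices")
  }
  if (is.null(electrodes)) electrodes <- rownames(M)
  if (length(electrodes) < 2L) stop("need at least 2 electrodes")
  idx <- match(electrodes, rownames(M))
  if (anyNA(idx)) stop("electrode(s) missing from data")
  X <- t(M[idx, , drop = FALSE])
  cs <- welch_cross(X, fs, seg_len)
  rows <- list()
  for (a in seq_along(electrodes)[-length(electrodes)]) {
    for (b in (a + 1):length(electrodes)) {
      coh <- Mod(cs$spec[, a, b])^2 /
        (Re(cs$spec[, a, a]) * Re(cs$spec[, b, b]))
      for (bn in names(bands)) {
        sel <- cs$freq >= bands[[bn]][1] & cs$freq <= bands[[bn]][2]
        rows[[length(rows) + 1L]] <- data.frame(
          electrode_a = electrodes[a], electrode_b = electrodes[b],
          band = bn, coherence = mean(coh[sel]), stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "n_segments") <- cs$n_segments
  out
}
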