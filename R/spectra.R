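#' Welch power spectral density
#'
#' Averaged-periodogram spectral estimate with a Hann window and 50%
#' segment overlap. Used by the synthetic-data checks, by band-power
#' summaries, and as the cross-spectral engine behind
#' [coherence_summary()].
#'
#' @param x Numeric vector.
#' @param fs Sampling rate in Hz.
#' @param seg_len Segment length in samples (default: `fs` rounded, i.e.
#'   1-second segments, capped at the series length).
#' @return A list with `freq` (Hz) and `psd` (power per Hz, one-sided).
#' @export
welch_psd <- function(x, fs, seg_len = NULL) {
  cs <- welch_cross(cbind(x), fs, seg_len)
  list(freq = cs$freq, psd = Re(cs$spec[, 1, 1]))
}

# Welch auto/cross spectra for a channels-in-columns matrix.
# Returns freq vector and spec: freq x ch x ch complex array.
welch_cross <- function(X, fs, seg_len = NULL) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (is.null(seg_len)) seg_len <- min(n, max(32L, round(fs)))
  seg_len <- as.integer(seg_len)
  if (seg_len > n) stop("segment length ", seg_len, " exceeds data length ", n)
  hop <- max(1L, seg_len %/% 2L)
  starts <- seq(1L, n - seg_len + 1L, by = hop)
  win <- 0.5 - 0.5 * cos(2 * pi * seq_len(seg_len) / (seg_len + 1))
  wnorm <- sum(win^2)
  nf <- seg_len %/% 2L + 1L
  k <- ncol(X)
  spec <- array(0 + 0i, c(nf, k, k))
  for (s in starts) {
    seg <- X[s:(s + seg_len - 1L), , drop = FALSE]
    seg <- sweep(seg, 2L, colMeans(seg))
    F <- stats::mvfft(seg * win)[seq_len(nf), , drop = FALSE]
    for (i in seq_len(k)) for (j in seq_len(k)) {
      spec[, i, j] <- spec[, i, j] + F[, i] * Conj(F[, j])
    }
  }
  spec <- spec / (length(starts) * wnorm * fs)
  # one-sided scaling (DC and Nyquist unscaled)
  inner <- 2:(nf - if (seg_len %% 2L == 0L) 1L else 0L)
  spec[inner, , ] <- 2 * spec[inner, , ]
  list(freq = (seq_len(nf) - 1L) * fs / seg_len, spec = spec,
       n_segments = length(starts))
}

# Band-averaged power from a Welch PSD.
band_power_welch <- function(x, fs, band, seg_len = NULL) {
  p <- welch_psd(x, fs, seg_len)
  sel <- p$freq >= band[1] & p$freq <= band[2]
  mean(p$psd[sel])
}

#' Canonical EEG frequency bands
#'
#' The five bands used throughout: delta (0.5-4), theta (4-8),
#' alpha (8-12), beta (12-30), gamma (30-48) Hz.
#'
#' @return Named list of `c(low, high)` edges in Hz.
#' @export
eeg_bands <- function() {
  list(delta = c(0.5, 4), theta = c(4, 8), alpha = c(8, 12),
       beta = c(12, 30), gamma = c(30, 48))
}
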