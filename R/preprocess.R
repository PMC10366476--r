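#' Zero-phase Butterworth bandpass
#'
#' Order-`order` Butterworth design applied forward-backward
#' (`signal::filtfilt`), so the passband is phase-neutral and the
#' stopband attenuation is doubled relative to a single pass.
#'
#' @param rec An [eeg_recording()].
#' @param low,high Band edges in Hz (defaults 0.5 and 48).
#' @param order Filter order (default 4).
#' @return The filtered recording.
#' @export
bandpass <- function(rec, low = 0.5, high = 48, order = 4) {
  if (order < 1) stop("order must be >= 1")
  if (rec$fs <= 2 * high) stop("sampling rate too low for a ", high, " Hz edge")
  ny <- rec$fs / 2
  bf <- signal::butter(order, c(low, high) / ny, type = "pass")
  out <- rec
  out$data <- t(apply(rec$data, 1L, function(x) signal::filtfilt(bf, x)))
  out
}

#' Common average re-reference
#'
#' Subtracts the instantaneous mean across all channels from every
#' channel, so each column (sample) of the result has zero mean.
#'
#' @param rec An [eeg_recording()] with at least two channels.
#' @return The re-referenced recording.
#' @export
rereference_average <- function(rec) {
  if (nrow(rec$data) < 2L) stop("average reference needs >= 2 channels")
  out <- rec
  out$data <- sweep(rec$data, 2L, colMeans(rec$data))
  out
}

# Logistic Infomax ICA on whitened data. X: channels x samples (centered).
# Returns unmixing matrix W (sources = W %*% X) and mixing A (X = A %*% S).
infomax_ica <- function(X, n_comp = nrow(X), max_iter = 200L, lr = 0.01,
                        tol = 1e-6) {
  n <- ncol(X)
  X <- X - rowMeans(X)
  cv <- tcrossprod(X) / n
  eg <- eigen(cv, symmetric = TRUE)
  keep <- seq_len(n_comp)
  if (eg$values[n_comp] < 1e-12 * eg$values[1]) {
    stop("rank-deficient data: whitening failed")
  }
  K <- diag(1 / sqrt(eg$values[keep])) %*% t(eg$vectors[, keep, drop = FALSE])
  Z <- K %*% X  # whitened, n_comp x n
  W <- diag(n_comp)
  block <- min(n, 512L)
  for (it in seq_len(max_iter)) {
    W_old <- W
    starts <- seq(1L, n - block + 1L, by = block)
    for (s in starts) {
      zb <- Z[, s:(s + block - 1L), drop = FALSE]
      u <- W %*% zb
      y <- 1 / (1 + exp(-u))
      W <- W + lr * (diag(n_comp) + ((1 - 2 * y) %*% t(u)) / block) %*% W
    }
    if (max(abs(W - W_old)) < tol) break
  }
  unmix <- W %*% K                 # sources = unmix %*% X
  mix <- MASS_ginv(unmix)          # X ~ mix %*% sources
  list(unmix = unmix, mix = mix, sources = unmix %*% X)
}

# Moore-Penrose pseudoinverse (SVD).
MASS_ginv <- function(M, tol = sqrt(.Machine$double.eps)) {
  s <- svd(M)
  pos <- s$d > tol * s$d[1]
  s$v[, pos, drop = FALSE] %*% (t(s$u[, pos, drop = FALSE]) / s$d[pos])
}

#' ICA-based ocular artifact removal
#'
#' Decomposes the recording with Infomax ICA (after PCA reduction),
#' identifies components whose activation correlates with a composite of
#' the frontal reference channels above `corr_threshold` in absolute
#' value, zeroes them, and reconstructs. The blink topography projects
#' almost exclusively onto such components, so correlation with the
#' frontal-pole channels is an effective automated stand-in for visual
#' component inspection.
#'
#' @param rec An [eeg_recording()].
#' @param frontal_refs Channels whose mean forms the ocular reference.
#' @param corr_threshold Absolute correlation above which a component is
#'   removed (must be > 0; default 0.7).
#' @param n_comp Number of PCA components retained for the decomposition.
#' @return Cleaned recording, with attributes `n_removed` (count of
#'   zeroed components) and `ica_failed` (TRUE when the decomposition
#'   could not be run and the input was returned unchanged).
#' @export
remove_artifacts_ica <- function(rec, frontal_refs = c("Fp1", "Fp2"),
                                 corr_threshold = 0.7,
                                 n_comp = min(20L, nrow(rec$data))) {
  if (corr_threshold <= 0) stop("corr_threshold must be > 0")
  fidx <- match(frontal_refs, rec$labels)
  if (anyNA(fidx)) stop("frontal reference channel(s) missing from recording")
  ref <- colMeans(rec$data[fidx, , drop = FALSE])
  ctr <- rowMeans(rec$data)
  X <- rec$data - ctr
  dec <- tryCatch(infomax_ica(X, n_comp = n_comp), error = function(e) e)
  if (inherits(dec, "error")) {
    warning("ICA failed (", conditionMessage(dec), "); returning input unchanged")
    out <- rec
    attr(out, "n_removed") <- 0L
    attr(out, "ica_failed") <- TRUE
    return(out)
  }
  cors <- apply(dec$sources, 1L, function(s) {
    if (stats::sd(s) == 0) 0 else abs(stats::cor(s, ref))
  })
  bad <- which(cors >= corr_threshold)
  S <- dec$sources
  S[bad, ] <- 0
  out <- rec
  out$data <- dec$mix %*% S + ctr
  dimnames(out$data) <- dimnames(rec$data)
  attr(out, "n_removed") <- length(bad)
  attr(out, "ica_failed") <- FALSE
  out
}

#' Epoch a recording with pre-onset baseline correction
#'
#' Cuts one epoch per onset, spanning `baseline_s` seconds before the
#' onset to `duration_s` seconds after, and subtracts each channel's
#' mean over the pre-onset baseline window.
#'
#' @param rec An [eeg_recording()].
#' @param onsets Onset sample indices.
#' @param baseline_s Baseline window length in seconds (default 0.5).
#' @param duration_s Post-onset epoch length in seconds; defaults to the
#'   longest length available after the last onset.
#' @return List of baseline-corrected `eeg_recording` epochs, each with
#'   an event marking the onset position within the epoch.
#' @export
epoch_and_baseline <- function(rec, onsets, baseline_s = 0.5,
                               duration_s = NULL) {
  n_pre <- round(baseline_s * rec$fs)
  if (any(onsets <= n_pre)) {
    stop("onset(s) closer than the ", baseline_s * 1000,
         " ms baseline window to the recording start")
  }
  if (is.null(duration_s)) {
    duration_s <- (ncol(rec$data) - max(onsets)) / rec$fs
  }
  n_post <- floor(duration_s * rec$fs)
  if (any(onsets + n_post - 1L > ncol(rec$data))) {
    stop("epoch extends past the end of the recording")
  }
  lapply(onsets, function(o) {
    idx <- (o - n_pre):(o + n_post - 1L)
    seg <- rec$data[, idx, drop = FALSE]
    base <- rowMeans(rec$data[, (o - n_pre):(o - 1L), drop = FALSE])
    eeg_recording(seg - base, rec$fs, rec$labels,
                  events = data.frame(onset = n_pre + 1L, code = "onset"))
  })
}

# Morlet wavelet center frequencies tiling 0.5-48 Hz (log-spaced).
morlet_freqs <- function(voices_per_octave = 8) {
  2^seq(log2(0.5), log2(48), by = 1 / voices_per_octave)
}

# FFT-domain Morlet transform of one series: returns n_freq x n complex
# matrix of analytic wavelet coefficients (peak-normalized Gaussians).
morlet_cwt <- function(x, fs, freqs, n_cycles = 6) {
  n <- length(x)
  X <- stats::fft(x)
  nu <- (seq_len(n) - 1L) * fs / n            # 0 .. fs
  W <- matrix(0 + 0i, length(freqs), n)
  for (i in seq_along(freqs)) {
    f <- freqs[i]
    resp <- exp(-(nu - f)^2 * n_cycles^2 / (2 * f^2))
    resp[nu > fs / 2] <- 0                     # analytic: kill negative freqs
    W[i, ] <- stats::fft(X * resp, inverse = TRUE) / n
  }
  W
}

#' Time-frequency band power via the Morlet wavelet transform
#'
#' Continuous Morlet transform (6 cycles, log-spaced center frequencies
#' tiling 0.5-48 Hz), squared magnitude averaged within each of the five
#' canonical bands per analysis frame. Per-frequency weights flatten the
#' Littlewood-Paley sum of the wavelet bank, so summing the five band
#' powers approximates the total 0.5-48 Hz power.
#'
#' @param rec An [eeg_recording()] (cleaned).
#' @param frame_hop Frame hop in seconds (default 0.1).
#' @param n_cycles Morlet cycles (default 6).
#' @return A `band_power` object: list with `power` (channels x bands x
#'   frames, non-negative), `bands`, `frame_hop`, `frame_times`.
#' @export
wavelet_band_power <- function(rec, frame_hop = 0.1, n_cycles = 6) {
  freqs <- morlet_freqs()
  # need at least two periods of the slowest wavelet's center frequency
  support <- 2 / min(freqs)
  if (ncol(rec$data) / rec$fs < support) {
    stop("recording shorter than the largest wavelet support (",
         round(support, 1), " s)")
  }
  bands <- eeg_bands()
  hop <- max(1L, round(frame_hop * rec$fs))
  frames <- seq(1L, ncol(rec$data), by = hop)
  # flatten the bank: the squared-response Littlewood-Paley sum of the
  # log-spaced peak-normalized Gaussians is ~ sqrt(pi)/(n_cycles*dlnf),
  # and analytic coefficients carry half the two-sided power
  dlnf <- log(freqs[2]) - log(freqs[1])
  w_f <- rep(2 * n_cycles * dlnf / sqrt(pi), length(freqs))
  n_ch <- nrow(rec$data)
  pow <- array(0, c(n_ch, length(bands), length(frames)),
               dimnames = list(rec$labels, names(bands), NULL))
  band_of <- vapply(freqs, function(f) {
    hit <- which(vapply(bands, function(b) f >= b[1] & f <= b[2], logical(1)))
    if (length(hit)) hit[1] else NA_integer_
  }, integer(1))
  for (ch in seq_len(n_ch)) {
    W <- morlet_cwt(rec$data[ch, ], rec$fs, freqs, n_cycles)
    P <- Mod(W)^2 * w_f               # weighted power, freq x time
    for (b in seq_along(bands)) {
      sel <- which(band_of == b)
      if (length(sel)) {
        pow[ch, b, ] <- colSums(P[sel, frames, drop = FALSE])
      }
    }
  }
  structure(list(power = pow, bands = bands, frame_hop = hop / rec$fs,
                 frame_times = (frames - 1L) / rec$fs, fs = rec$fs),
            class = "band_power")
}

#' Event-related spectral perturbation
#'
#' Baseline-normalized time-frequency power, `10*log10(P/P_baseline)`
#' in dB per frequency per frame, averaged over epochs (and channels).
#'
#' @param epochs List of baseline-aligned epochs from
#'   [epoch_and_baseline()] (all sharing fs and the onset position).
#' @param baseline_power Optional per-frequency baseline power vector;
#'   when NULL it is estimated from the pre-onset window of the epochs.
#' @param freqs Center frequencies (defaults to the Morlet bank).
#' @param n_cycles Morlet cycles.
#' @return List with `db` (freq x frame matrix), `freqs`, `times`.
#' @export
ersp <- function(epochs, baseline_power = NULL, freqs = morlet_freqs(),
                 n_cycles = 6) {
  if (length(epochs) < 1L) stop("need at least one epoch")
  fs <- epochs[[1]]$fs
  onset <- epochs[[1]]$events$onset[1]
  n <- ncol(epochs[[1]]$data)
  acc <- matrix(0, length(freqs), n)
  for (ep in epochs) {
    for (ch in seq_len(nrow(ep$data))) {
      acc <- acc + Mod(morlet_cwt(ep$data[ch, ], fs, freqs, n_cycles))^2
    }
  }
  acc <- acc / (length(epochs) * nrow(epochs[[1]]$data))
  if (is.null(baseline_power)) {
    if (onset < 2L) stop("no pre-onset baseline available in the epochs")
    baseline_power <- rowMeans(acc[, seq_len(onset - 1L), drop = FALSE])
  }
  if (any(baseline_power <= 0)) stop("zero baseline power at some frequency")
  list(db = 10 * log10(acc / baseline_power), freqs = freqs,
       times = (seq_len(n) - onset) / fs)
}
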