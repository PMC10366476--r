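#' Threshold (temporal-contrast) spike encoding
#'
#' Converts each channel into an ON and an OFF spike train by the
#' cumulative temporal-contrast rule: a running accumulator integrates
#' the signed sample-to-sample change; when it reaches `+theta` an ON
#' spike is emitted and `theta` is subtracted, when it reaches `-theta`
#' an OFF spike is emitted and `theta` is added. The per-channel
#' threshold is `theta = k * sd(diff(signal))`. The code is insensitive
#' to DC offsets and approximately decodable: accumulating
#' `+theta`/`-theta` per ON/OFF spike tracks the signal within `theta`
#' per inter-spike interval.
#'
#' @param signal Numeric matrix, channels x samples (or a vector for a
#'   single channel), or an [eeg_recording()].
#' @param k Threshold factor (> 0, default 0.5).
#' @param dt Time step in seconds; defaults to the recording's sampling
#'   interval (required for plain matrices).
#' @param theta Optional per-channel threshold vector overriding the
#'   `k * sd(diff)` rule, e.g. a pooled estimate over a whole dataset so
#'   that amplitude differences between trials stay expressed in the
#'   spike rate.
#' @return A `spike_tensor`: list with `spikes` (2*channels x (samples-1)
#'   binary matrix; rows ordered ON_1, OFF_1, ON_2, OFF_2, ...),
#'   `dt`, `theta` (per channel), and `neuron_map` (data.frame neuron ->
#'   channel, polarity).
#' @export
encode_threshold <- function(signal, k = 0.5, dt = NULL, theta = NULL) {
  if (inherits(signal, "eeg_recording")) {
    if (is.null(dt)) dt <- 1 / signal$fs
    labels <- signal$labels
    signal <- signal$data
  } else {
    if (is.null(dt)) stop("dt must be given for plain matrices")
    if (is.null(dim(signal))) signal <- matrix(signal, nrow = 1)
    labels <- rownames(signal)
    if (is.null(labels)) labels <- paste0("ch", seq_len(nrow(signal)))
  }
  if (k <= 0) stop("k must be > 0")
  if (!all(is.finite(signal))) stop("signal must be finite")
  n_ch <- nrow(signal)
  n <- ncol(signal)
  if (n < 2L) stop("need at least two samples to encode changes")
  spikes <- matrix(0L, 2L * n_ch, n - 1L)
  if (!is.null(theta) && length(theta) != n_ch) {
    stop("theta must have one entry per channel")
  }
  thetas <- numeric(n_ch)
  for (ch in seq_len(n_ch)) {
    d <- diff(signal[ch, ])
    th <- if (is.null(theta)) k * stats::sd(d) else theta[ch]
    thetas[ch] <- th
    if (!is.finite(th) || th == 0) {
      warning("constant channel ", labels[ch], " encodes to all-zero trains")
      next
    }
    acc <- 0
    on <- integer(n - 1L); off <- integer(n - 1L)
    for (t in seq_len(n - 1L)) {
      acc <- acc + d[t]
      if (acc >= th) { on[t] <- 1L; acc <- acc - th }
      else if (acc <= -th) { off[t] <- 1L; acc <- acc + th }
    }
    spikes[2L * ch - 1L, ] <- on
    spikes[2L * ch, ] <- off
  }
  neuron_map <- data.frame(
    neuron = seq_len(2L * n_ch),
    channel = rep(labels, each = 2L),
    polarity = rep(c("on", "off"), n_ch),
    stringsAsFactors = FALSE
  )
  structure(list(spikes = spikes, dt = dt, theta = thetas,
                 neuron_map = neuron_map),
            class = "spike_tensor")
}

#' @export
print.spike_tensor <- function(x, ...) {
  cat(sprintf("<spike_tensor> %d neurons x %d steps, dt = %g s, %.1f%% active\n",
              nrow(x$spikes), ncol(x$spikes), x$dt, 100 * mean(x$spikes)))
  invisible(x)
}

#' 471-node spatial grid with electrode assignment
#'
#' Builds the fixed 471-node spatial scaffold: a 1 cm lattice clipped to
#' an ellipsoidal head volume by taking the 471 lattice points of
#' smallest ellipsoidal norm (ties broken by lattice order), then
#' assigns every electrode its nearest node under Euclidean distance,
#' ties broken by lowest node index.
#'
#' @param montage A montage from [standard_montage_62()].
#' @return A `node_grid`: list with `nodes` (471 x 3 matrix, mm) and
#'   `electrode_assignment` (named integer vector, electrode -> node).
#' @export
build_node_grid <- function(montage) {
  semi <- c(80, 90, 70)  # lattice ellipsoid semi-axes, mm
  step <- 10             # 1 cm resolution
  ax <- lapply(semi, function(s) seq(-s, s, by = step))
  g <- as.matrix(expand.grid(x = ax[[1]], y = ax[[2]], z = ax[[3]]))
  q <- (g[, 1] / semi[1])^2 + (g[, 2] / semi[2])^2 + (g[, 3] / semi[3])^2
  ord <- order(q, seq_along(q))
  nodes <- g[ord[1:471], , drop = FALSE]
  rownames(nodes) <- NULL

  coords <- montage_coords(montage, montage$label)
  lim <- apply(abs(g), 2, max)
  out_of_box <- abs(coords[, 1]) > lim[1] | abs(coords[, 2]) > lim[2] |
    abs(coords[, 3]) > lim[3]
  if (any(out_of_box)) {
    stop("electrode(s) outside the grid bounding volume: ",
         paste(montage$label[out_of_box], collapse = ", "))
  }
  assign <- vapply(seq_len(nrow(coords)), function(i) {
    d2 <- colSums((t(nodes) - coords[i, ])^2)
    which.min(d2)  # which.min takes the lowest index on ties
  }, integer(1))
  names(assign) <- montage$label
  structure(list(nodes = nodes, electrode_assignment = assign),
            class = "node_grid")
}

#' Map electrode spike streams onto the 100-neuron input layer
#'
#' The decoder's input layer has a fixed size of 100 neurons regardless
#' of how many electrodes feed it. Each electrode contributes an ON and
#' an OFF stream; the `2 * n_electrodes` streams are dealt round-robin
#' over the 100 input slots, so for up to 50 electrodes every stream
#' appears at least once and the remaining slots replicate streams in
#' round-robin order, while for larger subsets the slots subsample the
#' streams evenly.
#'
#' @param electrodes Character vector of electrode labels (the mined
#'   subset, in order).
#' @param n_input Input layer size (default 100).
#' @return Data frame with columns `neuron`, `channel`, `polarity`,
#'   `stream` (index into the ON/OFF stream list).
#' @export
input_layer_map <- function(electrodes, n_input = 100L) {
  if (length(electrodes) == 0L) stop("empty electrode set")
  streams <- data.frame(
    channel = rep(electrodes, each = 2L),
    polarity = rep(c("on", "off"), length(electrodes)),
    stringsAsFactors = FALSE
  )
  stream_idx <- ((seq_len(n_input) - 1L) %% nrow(streams)) + 1L
  data.frame(neuron = seq_len(n_input),
             channel = streams$channel[stream_idx],
             polarity = streams$polarity[stream_idx],
             stream = stream_idx,
             stringsAsFactors = FALSE)
}

# Expand a per-electrode spike tensor into the fixed-size input layer.
# st: spike_tensor over exactly the mapped electrodes.
input_spikes <- function(st, map) {
  key <- paste(st$neuron_map$channel, st$neuron_map$polarity)
  want <- paste(map$channel, map$polarity)
  idx <- match(want, key)
  if (anyNA(idx)) stop("spike tensor does not cover the mapped electrode streams")
  st$spikes[idx, , drop = FALSE]
}
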