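#' EEG recording container
#'
#' A minimal container for one multichannel recording: a channels x
#' samples matrix in microvolts, its sampling rate, channel labels, and
#' optional event markers.
#'
#' @param data Numeric matrix, channels x samples.
#' @param fs Sampling rate, Hz.
#' @param labels Character vector of channel names, one per row.
#' @param events Data frame with columns `onset` (sample index) and
#'   `code` (character), or NULL.
#' @return An `eeg_recording` object.
#' @export
eeg_recording <- function(data, fs, labels, events = NULL) {
  data <- as.matrix(data)
  if (length(labels) != nrow(data)) {
    stop("channel count (", nrow(data), ") does not match label count (",
         length(labels), ")")
  }
  if (!is.numeric(fs) || fs <= 0) stop("fs must be a positive number")
  if (is.null(events)) {
    events <- data.frame(onset = integer(0), code = character(0))
  }
  structure(
    list(data = data, fs = fs, labels = as.character(labels), events = events),
    class = "eeg_recording"
  )
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d channels x %d samples @ %g Hz (%.1f s)\n",
              nrow(x$data), ncol(x$data), x$fs, ncol(x$data) / x$fs))
  invisible(x)
}

#' Extract a channel subset of a recording
#'
#' @param rec An `eeg_recording`.
#' @param labels Channels to keep, in the given order.
#' @return An `eeg_recording` restricted to `labels`.
#' @export
select_channels <- function(rec, labels) {
  idx <- match(labels, rec$labels)
  if (anyNA(idx)) {
    stop("channel(s) not in recording: ", paste(labels[is.na(idx)], collapse = ", "))
  }
  eeg_recording(rec$data[idx, , drop = FALSE], rec$fs, labels, rec$events)
}

#' Evaluate code under a fixed RNG seed
#'
#' Runs `code` with the RNG seeded to `seed` and restores the caller's
#' random stream afterwards; the package's own determinism guarantees
#' are built on it.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @export
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}
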