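#' Serialize a spike tensor as a sparse coordinate list
#'
#' Writes a JSON file with the tensor's metadata (dt, per-channel
#' thresholds, neuron map, dimensions) and the spikes as (neuron, step)
#' coordinate pairs.
#'
#' @param st A `spike_tensor` from [encode_threshold()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_spike_tensor <- function(st, path) {
  coords <- which(st$spikes == 1L, arr.ind = TRUE)
  obj <- list(
    dt = st$dt,
    theta = as.numeric(st$theta),
    n_neurons = nrow(st$spikes),
    n_steps = ncol(st$spikes),
    neuron_map = st$neuron_map,
    neuron = as.integer(coords[, 1]),
    step = as.integer(coords[, 2])
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_spike_tensor
#' @export
read_spike_tensor <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  spikes <- matrix(0L, obj$n_neurons, obj$n_steps)
  if (length(obj$neuron)) spikes[cbind(obj$neuron, obj$step)] <- 1L
  structure(list(spikes = spikes, dt = obj$dt, theta = obj$theta,
                 neuron_map = as.data.frame(obj$neuron_map)),
            class = "spike_tensor")
}

#' Serialize band power with a JSON header
#'
#' Writes the channels x bands x frames array as a flat TSV (one row
#' per channel-band pair) plus a JSON header describing the axes.
#'
#' @param bp A `band_power` from [wavelet_band_power()].
#' @param prefix Path prefix; writes `<prefix>.tsv` and `<prefix>.json`.
#' @return The prefix, invisibly.
#' @export
write_band_power <- function(bp, prefix) {
  d <- dim(bp$power)
  header <- list(channels = dimnames(bp$power)[[1]],
                 bands = bp$bands, frame_hop = bp$frame_hop,
                 frame_times = bp$frame_times, fs = bp$fs,
                 n_frames = d[3])
  jsonlite::write_json(header, paste0(prefix, ".json"), auto_unbox = TRUE,
                       digits = NA)
  flat <- do.call(rbind, lapply(seq_len(d[1]), function(ch) {
    do.call(rbind, lapply(seq_len(d[2]), function(b) {
      data.frame(channel = dimnames(bp$power)[[1]][ch],
                 band = names(bp$bands)[b],
                 t(bp$power[ch, b, ]))
    }))
  }))
  utils::write.table(flat, paste0(prefix, ".tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(prefix)
}

#' @rdname write_band_power
#' @export
read_band_power <- function(prefix) {
  header <- jsonlite::read_json(paste0(prefix, ".json"),
                                simplifyVector = TRUE)
  flat <- utils::read.table(paste0(prefix, ".tsv"), sep = "\t", header = TRUE,
                            stringsAsFactors = FALSE)
  chs <- header$channels
  bands <- lapply(header$bands, as.numeric)
  pow <- array(0, c(length(chs), length(bands), header$n_frames),
               dimnames = list(chs, names(bands), NULL))
  for (i in seq_len(nrow(flat))) {
    pow[flat$channel[i], flat$band[i], ] <-
      as.numeric(flat[i, -(1:2)])
  }
  structure(list(power = pow, bands = bands, frame_hop = header$frame_hop,
                 frame_times = header$frame_times, fs = header$fs),
            class = "band_power")
}

#' Save and restore a decoder checkpoint
#'
#' Writes a JSON manifest (layout, classes, electrodes, parameters,
#' thresholds, calibration) plus plain-text weight matrices and the
#' training history CSV into a directory.
#'
#' @param decoder A decoder (trained or not).
#' @param dir Checkpoint directory (created if needed).
#' @return `dir` invisibly; `read_decoder` returns the decoder.
#' @export
write_decoder <- function(decoder, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(
    electrodes = decoder$electrodes, classes = decoder$classes,
    hidden_sign = decoder$hidden_sign, vth_hidden = decoder$vth_hidden,
    lif = unclass(decoder$lif), lif_out = unclass(decoder$lif_out),
    stp = unclass(decoder$stp), stdp = unclass(decoder$stdp),
    sbp = decoder$sbp, trained = decoder$trained,
    teaching_rate = decoder$teaching_rate,
    count_threshold = decoder$count_threshold,
    positive_high = decoder$positive_high,
    hidden_nodes = decoder$hidden_nodes
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  utils::write.table(decoder$W_ih, file.path(dir, "w_in_hidden.tsv"),
                     sep = "\t", row.names = FALSE, col.names = FALSE)
  utils::write.table(decoder$W_ho, file.path(dir, "w_hidden_out.tsv"),
                     sep = "\t", row.names = FALSE, col.names = FALSE)
  if (!is.null(decoder$history)) {
    utils::write.csv(decoder$history, file.path(dir, "history.csv"),
                     row.names = FALSE)
  }
  invisible(dir)
}

#' @rdname write_decoder
#' @export
read_decoder <- function(dir) {
  m <- jsonlite::read_json(file.path(dir, "manifest.json"),
                           simplifyVector = TRUE)
  dec <- decoder_new(m$electrodes, m$classes,
                     lif = do.call(lif_params, m$lif),
                     lif_out = do.call(lif_params, m$lif_out),
                     stp = do.call(stp_params, m$stp),
                     stdp = do.call(stdp_params, m$stdp),
                     sbp = m$sbp)
  dec$W_ih <- as.matrix(utils::read.table(file.path(dir, "w_in_hidden.tsv"),
                                          sep = "\t"))
  dec$W_ho <- as.matrix(utils::read.table(file.path(dir, "w_hidden_out.tsv"),
                                          sep = "\t"))
  dimnames(dec$W_ih) <- NULL
  dimnames(dec$W_ho) <- NULL
  dec$hidden_sign <- m$hidden_sign
  dec$vth_hidden <- m$vth_hidden
  dec$trained <- isTRUE(m$trained)
  dec$teaching_rate <- m$teaching_rate
  dec$count_threshold <- m$count_threshold
  dec$positive_high <- m$positive_high
  hist_path <- file.path(dir, "history.csv")
  if (file.exists(hist_path)) dec$history <- utils::read.csv(hist_path)
  dec
}
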