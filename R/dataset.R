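#' Spike-encode a labeled EEG set for a given electrode subset
#'
#' Selects the electrodes, keeps the post-onset portion of each trial,
#' threshold-encodes it ([encode_threshold()]) and expands the ON/OFF
#' streams onto the fixed 100-neuron input layer ([input_layer_map()]).
#'
#' @param set A `labeled_eeg_set`.
#' @param electrodes Electrode subset.
#' @param k Encoding threshold factor (default 1: at the pooled-theta
#'   dataset level a unit threshold keeps spike rates in the decoder's
#'   sensitive range).
#' @param n_input Input layer size.
#' @return A spike dataset: list with `spikes` (list of n_input x T
#'   binary matrices), `labels`, `dt`, `electrodes`.
#' @export
encode_dataset <- function(set, electrodes, k = 1, n_input = 100L) {
  map <- input_layer_map(electrodes, n_input)
  mats <- lapply(set$recordings, function(rec) {
    sub <- select_channels(rec, electrodes)
    onset <- rec$events$onset[1]
    if (is.finite(onset) && onset > 1) {
      sub$data <- sub$data[, onset:ncol(sub$data), drop = FALSE]
    }
    rownames(sub$data) <- sub$labels
    sub$data
  })
  theta <- pooled_theta(mats, k)
  dt <- 1 / set$recordings[[1]]$fs
  spikes <- lapply(mats, function(m) {
    st <- suppressWarnings(encode_threshold(m, k = k, dt = dt, theta = theta))
    input_spikes(st, map)
  })
  list(spikes = spikes, labels = set$labels, dt = dt, electrodes = electrodes)
}

# Per-channel encoding threshold pooled over all trials (k times the sd
# of the first difference of the concatenated trials); label-free, so
# trial-to-trial amplitude differences survive in the spike rates.
pooled_theta <- function(mats, k) {
  k * apply(do.call(cbind, lapply(mats, function(m) {
    m[, -1, drop = FALSE] - m[, -ncol(m), drop = FALSE]
  })), 1, stats::sd)
}

#' Spike-encode per-band power frames of a labeled EEG set
#'
#' Computes wavelet band power per trial and encodes the chosen band's
#' channel x frame series as spikes; the time step becomes the frame
#' hop. This is the time-frequency-domain input route of the decoder.
#'
#' @param set A `labeled_eeg_set`.
#' @param electrodes Electrode subset.
#' @param band Band name from [eeg_bands()].
#' @param frame_hop Frame hop in seconds.
#' @param k,n_input As in [encode_dataset()].
#' @return A spike dataset (same shape as [encode_dataset()]).
#' @export
encode_band_dataset <- function(set, electrodes, band, frame_hop = 0.1,
                                k = 1, n_input = 100L) {
  if (!band %in% names(eeg_bands())) stop("unknown band: ", band)
  map <- input_layer_map(electrodes, n_input)
  mats <- lapply(set$recordings, function(rec) {
    sub <- select_channels(rec, electrodes)
    onset <- rec$events$onset[1]
    if (is.finite(onset) && onset > 1) {
      sub$data <- sub$data[, onset:ncol(sub$data), drop = FALSE]
    }
    bp <- wavelet_band_power(sub, frame_hop = frame_hop)
    frames <- bp$power[, band, , drop = TRUE]
    if (is.null(dim(frames))) frames <- matrix(frames, nrow = 1)
    rownames(frames) <- electrodes
    frames
  })
  theta <- pooled_theta(mats, k)
  spikes <- lapply(mats, function(m) {
    st <- suppressWarnings(encode_threshold(m, k = k, dt = frame_hop,
                                            theta = theta))
    input_spikes(st, map)
  })
  list(spikes = spikes, labels = set$labels, dt = frame_hop,
       electrodes = electrodes)
}

subset_dataset <- function(dataset, idx) {
  out <- dataset
  out$spikes <- dataset$spikes[idx]
  out$labels <- dataset$labels[idx]
  out
}

#' Stratified train/test split
#'
#' @param labels Factor of class labels.
#' @param test_frac Held-out fraction per class.
#' @param seed Integer seed.
#' @return List with integer vectors `train` and `test`.
#' @export
split_stratified <- function(labels, test_frac = 0.2, seed = 1L) {
  with_seed(seed, {
    test <- unlist(lapply(split(seq_along(labels), labels), function(idx) {
      n_test <- max(1L, round(length(idx) * test_frac))
      sample(idx, n_test)
    }), use.names = FALSE)
    list(train = setdiff(seq_along(labels), test), test = sort(test))
  })
}

#' Train a decoder on a split and score it on the held-out trials
#'
#' @param dataset A spike dataset from [encode_dataset()].
#' @param cfg A [train_config()].
#' @param montage Montage for decoder construction.
#' @param split Optional list(train, test); defaults to a stratified
#'   80/20 split seeded by `cfg$seed`.
#' @param decoder_seed Seed for decoder initialization.
#' @param ... Extra arguments for [decoder_new()].
#' @return List with `accuracy` (percent), `f1`, `decoder`, `preds`,
#'   `truth`, `report`.
#' @export
fit_and_score <- function(dataset, cfg = train_config(),
                          montage = standard_montage_62(), split = NULL,
                          decoder_seed = cfg$seed, ...) {
  classes <- levels(dataset$labels)
  if (is.null(split)) split <- split_stratified(dataset$labels, 0.2, cfg$seed)
  dec <- decoder_new(dataset$electrodes, classes, montage = montage,
                     seed = decoder_seed, ...)
  dec <- snn_train(dec, subset_dataset(dataset, split$train), cfg)
  preds <- snn_predict(dec, dataset$spikes[split$test], dataset$dt)
  truth <- as.character(dataset$labels[split$test])
  rep <- evaluate(preds, truth,
                  task = if (length(classes) == 2L) "binary" else "multiclass",
                  classes = classes)
  list(accuracy = rep$accuracy, f1 = rep$f1, decoder = dec,
       preds = preds, truth = truth, report = rep)
}
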