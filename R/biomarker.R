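#' Decode a single frequency band with the spiking pipeline
#'
#' Computes wavelet band power for the chosen band, re-encodes the
#' channel x frame power series to spikes and classifies with the
#' standard decoder under stratified k-fold cross-validation, pooling
#' the held-out predictions of all folds into one evaluation.
#'
#' @param set A `labeled_eeg_set`.
#' @param electrodes Electrode subset.
#' @param band Band name from [eeg_bands()].
#' @param cfg A [train_config()].
#' @param frame_hop Band-power frame hop, seconds.
#' @param n_folds Cross-validation folds (default 5).
#' @return List with `band`, `accuracy` (percent), `f1`, and the
#'   per-fold accuracies in `fold_accuracy`.
#' @export
band_decode <- function(set, electrodes, band, cfg = train_config(),
                        frame_hop = 0.1, n_folds = 5L) {
  if (!band %in% names(eeg_bands())) stop("unknown band name: ", band)
  ds <- encode_band_dataset(set, electrodes, band, frame_hop = frame_hop)
  if (all(vapply(ds$spikes, sum, numeric(1)) == 0)) {
    warning("zero-variance band '", band, "': decoding at chance")
  }
  n_folds <- max(2L, min(n_folds, min(table(ds$labels))))
  folds <- stratified_folds(ds$labels, n_folds, cfg$seed)
  classes <- levels(ds$labels)
  preds <- character(length(ds$labels))
  fold_acc <- numeric(length(folds))
  for (fi in seq_along(folds)) {
    test <- folds[[fi]]
    fit <- fit_and_score(ds, cfg, montage = set$montage,
                         split = list(train = setdiff(seq_along(ds$labels),
                                                      test),
                                      test = test))
    preds[test] <- fit$preds
    fold_acc[fi] <- fit$accuracy
  }
  rep <- evaluate(preds, as.character(ds$labels),
                  task = if (length(classes) == 2L) "binary" else "multiclass",
                  classes = classes)
  list(band = band, accuracy = rep$accuracy, f1 = rep$f1,
       fold_accuracy = fold_acc)
}

# Stratified fold assignment: list of test-index vectors.
stratified_folds <- function(labels, n_folds, seed) {
  with_seed(seed, {
    fold_of <- integer(length(labels))
    for (idx in split(seq_along(labels), labels)) {
      fold_of[sample(idx)] <- rep_len(seq_len(n_folds), length(idx))
    }
    lapply(seq_len(n_folds), function(f) sort(which(fold_of == f)))
  })
}

# Per-band flattened band-power feature blocks: list of n_trials x d
# matrices, one per band.
band_feature_blocks <- function(set, electrodes, frame_hop = 0.1) {
  bands <- names(eeg_bands())
  feats <- lapply(set$recordings, function(rec) {
    sub <- select_channels(rec, electrodes)
    onset <- rec$events$onset[1]
    if (is.finite(onset) && onset > 1) {
      sub$data <- sub$data[, onset:ncol(sub$data), drop = FALSE]
    }
    bp <- wavelet_band_power(sub, frame_hop = frame_hop)
    lapply(seq_along(bands), function(b) as.numeric(bp$power[, b, ]))
  })
  out <- lapply(seq_along(bands), function(b) {
    do.call(rbind, lapply(feats, `[[`, b))
  })
  names(out) <- bands
  out
}

# Euclidean projection of v onto the probability simplex.
project_simplex <- function(v) {
  u <- sort(v, decreasing = TRUE)
  css <- cumsum(u)
  rho <- max(which(u + (1 - css) / seq_along(u) > 0))
  pmax(v + (1 - css[rho]) / rho, 0)
}

# EasyMKL kernel weights for a binary +-1 problem (Aiolli & Donini):
# solve the margin problem min_gamma (1-lambda) gamma' Y K Y gamma +
# lambda ||gamma||^2 over the product of the two class simplexes on the
# sum kernel, then score each kernel by eta_r = gamma' Y K_r Y gamma.
easymkl_binary <- function(kernels, y, lambda = 0.2, max_iter = 300L) {
  n <- length(y)
  Ksum <- Reduce(`+`, kernels)
  Yd <- y  # diagonal of Y
  pos <- which(y > 0); neg <- which(y < 0)
  gamma <- numeric(n)
  gamma[pos] <- 1 / length(pos)
  gamma[neg] <- 1 / length(neg)
  YKY <- Ksum * tcrossprod(Yd)
  L <- 2 * ((1 - lambda) * norm(YKY, "2") + lambda)
  step <- 1 / L
  for (it in seq_len(max_iter)) {
    g <- 2 * (1 - lambda) * (YKY %*% gamma) + 2 * lambda * gamma
    gnew <- gamma - step * as.numeric(g)
    gnew[pos] <- project_simplex(gnew[pos])
    gnew[neg] <- project_simplex(gnew[neg])
    if (max(abs(gnew - gamma)) < 1e-10) { gamma <- gnew; break }
    gamma <- gnew
  }
  eta <- vapply(kernels, function(K) {
    as.numeric(t(gamma * Yd) %*% K %*% (gamma * Yd))
  }, numeric(1))
  list(eta = pmax(eta, 0), gamma = gamma)
}

#' EasyMKL attribution of frequency-band contributions
#'
#' Builds one trace-normalized linear kernel per band from flattened
#' band-power features, learns the margin-optimal convex kernel
#' combination (EasyMKL) and reports each band's contribution as its
#' kernel coefficient as a percentage of the total. Multi-class labels
#' are handled one-vs-rest with contributions averaged across rests.
#'
#' @param set A `labeled_eeg_set`.
#' @param electrodes Electrode subset (default: whole montage).
#' @param labels Trial labels (default: the set's).
#' @param lambda EasyMKL regularization in [0, 1] (default 0.2).
#' @param frame_hop Band-power frame hop, seconds.
#' @param seed Unused randomness guard (the solver is deterministic);
#'   kept for interface stability.
#' @return An `mkl_result`: list with `contributions` (named percent,
#'   summing to 100), `kernel_weights` (raw coefficients), `lambda`.
#' @export
easymkl_contributions <- function(set, electrodes = set$montage$label,
                                  labels = set$labels, lambda = 0.2,
                                  frame_hop = 0.1, seed = 1L) {
  classes <- unique(as.character(labels))
  if (length(classes) < 2L) stop("need at least 2 classes")
  blocks <- band_feature_blocks(set, electrodes, frame_hop)
  kernels <- lapply(blocks, function(X) {
    X <- scale(X, center = TRUE, scale = FALSE)
    K <- tcrossprod(X)
    tr <- sum(diag(K))
    if (tr <= 0) stop("degenerate kernel (zero trace)")
    K / tr * nrow(K)
  })
  etas <- vapply(classes, function(cl) {
    y <- ifelse(as.character(labels) == cl, 1, -1)
    easymkl_binary(kernels, y, lambda)$eta
  }, numeric(length(kernels)))
  eta <- rowMeans(etas)
  contributions <- if (sum(eta) == 0) {
    rep(100 / length(eta), length(eta))
  } else 100 * eta / sum(eta)
  names(contributions) <- names(blocks)
  structure(list(contributions = contributions, kernel_weights = eta,
                 lambda = lambda),
            class = "mkl_result")
}

#' @export
print.mkl_result <- function(x, ...) {
  cat("<mkl_result> band contributions (%):\n")
  print(round(x$contributions, 2))
  invisible(x)
}
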