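#' Two-cluster K-means of subnetwork model performances
#'
#' Standardizes the (accuracy, F1) columns to zero mean and unit
#' variance (the two scales differ by two orders of magnitude), then
#' runs Lloyd iterations to convergence from 10 seeded random restarts
#' and keeps the partition with the lowest within-cluster sum of
#' squares. The iteration loop is explicit so the objective trajectory
#' is recorded; the final partition agrees with `stats::kmeans`.
#'
#' @param points Matrix or data.frame with two columns (accuracy, f1),
#'   one row per model.
#' @param seed Integer seed.
#' @param n_restarts Number of random restarts.
#' @return List with `cluster` (1/2 per point), `centers` (on the
#'   original scale), `objective` (final within-cluster SS on the
#'   standardized scale), `objective_trace` (per Lloyd iteration of the
#'   winning restart), and `degenerate` (TRUE when all points coincide,
#'   leaving a single effective cluster).
#' @export
kmeans_2 <- function(points, seed = 1L, n_restarts = 10L) {
  X <- as.matrix(points)
  if (nrow(X) < 2L) stop("need at least 2 points")
  mu <- colMeans(X)
  sd_ <- apply(X, 2, stats::sd)
  sd_[sd_ == 0] <- 1
  Z <- sweep(sweep(X, 2, mu), 2, sd_, "/")
  if (all(apply(Z, 2, function(c) max(c) - min(c)) < 1e-12)) {
    return(list(cluster = rep(1L, nrow(X)), centers = rbind(mu),
                objective = 0, objective_trace = 0, degenerate = TRUE))
  }
  lloyd <- function(centers) {
    trace <- numeric(0)
    cl <- integer(nrow(Z))
    repeat {
      d1 <- rowSums(sweep(Z, 2, centers[1, ])^2)
      d2 <- rowSums(sweep(Z, 2, centers[2, ])^2)
      new_cl <- ifelse(d1 <= d2, 1L, 2L)
      wss <- sum(pmin(d1, d2))
      trace <- c(trace, wss)
      for (g in 1:2) {
        if (any(new_cl == g)) {
          centers[g, ] <- colMeans(Z[new_cl == g, , drop = FALSE])
        }
      }
      if (identical(new_cl, cl)) break
      cl <- new_cl
    }
    # one more objective evaluation after the final center update
    d1 <- rowSums(sweep(Z, 2, centers[1, ])^2)
    d2 <- rowSums(sweep(Z, 2, centers[2, ])^2)
    trace <- c(trace, sum(pmin(d1, d2)))
    list(cluster = cl, centers = centers, objective = trace[length(trace)],
         trace = trace)
  }
  best <- NULL
  with_seed(seed, {
    for (r in seq_len(n_restarts)) {
      init <- Z[sample.int(nrow(Z), 2L), , drop = FALSE]
      if (max(abs(init[1, ] - init[2, ])) < 1e-12) next
      res <- lloyd(init)
      if (is.null(best) || res$objective < best$objective - 1e-12) best <- res
    }
  })
  centers <- sweep(sweep(best$centers, 2, sd_, "*"), 2, mu, "+")
  list(cluster = best$cluster, centers = centers, objective = best$objective,
       objective_trace = best$trace, degenerate = FALSE)
}

#' Train a fusion model over pooled subnetwork electrode sets
#'
#' Pools the (deduplicated) electrode sets of the member subnetworks'
#' selected models and trains the standard spiking decoder on the
#' pooled channels.
#'
#' @param set A `labeled_eeg_set`.
#' @param members List of electrode character vectors, one per member
#'   subnetwork (e.g. the best-model sets of the winning cluster).
#' @param cfg A [train_config()].
#' @param split Optional fixed train/test split (shared across the
#'   models being compared).
#' @return A `fusion_model`: list with `members`, `electrodes` (pooled,
#'   no duplicates), `accuracy`, `f1`, `decoder`, `split`.
#' @export
build_fusion <- function(set, members, cfg = train_config(), split = NULL) {
  if (length(members) == 0L) stop("members must be non-empty")
  pooled <- sort(unique(unlist(members)))
  if (length(pooled) == 0L) stop("pooled electrode set is empty")
  ds <- encode_dataset(set, pooled)
  if (is.null(split)) split <- split_stratified(ds$labels, 0.2, cfg$seed)
  fit <- fit_and_score(ds, cfg, montage = set$montage, split = split)
  structure(list(members = members, electrodes = pooled,
                 accuracy = fit$accuracy, f1 = fit$f1,
                 decoder = fit$decoder, split = split),
            class = "fusion_model")
}

#' Rank best-fusion, simplest-fusion and best-single models
#'
#' Produces the comparison report of the three candidate emotional
#' brain-network structures: the best fusion model (BFM), the simplest
#' fusion model (SFM) and the best single-subnetwork model (BSM). No
#' ordering is asserted; the observed one is reported.
#'
#' @param bfm,sfm,bsm Lists with `accuracy`, `f1` and optionally
#'   `split` (all three must share the same evaluation split when
#'   given).
#' @return Data frame (model, accuracy, f1, rank), ranked by accuracy
#'   with F1 as tie-break.
#' @export
rank_models <- function(bfm, sfm, bsm) {
  models <- list(BFM = bfm, SFM = sfm, BSM = bsm)
  splits <- Filter(Negate(is.null), lapply(models, function(m) m$split))
  if (length(splits) > 1L) {
    for (s in splits[-1]) {
      if (!identical(s$test, splits[[1]]$test)) {
        stop("models were evaluated on different held-out splits")
      }
    }
  }
  out <- data.frame(
    model = names(models),
    accuracy = vapply(models, function(m) m$accuracy, numeric(1)),
    f1 = vapply(models, function(m) m$f1, numeric(1)),
    row.names = NULL
  )
  out$rank <- rank(-out$accuracy * 1e6 - out$f1, ties.method = "min")
  out[order(out$rank), ]
}
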