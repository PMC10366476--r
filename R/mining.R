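#' Seven-way spatial subnetwork partition of a 10-20 montage
#'
#' Assigns electrodes to the seven scalp subnetworks by label prefix
#' with longest-prefix matching (so `FC1` lands in the frontal-central
#' group, not the frontal one): Fp/AF -> 1 (prefrontal), F -> 2
#' (frontal), FC/FT -> 3 (frontal-central/-temporal), C/T -> 4
#' (central/temporal), CP/TP -> 5 (central-/temporal-parietal),
#' P -> 6 (parietal), PO/O -> 7 (parieto-occipital/occipital).
#'
#' @param montage A montage.
#' @return List of 7 `subnetwork_def` objects, each with `id`, `name`
#'   and `electrodes`; together they partition the montage.
#' @export
partition_subnetworks <- function(montage) {
  rules <- c(Fp = 1L, AF = 1L, FC = 3L, FT = 3L, CP = 5L, TP = 5L, PO = 7L,
             F = 2L, C = 4L, T = 4L, P = 6L, O = 7L)  # longest prefixes first
  assign_one <- function(lab) {
    for (pre in names(rules)) {
      if (startsWith(lab, pre)) return(rules[[pre]])
    }
    stop("unrecognized electrode label: ", lab)
  }
  ids <- vapply(montage$label, assign_one, integer(1))
  names_ <- c("prefrontal (Fp/AF)", "frontal (F)", "frontal-central (FC/FT)",
              "central-temporal (C/T)", "centro-parietal (CP/TP)",
              "parietal (P)", "parieto-occipital (PO/O)")
  lapply(1:7, function(i) {
    structure(list(id = i, name = names_[i],
                   electrodes = montage$label[ids == i]),
              class = "subnetwork_def")
  })
}

#' Per-electrode contribution of a trained decoder
#'
#' The contribution of electrode e is the total absolute input weight
#' mass `sum |W_ij|` over the input neurons subscribed to e's streams
#' and all hidden neurons, normalized across the decoder's electrodes
#' to sum to 100 percent.
#'
#' @param decoder A trained decoder.
#' @param electrode Optional single electrode; when given, returns just
#'   its percentage (error if it is not in the decoder's map).
#' @return Named numeric vector of percentages (or a scalar).
#' @export
electrode_contribution <- function(decoder, electrode = NULL) {
  mass <- tapply(rowSums(abs(decoder$W_ih)), decoder$map$channel, sum)
  mass <- mass[decoder$electrodes]
  names(mass) <- decoder$electrodes
  total <- sum(mass)
  pct <- if (total == 0) {
    stats::setNames(rep(100 / length(mass), length(mass)), names(mass))
  } else 100 * mass / total
  if (!is.null(electrode)) {
    if (!electrode %in% names(pct)) {
      stop("electrode absent from the decoder's map: ", electrode)
    }
    return(unname(pct[electrode]))
  }
  pct
}

#' Mine a subnetwork by contribution-ranked electrode elimination
#'
#' Starting from the full electrode set of the subnetwork, repeatedly:
#' train a fresh decoder on the current set (stratified 80/20 split),
#' record the held-out accuracy/F1 and each electrode's contribution,
#' then drop the electrode with the smallest contribution (ties broken
#' alphabetically). The loop stops when a single electrode remains or
#' performance stays poor (below chance + 5 points) for three
#' consecutive steps, so an n-electrode subnetwork yields up to n
#' models.
#'
#' @param set A binary-task `labeled_eeg_set` (emotion vs neutral).
#' @param subnet A `subnetwork_def` (or character vector of electrodes).
#' @param cfg A [train_config()].
#' @param encode One of "time" (raw post-onset signal) or a band name
#'   from [eeg_bands()] (band-power frames).
#' @param contribution Contribution metric driving the elimination:
#'   "occlusion" (default; combined silence-one and keep-one probes of
#'   the trained decoder's class separation, see
#'   [occlusion_contribution()]), "weight" (input-weight mass,
#'   [electrode_contribution()]), or "drop_one" (retrain without each
#'   electrode; contribution is the accuracy drop). All modes are
#'   shifted to be non-negative and normalized to sum to 100.
#' @return A `mining_trace`: list with `steps` (each: electrodes,
#'   contributions, eliminated, accuracy, f1) and `subnetwork`.
#' @export
mine_subnetwork <- function(set, subnet, cfg = train_config(),
                            encode = "time",
                            contribution = c("occlusion", "weight", "drop_one")) {
  contribution <- match.arg(contribution)
  electrodes <- if (inherits(subnet, "subnetwork_def")) subnet$electrodes
                else as.character(subnet)
  if (length(electrodes) == 0L) stop("empty subnetwork")
  chance <- 100 * max(table(set$labels)) / length(set$labels)
  encode_fn <- function(els) {
    if (encode == "time") encode_dataset(set, els)
    else encode_band_dataset(set, els, band = encode)
  }
  steps <- list()
  current <- sort(electrodes)
  poor_run <- 0L
  repeat {
    ds <- encode_fn(current)
    fit <- fit_and_score(ds, cfg, montage = set$montage)
    contrib <- switch(contribution,
      weight = electrode_contribution(fit$decoder),
      occlusion = occlusion_contribution(fit$decoder, ds),
      drop_one = drop_one_contribution(set, current, cfg, encode_fn,
                                       fit$accuracy))
    victim <- if (length(current) > 1L) {
      current[order(contrib[current], current)][1]  # min contribution, tie: alphabetical
    } else NA_character_
    steps[[length(steps) + 1L]] <- list(
      electrodes = current, contributions = contrib, eliminated = victim,
      accuracy = fit$accuracy, f1 = fit$f1
    )
    poor_run <- if (fit$accuracy < chance + 5) poor_run + 1L else 0L
    if (length(current) == 1L || poor_run >= 3L) break
    current <- setdiff(current, victim)
  }
  structure(list(steps = steps,
                 subnetwork = if (inherits(subnet, "subnetwork_def")) subnet
                              else NULL),
            class = "mining_trace")
}

#' Occlusion contribution of each electrode to a trained decoder
#'
#' Scores each electrode by two complementary occlusion probes on the
#' trained decoder's output spike counts, using a standardized class
#' separation (difference of class-conditional mean counts over its
#' standard error for binary tasks, mean between-class spread
#' otherwise): the *drop* in separation when the electrode's input
#' neurons are silenced, and the *solo* separation retained when every
#' other electrode is silenced instead. The drop probe measures unique
#' information but is blind to redundancy (silencing one of two equally
#' informative electrodes barely hurts); the solo probe measures
#' standalone information and is redundancy-proof. Each probe is
#' shifted to be non-negative and normalized, and their average is
#' returned as percentages summing to 100.
#'
#' @param decoder A trained decoder.
#' @param dataset The spike dataset it was trained on (or any labeled
#'   dataset encoded for the same electrodes).
#' @return Named percentage vector over the decoder's electrodes.
#' @export
occlusion_contribution <- function(decoder, dataset) {
  sep_of <- function(counts_mat) {
    # counts_mat: n_out x n_trials
    if (nrow(counts_mat) == 1L) {
      pos <- dataset$labels == decoder$classes[1]
      x <- counts_mat[1, pos]; y <- counts_mat[1, !pos]
      se <- sqrt(stats::var(x) / length(x) + stats::var(y) / length(y))
      if (!is.finite(se) || se == 0) se <- 1
      abs(mean(x) - mean(y)) / se   # standardized class separation
    } else {
      per_class <- sapply(decoder$classes, function(cl) {
        rowMeans(counts_mat[, dataset$labels == cl, drop = FALSE])
      })
      mean(apply(per_class, 1, stats::sd))
    }
  }
  sep_with_rows <- function(keep_rows) {
    cm <- vapply(dataset$spikes, function(sp) {
      sp[setdiff(seq_len(nrow(sp)), keep_rows), ] <- 0L
      run_trial(decoder, sp, dataset$dt, learn = FALSE)$out_counts
    }, numeric(ncol(decoder$W_ho)))
    sep_of(matrix(cm, ncol = length(dataset$spikes)))
  }
  all_rows <- seq_len(nrow(decoder$W_ih))
  sep_full <- sep_with_rows(all_rows)
  probes <- vapply(decoder$electrodes, function(e) {
    rows <- which(decoder$map$channel == e)
    c(drop = sep_full - sep_with_rows(setdiff(all_rows, rows)),
      solo = sep_with_rows(rows))
  }, numeric(2))
  norm1 <- function(v) {
    v <- v - min(v, 0) + 1e-9
    v / sum(v)
  }
  pct <- 50 * (norm1(probes["drop", ]) + norm1(probes["solo", ]))
  stats::setNames(100 * pct / sum(pct), decoder$electrodes)
}

drop_one_contribution <- function(set, electrodes, cfg, encode_fn, full_acc) {
  if (length(electrodes) == 1L) {
    return(stats::setNames(100, electrodes))
  }
  drops <- vapply(electrodes, function(e) {
    ds <- encode_fn(setdiff(electrodes, e))
    full_acc - fit_and_score(ds, cfg, montage = set$montage)$accuracy
  }, numeric(1))
  shifted <- drops - min(drops) + 1e-9
  100 * shifted / sum(shifted)
}

#' @export
print.mining_trace <- function(x, ...) {
  cat(sprintf("<mining_trace> %d steps (%d -> %d electrodes)\n",
              length(x$steps), length(x$steps[[1]]$electrodes),
              length(x$steps[[length(x$steps)]]$electrodes)))
  invisible(x)
}

#' Flatten a mining trace to a data frame
#'
#' @param trace A `mining_trace`.
#' @return Data frame with one row per step: step, n_electrodes,
#'   electrodes, eliminated, accuracy, f1, contributions (JSON).
#' @export
mining_trace_df <- function(trace) {
  do.call(rbind, lapply(seq_along(trace$steps), function(i) {
    s <- trace$steps[[i]]
    data.frame(step = i, n_electrodes = length(s$electrodes),
               electrodes = paste(s$electrodes, collapse = ";"),
               eliminated = s$eliminated,
               accuracy = s$accuracy, f1 = s$f1,
               contributions = as.character(
                 jsonlite::toJSON(as.list(round(s$contributions, 4)),
                                  auto_unbox = TRUE)),
               stringsAsFactors = FALSE)
  }))
}

#' Best and simplest models of a mining trace
#'
#' The best model maximizes accuracy, with ties broken by higher F1 and
#' then by fewer electrodes; the simplest model is the final recorded
#' step.
#'
#' @param trace A `mining_trace`.
#' @return List with `best` and `simplest`, each the corresponding step
#'   augmented with its `index` in the trace.
#' @export
select_best_simplest <- function(trace) {
  if (length(trace$steps) == 0L) stop("empty trace")
  acc <- vapply(trace$steps, `[[`, numeric(1), "accuracy")
  f1 <- vapply(trace$steps, `[[`, numeric(1), "f1")
  size <- vapply(trace$steps, function(s) length(s$electrodes), numeric(1))
  ord <- order(-acc, -f1, size)
  best <- trace$steps[[ord[1]]]
  best$index <- ord[1]
  simplest <- trace$steps[[length(trace$steps)]]
  simplest$index <- length(trace$steps)
  list(best = best, simplest = simplest)
}
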