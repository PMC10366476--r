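#' Accuracy, F1 and confusion matrix for a prediction run
#'
#' Accuracy is `correct / total * 100`. For a binary task the F1 score
#' is `2PR/(P+R)` of the positive class (the first level); for the
#' four-class task it is the unweighted macro mean of the per-class F1
#' scores.
#'
#' @param preds Predicted labels.
#' @param labels True labels.
#' @param task `"binary"` or `"multiclass"`.
#' @param classes Class set; defaults to the levels of `labels`.
#' @return An `eval_report` list with `accuracy` (percent), `f1`,
#'   `confusion` (true x predicted), `task`, `chance` (percent accuracy
#'   of always answering the majority class).
#' @export
evaluate <- function(preds, labels, task = c("binary", "multiclass"),
                     classes = NULL) {
  task <- match.arg(task)
  preds <- as.character(preds); labels <- as.character(labels)
  if (length(preds) == 0L) stop("empty input")
  if (length(preds) != length(labels)) stop("preds and labels differ in length")
  if (is.null(classes)) classes <- sort(unique(labels))
  if (!all(labels %in% classes) || !all(preds %in% classes)) {
    stop("label outside the task's class set")
  }
  cm <- table(factor(labels, classes), factor(preds, classes))
  acc <- 100 * sum(diag(cm)) / sum(cm)
  f1_of <- function(cl) {
    tp <- cm[cl, cl]
    prec_den <- sum(cm[, cl]); rec_den <- sum(cm[cl, ])
    if (tp == 0) return(0)
    p <- tp / prec_den; r <- tp / rec_den
    2 * p * r / (p + r)
  }
  f1 <- if (task == "binary") f1_of(classes[1]) else {
    mean(vapply(classes, f1_of, numeric(1)))
  }
  structure(list(accuracy = acc, f1 = f1, confusion = cm, task = task,
                 chance = 100 * max(table(factor(labels, classes))) /
                   length(labels)),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> %s: accuracy %.2f%% (chance %.2f%%), F1 %.3f\n",
              x$task, x$accuracy, x$chance, x$f1))
  print(x$confusion)
  invisible(x)
}

#' Run configuration for the end-to-end pipeline
#'
#' Collects the stage parameters of every module plus the global seed.
#' Round-trips losslessly through YAML ([write_run_config()] /
#' [read_run_config()]).
#'
#' @param emotion Emotion for the binary task.
#' @param n_trials_per_class,fs,duration_s,multiplier Generator settings.
#' @param epochs,batch_size,eta Training settings.
#' @param subnetworks Subnetwork ids to mine.
#' @param bands Bands for the biomarker stage.
#' @param gc_order,gc_freqs Granger stage settings.
#' @param seed Global seed.
#' @return A `run_config` list.
#' @export
run_config <- function(emotion = "fear", n_trials_per_class = 10L, fs = 128,
                       duration_s = 5, multiplier = 2, epochs = 20L,
                       batch_size = 20L, eta = 0.01, subnetworks = 6L,
                       bands = names(eeg_bands()), gc_order = 20L,
                       gc_freqs = 1:48, seed = 1L) {
  cfg <- list(emotion = emotion,
              n_trials_per_class = as.integer(n_trials_per_class),
              fs = fs, duration_s = duration_s, multiplier = multiplier,
              epochs = as.integer(epochs), batch_size = as.integer(batch_size),
              eta = eta, subnetworks = as.integer(subnetworks), bands = bands,
              gc_order = as.integer(gc_order), gc_freqs = as.integer(gc_freqs),
              seed = as.integer(seed))
  required <- c("emotion", "fs", "duration_s", "seed")
  missing <- required[vapply(cfg[required], is.null, logical(1))]
  if (length(missing)) stop("run_config missing field(s): ",
                            paste(missing, collapse = ", "))
  class(cfg) <- "run_config"
  cfg
}

#' @rdname run_config
#' @param cfg A `run_config`.
#' @param path YAML file path.
#' @export
write_run_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @rdname run_config
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(run_config, raw)
}

config_hash <- function(cfg) {
  # order-stable digest of the config for provenance stamping
  s <- paste(deparse(unclass(cfg)[order(names(unclass(cfg)))]), collapse = "")
  sprintf("%08x", sum(utf8ToInt(s) * (seq_along(utf8ToInt(s)) %% 251 + 1)) %%
            .Machine$integer.max)
}

#' Run the full analysis pipeline and write stage artifacts
#'
#' Executes simulate -> encode -> train/mine -> fuse -> per-band
#' decoding + kernel attribution -> Granger connectivity on the
#' synthetic task defined by `cfg`, writing every stage's output (CSV)
#' plus a provenance log to `out_dir`. Metric CSVs are deterministic
#' functions of the config, so a rerun with the same config reproduces
#' them byte-identically.
#'
#' @param cfg A [run_config()].
#' @param out_dir Output directory.
#' @return Invisibly, a list of the stage results.
#' @export
run_pipeline <- function(cfg, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stamp <- function(stage) {
    cat(sprintf("%s [%s] config=%s seed=%d\n",
                format(Sys.time(), "%Y-%m-%dT%H:%M:%S"), stage,
                config_hash(cfg), cfg$seed),
        file = file.path(out_dir, "provenance.log"), append = TRUE)
  }
  run_stage <- function(stage, expr) {
    stamp(stage)
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  tcfg <- train_config(epochs = cfg$epochs, batch_size = cfg$batch_size,
                       eta = cfg$eta, seed = cfg$seed)

  set <- run_stage("simulate", standard_emotion_task(
    cfg$emotion, n_trials_per_class = cfg$n_trials_per_class, fs = cfg$fs,
    duration_s = cfg$duration_s, multiplier = cfg$multiplier, seed = cfg$seed))

  mining <- run_stage("mine", {
    subs <- partition_subnetworks(set$montage)
    traces <- lapply(cfg$subnetworks, function(id) {
      mine_subnetwork(set, subs[[id]], tcfg)
    })
    names(traces) <- paste0("subnetwork_", cfg$subnetworks)
    for (nm in names(traces)) {
      utils::write.csv(mining_trace_df(traces[[nm]]),
                       file.path(out_dir, paste0("mine_", nm, ".csv")),
                       row.names = FALSE)
    }
    traces
  })

  fusion <- run_stage("fuse", {
    sel <- lapply(mining, select_best_simplest)
    pts_best <- data.frame(
      subnetwork = seq_along(sel),
      accuracy = vapply(sel, function(s) s$best$accuracy, numeric(1)),
      f1 = vapply(sel, function(s) s$best$f1, numeric(1)))
    if (nrow(pts_best) >= 2L) {
      cl <- kmeans_2(pts_best[, c("accuracy", "f1")], seed = cfg$seed)
      pts_best$cluster <- cl$cluster
    } else pts_best$cluster <- 1L
    utils::write.csv(pts_best, file.path(out_dir, "fusion_points.csv"),
                     row.names = FALSE)
    pts_best
  })

  biomarker <- run_stage("bands", {
    el <- partition_subnetworks(set$montage)[[cfg$subnetworks[1]]]$electrodes
    bd <- lapply(cfg$bands, function(b) {
      r <- band_decode(set, el, band = b, cfg = tcfg)
      data.frame(band = b, accuracy = r$accuracy, f1 = r$f1)
    })
    bd <- do.call(rbind, bd)
    utils::write.csv(bd, file.path(out_dir, "band_decoding.csv"),
                     row.names = FALSE)
    mkl <- easymkl_contributions(set, seed = cfg$seed)
    utils::write.csv(data.frame(band = names(mkl$contributions),
                                contribution = as.numeric(mkl$contributions)),
                     file.path(out_dir, "mkl_contributions.csv"),
                     row.names = FALSE)
    list(band_decoding = bd, mkl = mkl)
  })

  gc <- run_stage("granger", {
    eff <- cfg_effect_electrodes(cfg)
    trials <- lapply(set$recordings[set$labels == cfg$emotion], function(r) {
      t(select_channels(r, eff)$data)  # samples x channels
    })
    g <- spectral_granger(trials, order = cfg$gc_order,
                          freqs = cfg$gc_freqs, fs = cfg$fs,
                          labels = eff)
    net <- directed_network(g, band = "beta", trials = trials,
                            n_surrogates = 20L, seed = cfg$seed)
    utils::write.csv(net$edges, file.path(out_dir, "granger_edges.csv"),
                     row.names = FALSE)
    net
  })

  invisible(list(set = set, mining = mining, fusion = fusion,
                 biomarker = biomarker, granger = gc))
}

cfg_effect_electrodes <- function(cfg) {
  eff <- Filter(function(e) e$class == cfg$emotion, default_effect_map())
  if (length(eff)) eff[[1]]$electrodes else c("P1", "P2", "P5")
}
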