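#' @useDynLib sbpsnn, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' Leaky integrate-and-fire parameters
#'
#' @param tau_m Membrane time constant, s.
#' @param v_rest,v_reset,v_th Resting, reset and threshold potentials
#'   (dimensionless units; `v_th > v_rest`).
#' @param t_ref Absolute refractory period, s.
#' @param r_m Membrane resistance (scales external currents).
#' @return A `lif_params` list.
#' @export
lif_params <- function(tau_m = 0.02, v_rest = 0, v_reset = 0, v_th = 1,
                       t_ref = 0.002, r_m = 1) {
  stopifnot(tau_m > 0, t_ref > 0, v_th > v_rest)
  structure(list(tau_m = tau_m, v_rest = v_rest, v_reset = v_reset,
                 v_th = v_th, t_ref = t_ref, r_m = r_m),
            class = "lif_params")
}

#' One Euler step of a LIF neuron
#'
#' `dv/dt = (-(v - v_rest) + r_m * I) / tau_m`; a spike is emitted when
#' `v >= v_th`, after which `v` is reset and clamped for the refractory
#' period.
#'
#' @param state List with `v` (membrane potential) and `ref` (remaining
#'   refractory time, s); use `lif_state(p)` for a resting state.
#' @param input_current External current I.
#' @param p A [lif_params()].
#' @param dt Time step, s (`dt <= tau_m / 10`).
#' @return List with updated `state` and `spiked` flag.
#' @export
lif_step <- function(state, input_current, p, dt) {
  if (dt <= 0) stop("dt must be > 0")
  if (dt > p$tau_m / 10) stop("dt must be <= tau_m / 10 for a stable Euler step")
  spiked <- FALSE
  if (state$ref > 0) {
    state$ref <- max(0, state$ref - dt)
  } else {
    state$v <- state$v +
      dt * (-(state$v - p$v_rest) + p$r_m * input_current) / p$tau_m
    if (state$v >= p$v_th) {
      spiked <- TRUE
      state$v <- p$v_reset
      state$ref <- p$t_ref
    }
  }
  list(state = state, spiked = spiked)
}

#' @rdname lif_step
#' @export
lif_state <- function(p) list(v = p$v_rest, ref = 0)

#' Short-term plasticity parameters (Tsodyks-Markram)
#'
#' @param U Utilization increment per spike (0 < U <= 1).
#' @param tau_f Facilitation decay time constant, s.
#' @param tau_d Depression recovery time constant, s.
#' @return An `stp_params` list.
#' @export
stp_params <- function(U = 0.2, tau_f = 0.2, tau_d = 0.1) {
  stopifnot(U > 0, U <= 1, tau_f > 0, tau_d > 0)
  structure(list(U = U, tau_f = tau_f, tau_d = tau_d), class = "stp_params")
}

#' One step of Tsodyks-Markram short-term plasticity
#'
#' Between spikes the utilization `u` decays to 0 with `tau_f` and the
#' resource `R` recovers to 1 with `tau_d`. On a presynaptic spike,
#' `u <- u + U * (1 - u)`, the synaptic efficacy `u * R * w` is
#' released, and then `R <- R * (1 - u)`.
#'
#' @param syn_state List with `u` and `R`; rest state is
#'   `list(u = 0, R = 1)`.
#' @param pre_spike 1 if the presynaptic neuron spiked this step.
#' @param p An [stp_params()].
#' @param dt Time step, s.
#' @param w Static synaptic weight multiplying the efficacy.
#' @return List with updated `syn_state` and `efficacy` (0 when no
#'   spike).
#' @export
stp_update <- function(syn_state, pre_spike, p, dt, w = 1) {
  u <- syn_state$u; R <- syn_state$R
  if (u < 0 || u > 1 || R < 0 || R > 1) stop("invalid STP state")
  u <- u * exp(-dt / p$tau_f)
  R <- 1 - (1 - R) * exp(-dt / p$tau_d)
  eff <- 0
  if (pre_spike) {
    u <- u + p$U * (1 - u)
    eff <- u * R * w
    R <- R * (1 - u)
  }
  list(syn_state = list(u = u, R = R), efficacy = eff)
}

#' STDP parameters
#'
#' @param a_plus,a_minus LTP / LTD amplitudes (>= 0).
#' @param tau_plus,tau_minus Trace time constants, s.
#' @return An `stdp_params` list.
#' @export
stdp_params <- function(a_plus = 0.01, a_minus = 0.01,
                        tau_plus = 0.02, tau_minus = 0.02) {
  stopifnot(a_plus >= 0, a_minus >= 0, tau_plus > 0, tau_minus > 0)
  structure(list(a_plus = a_plus, a_minus = a_minus,
                 tau_plus = tau_plus, tau_minus = tau_minus),
            class = "stdp_params")
}

#' Pairwise STDP weight change
#'
#' `a_plus * exp(-dt/tau_plus)` for pre-before-post (`delta_t > 0`),
#' `-a_minus * exp(dt/tau_minus)` for post-before-pre, 0 at exact
#' coincidence.
#'
#' @param delta_t `t_post - t_pre`, s (vectorized).
#' @param p An [stdp_params()].
#' @return Weight change(s).
#' @export
stdp_delta <- function(delta_t, p) {
  stopifnot(all(is.finite(delta_t)))
  ifelse(delta_t > 0, p$a_plus * exp(-delta_t / p$tau_plus),
         ifelse(delta_t < 0, -p$a_minus * exp(delta_t / p$tau_minus), 0))
}

#' Multiplicative homeostatic threshold adjustment
#'
#' Scales a neuron's firing threshold by
#' `1 + gamma * (rate - target) / target`, keeping it within
#' `[0.5, 2]` times its initial value, so persistently over-active
#' neurons become harder to fire and silent ones easier.
#'
#' @param neuron_state List with `v_th`, `v_th_init`, `gamma`
#'   (adjustment gain) and `spikes` (spike count in the window).
#' @param target_rate Target firing rate, Hz (> 0).
#' @param window Observation window, s (> 0).
#' @return Updated `neuron_state`.
#' @export
homeostatic_adjust <- function(neuron_state, target_rate, window) {
  if (target_rate <= 0) stop("target_rate must be > 0")
  if (window <= 0) stop("window must be > 0")
  rate <- neuron_state$spikes / window
  fac <- 1 + neuron_state$gamma * (rate - target_rate) / target_rate
  v_th <- neuron_state$v_th * fac
  neuron_state$v_th <- min(max(v_th, 0.5 * neuron_state$v_th_init),
                           2 * neuron_state$v_th_init)
  neuron_state
}

#' Self-backpropagation mirroring of output-synapse adjustments
#'
#' For each hidden neuron the potentiating (positive) part of its
#' aggregated outgoing weight adjustments is mirrored onto its active
#' incoming synapses scaled by `rho_ltp`, and the depressing (negative)
#' part scaled by `rho_ltd`. "Active" synapses are those whose
#' presynaptic input neuron spiked within the STDP trace window of a
#' postsynaptic hidden spike during the batch.
#'
#' @param output_deltas Matrix (n_hidden x n_out) of hidden-to-output
#'   weight adjustments from the teacher-driven STDP step.
#' @param active Binary matrix (n_in x n_hidden) marking active
#'   input-to-hidden synapses.
#' @param p List with `rho_ltp` and `rho_ltd`, both in [0, 1].
#' @return Matrix (n_in x n_hidden) of input-to-hidden adjustments.
#' @export
sbp_backpropagate <- function(output_deltas, active, p) {
  stopifnot(p$rho_ltp >= 0, p$rho_ltp <= 1, p$rho_ltd >= 0, p$rho_ltd <= 1)
  output_deltas <- as.matrix(output_deltas)
  active <- as.matrix(active)
  if (ncol(active) != nrow(output_deltas)) {
    stop("active mask and output deltas disagree on the hidden layer size")
  }
  pos <- rowSums(pmax(output_deltas, 0))
  neg <- rowSums(pmin(output_deltas, 0))
  mirrored <- p$rho_ltp * pos + p$rho_ltd * neg   # per hidden neuron
  # distribute each hidden neuron's mirrored adjustment over its active
  # incoming synapses (a lone active synapse receives the full amount)
  n_active <- pmax(colSums(active), 1)
  active * matrix(mirrored / n_active, nrow(active), ncol(active), byrow = TRUE)
}

#' Mean-square decoding loss
#'
#' `C = 1/2 * sum_k (u_k - o_k)^2` between realized output rates and
#' expected teaching outputs.
#'
#' @param u Realized outputs.
#' @param o Expected outputs.
#' @return The scalar loss.
#' @export
loss_mse <- function(u, o) {
  if (length(u) != length(o)) stop("u and o must have equal length")
  0.5 * sum((u - o)^2)
}

#' Distance-based small-world weight initialization
#'
#' Connects node pairs within `radius` with small random weights of
#' which a fixed fraction (default 80%) are positive; pairs beyond the
#' radius are connected with probability `p_long` under the same weight
#' law. Deterministic given `seed`.
#'
#' @param pre_pos,post_pos Matrices of 3D positions (mm) for the pre-
#'   and postsynaptic populations.
#' @param radius Connection radius, mm (> 0).
#' @param p_long Long-range connection probability.
#' @param w_scale Weight magnitude scale (half-normal).
#' @param positive_frac Fraction of local connections drawn positive.
#' @param seed Integer seed.
#' @return Weight matrix (n_pre x n_post) with attribute `local` (the
#'   logical within-radius mask).
#' @export
init_small_world <- function(pre_pos, post_pos = pre_pos, radius,
                             p_long = 0.05, w_scale = 0.1,
                             positive_frac = 0.8, seed = 1L) {
  if (radius <= 0) stop("radius must be > 0")
  pre_pos <- as.matrix(pre_pos); post_pos <- as.matrix(post_pos)
  n_pre <- nrow(pre_pos); n_post <- nrow(post_pos)
  d2 <- outer(rowSums(pre_pos^2), rowSums(post_pos^2), "+") -
    2 * pre_pos %*% t(post_pos)
  local <- d2 <= radius^2
  with_seed(seed, {
    long <- !local & matrix(stats::runif(n_pre * n_post) < p_long, n_pre, n_post)
    conn <- local | long
    if (!any(conn)) stop("radius yields zero connections")
    W <- matrix(0, n_pre, n_post)
    n_conn <- sum(conn)
    sgn <- ifelse(stats::runif(n_conn) < positive_frac, 1, -1)
    W[conn] <- sgn * abs(stats::rnorm(n_conn, sd = w_scale))
    attr(W, "local") <- local
    W
  })
}

#' Construct an untrained emotional decoder
#'
#' Builds the three-layer spiking decoder for a given electrode subset:
#' 100 input neurons (round-robin over the electrodes' ON/OFF streams,
#' see [input_layer_map()]), 200 hidden LIF neurons (half excitatory,
#' half inhibitory) placed on the 471-node spatial grid, and 1 (binary)
#' or 4 (four-class) output LIF neurons. Input-to-hidden weights are
#' initialized by the distance-based small-world rule over the grid.
#'
#' @param electrodes Electrode subset feeding the decoder.
#' @param classes Class labels; `length(classes) == 2` uses a single
#'   output neuron, otherwise one per class.
#' @param montage Montage carrying electrode positions.
#' @param n_hidden Hidden layer size (default 200).
#' @param lif,stp,stdp,sbp Parameter lists; see [lif_params()],
#'   [stp_params()], [stdp_params()]; `sbp` has `rho_ltp`, `rho_ltd`.
#' @param lif_out LIF parameters of the output layer; by default a slow
#'   integrator (long membrane time constant) so the output spike count
#'   reflects the accumulated weighted hidden activity of the whole
#'   trial rather than moment-to-moment fluctuations.
#' @param radius,p_long Small-world initialization parameters (mm).
#' @param seed Integer seed for all initialization randomness.
#' @return A `decoder` object.
#' @export
decoder_new <- function(electrodes, classes, montage = standard_montage_62(),
                        n_hidden = 200L,
                        lif = lif_params(r_m = 8),
                        lif_out = lif_params(tau_m = 0.5, r_m = 8),
                        stp = stp_params(),
                        stdp = stdp_params(),
                        sbp = list(rho_ltp = 0.9, rho_ltd = 0.6),
                        radius = 60, p_long = 0.05, seed = 1L) {
  map <- input_layer_map(electrodes)
  grid <- build_node_grid(montage)
  in_nodes <- grid$electrode_assignment[map$channel]
  in_pos <- grid$nodes[in_nodes, , drop = FALSE]
  hid_nodes <- with_seed(seed, sample.int(nrow(grid$nodes), n_hidden,
                                          replace = n_hidden > nrow(grid$nodes)))
  hid_pos <- grid$nodes[hid_nodes, , drop = FALSE]
  W_ih <- init_small_world(in_pos, hid_pos, radius = radius, p_long = p_long,
                           seed = seed + 1L)
  n_out <- if (length(classes) == 2L) 1L else length(classes)
  hidden_sign <- rep(c(1, -1), length.out = n_hidden)  # 1:1 E/I ratio
  W_ho <- with_seed(seed + 2L, {
    matrix(abs(stats::rnorm(n_hidden * n_out, sd = 0.05)), n_hidden, n_out) *
      hidden_sign
  })
  structure(list(
    electrodes = electrodes, classes = classes, map = map, grid = grid,
    hidden_nodes = hid_nodes, hidden_sign = hidden_sign,
    W_ih = W_ih, W_ho = W_ho,
    vth_hidden = rep(lif$v_th, n_hidden),
    lif = lif, lif_out = lif_out, stp = stp, stdp = stdp, sbp = sbp,
    trained = FALSE
  ), class = "decoder")
}

#' @export
print.decoder <- function(x, ...) {
  cat(sprintf("<decoder> %d electrodes -> %d/%d/%d, classes: %s%s\n",
              length(x$electrodes), nrow(x$W_ih), ncol(x$W_ih), ncol(x$W_ho),
              paste(x$classes, collapse = "/"),
              if (x$trained) " (trained)" else " (untrained)"))
  invisible(x)
}

#' Training configuration for the spiking decoder
#'
#' @param epochs Number of training epochs (default 100).
#' @param batch_size Trials per batch (default 20).
#' @param teaching_rate Teacher spike rate, Hz (default 100).
#' @param eta Learning rate.
#' @param sbp Whether self-backpropagation to the hidden synapses is
#'   enabled.
#' @param homeo_target Homeostatic target hidden rate, Hz.
#' @param homeo_gamma Homeostatic gain (0 disables).
#' @param weight_decay Per-batch multiplicative shrinkage of the learned
#'   weights toward zero; applied only while learning is active, it
#'   keeps the teacher-driven drift from pinning weights at the clip
#'   bounds.
#' @param seed Seed for trial shuffling.
#' @return A `train_config` list.
#' @export
train_config <- function(epochs = 100L, batch_size = 20L, teaching_rate = 100,
                         eta = 0.01, sbp = TRUE, homeo_target = 10,
                         homeo_gamma = 0.005, weight_decay = 5e-4,
                         seed = 1L) {
  stopifnot(epochs >= 1, batch_size >= 1, teaching_rate > 0, eta >= 0,
            weight_decay >= 0, weight_decay < 1)
  structure(list(epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 teaching_rate = teaching_rate, eta = eta, sbp = isTRUE(sbp),
                 homeo_target = homeo_target, homeo_gamma = homeo_gamma,
                 weight_decay = weight_decay, seed = as.integer(seed)),
            class = "train_config")
}

# Teacher spike period in steps: the requested rate, but never faster
# than the refractory-limited output rate (one spike per ref + 1 steps).
teaching_period <- function(rate, dt, t_ref) {
  max(round(1 / (rate * dt)), ceiling(t_ref / dt) + 1L, 1L)
}

# Regular teacher spike train at `rate` Hz for the target output neuron.
teacher_matrix <- function(label, classes, n_out, T, dt, rate, t_ref) {
  teach <- matrix(0L, n_out, T)
  k <- if (n_out == 1L) if (label == classes[1]) 1L else NA_integer_
       else match(label, classes)
  if (!is.na(k)) {
    period <- teaching_period(rate, dt, t_ref)
    teach[k, seq(period, T, by = period)] <- 1L
  }
  teach
}

run_trial <- function(decoder, spikes, dt, teach = NULL, learn = FALSE) {
  if (is.null(teach)) teach <- matrix(0L, 0L, 0L)
  sim_trial_cpp(spikes, decoder$W_ih, decoder$W_ho, decoder$vth_hidden,
                decoder$lif, decoder$lif_out, decoder$stp, dt,
                decoder$stdp$tau_plus, teach, learn, active_min = 0.2)
}

#' Train the spiking decoder with teacher-driven STDP and SBP
#'
#' Runs `cfg$epochs` epochs over the spike dataset in shuffled batches
#' of `cfg$batch_size`. Each trial is simulated forward (LIF dynamics
#' with short-term plasticity); the hidden-to-output synapses receive a
#' teacher-driven STDP adjustment, the difference between the teaching
#' spike train and the realized output spikes correlated with the
#' presynaptic hidden trace. With `cfg$sbp` enabled these output
#' adjustments are mirrored onto the active input-to-hidden synapses
#' with separate LTP/LTD proportions ([sbp_backpropagate()]). After
#' every batch the hidden-neuron sign constraint (excitatory outgoing
#' weights >= 0, inhibitory <= 0) is re-imposed, weights are clipped to
#' [-1, 1], and hidden thresholds are homeostatically adjusted.
#'
#' The per-epoch loss history records `C = 1/2 sum_k (u_k - o_k)^2`
#' averaged over trials, where `u_k` is the realized output rate
#' normalized by the teaching rate.
#'
#' @param decoder An untrained (or pre-trained) decoder from
#'   [decoder_new()].
#' @param data List with `spikes` (list of n_input x T binary matrices),
#'   `labels` (factor over the decoder's classes), and `dt`.
#' @param cfg A [train_config()].
#' @return The trained decoder, with a `history` data.frame
#'   (epoch, C, train_acc) attached.
#' @export
snn_train <- function(decoder, data, cfg = train_config()) {
  labels <- as.character(data$labels)
  n_trials <- length(data$spikes)
  if (n_trials == 0L) stop("empty dataset")
  if (length(unique(labels)) < 2L) stop("training needs at least two classes")
  if (!all(labels %in% decoder$classes)) stop("label outside the decoder's class set")
  dt <- data$dt
  T <- ncol(data$spikes[[1]])
  n_out <- ncol(decoder$W_ho)
  trial_s <- T * dt
  history <- data.frame(epoch = integer(0), C = numeric(0),
                        train_acc = numeric(0))
  teachers <- lapply(labels, teacher_matrix, classes = decoder$classes,
                     n_out = n_out, T = T, dt = dt, rate = cfg$teaching_rate,
                     t_ref = decoder$lif_out$t_ref)
  expected <- lapply(labels, function(l) {
    if (n_out == 1L) as.numeric(l == decoder$classes[1])
    else as.numeric(decoder$classes == l)
  })
  for (epoch in seq_len(cfg$epochs)) {
    order_ <- with_seed(cfg$seed + epoch, sample.int(n_trials))
    losses <- numeric(n_trials)
    correct <- logical(n_trials)
    b0 <- seq(1L, n_trials, by = cfg$batch_size)
    for (bs in b0) {
      idx <- order_[bs:min(bs + cfg$batch_size - 1L, n_trials)]
      delta_ho <- matrix(0, nrow(decoder$W_ho), n_out)
      active <- matrix(0L, nrow(decoder$W_ih), ncol(decoder$W_ih))
      hidden_spikes <- numeric(ncol(decoder$W_ih))
      for (i in idx) {
        res <- run_trial(decoder, data$spikes[[i]], dt,
                         teach = teachers[[i]], learn = TRUE)
        delta_ho <- delta_ho + res$delta_ho
        active <- pmax(active, res$active)
        hidden_spikes <- hidden_spikes + res$hidden_counts
        u <- res$out_counts / trial_s / cfg$teaching_rate
        losses[i] <- loss_mse(u, expected[[i]])
        correct[i] <- identical(decode_counts(res$out_counts, decoder$classes,
                                              cfg$teaching_rate, trial_s, dt,
                                              decoder$lif_out$t_ref),
                                labels[i])
      }
      # trace sums scaled by the STDP amplitudes, averaged over the batch
      delta_ho <- (decoder$stdp$a_plus * pmax(delta_ho, 0) +
                   decoder$stdp$a_minus * pmin(delta_ho, 0)) / length(idx)
      decoder$W_ho <- decoder$W_ho + cfg$eta * delta_ho
      # Dale sign constraint on hidden outgoing weights
      exc <- decoder$hidden_sign > 0
      decoder$W_ho[exc, ] <- pmax(decoder$W_ho[exc, , drop = FALSE], 0)
      decoder$W_ho[!exc, ] <- pmin(decoder$W_ho[!exc, , drop = FALSE], 0)
      decoder$W_ho <- pmin(pmax(decoder$W_ho, -1), 1)
      if (cfg$eta > 0) decoder$W_ho <- decoder$W_ho * (1 - cfg$weight_decay)
      if (cfg$sbp) {
        d_ih <- sbp_backpropagate(delta_ho, active, decoder$sbp)
        decoder$W_ih <- pmin(pmax(decoder$W_ih + cfg$eta * d_ih, -1), 1)
        decoder$W_ih <- decoder$W_ih * (1 - cfg$weight_decay)
      }
      if (cfg$homeo_gamma > 0) {
        window <- length(idx) * trial_s
        for (j in seq_along(decoder$vth_hidden)) {
          st <- homeostatic_adjust(
            list(v_th = decoder$vth_hidden[j], v_th_init = decoder$lif$v_th,
                 gamma = cfg$homeo_gamma, spikes = hidden_spikes[j]),
            cfg$homeo_target, window)
          decoder$vth_hidden[j] <- st$v_th
        }
      }
    }
    history <- rbind(history, data.frame(epoch = epoch, C = mean(losses),
                                         train_acc = mean(correct)))
  }
  decoder$trained <- TRUE
  decoder$teaching_rate <- cfg$teaching_rate
  decoder$history <- history
  # calibrate the binary decision threshold at the trained operating
  # point: midpoint of the class-conditional mean output counts on the
  # training set (the teacher-rate target itself is refractory-capped
  # and the learned equilibrium sits wherever potentiation and
  # depression balance)
  if (n_out == 1L) {
    counts <- vapply(data$spikes, function(sp) {
      run_trial(decoder, sp, dt, learn = FALSE)$out_counts[1]
    }, numeric(1))
    m_pos <- mean(counts[labels == decoder$classes[1]])
    m_neg <- mean(counts[labels != decoder$classes[1]])
    decoder$count_threshold <- if (is.finite(m_pos) && is.finite(m_neg) &&
                                   m_pos != m_neg) {
      (m_pos + m_neg) / 2
    } else NA_real_
    decoder$positive_high <- !is.na(decoder$count_threshold) && m_pos > m_neg
  }
  decoder
}

# Decision rule shared by training accuracy and predict(). Binary
# decoders compare the output count against a threshold: the trained
# calibration when available, otherwise half the teacher spike count
# realizable at this time step (the teacher train is clocked and
# refractory-limited, so its count is floor(T/period)).
decode_counts <- function(counts, classes, teaching_rate, trial_s, dt, t_ref,
                          threshold = NA_real_, positive_high = TRUE) {
  if (length(counts) == 1L) {
    if (is.na(threshold)) {
      period <- teaching_period(teaching_rate, dt, t_ref)
      threshold <- 0.5 * floor(trial_s / dt / period)
    }
    hit <- counts >= threshold
    if (!positive_high) hit <- !hit
    if (hit) classes[1] else classes[2]
  } else {
    classes[which.max(counts)]  # which.max: lowest index wins ties
  }
}

#' Predict the class of a spike-encoded trial
#'
#' Multi-class decoders pick the output neuron with the highest spike
#' count (ties to the lowest class index); binary decoders with one
#' output neuron answer the positive class when the count reaches half
#' the teaching train, `0.5 * teaching_rate * duration`.
#'
#' @param decoder A trained decoder.
#' @param spike_input n_input x T binary matrix (or list of them).
#' @param dt Time step, s.
#' @return Predicted class label (character vector for a list input).
#' @export
snn_predict <- function(decoder, spike_input, dt) {
  if (!isTRUE(decoder$trained)) stop("decoder has not been trained")
  if (is.list(spike_input)) {
    return(vapply(spike_input, function(s) snn_predict(decoder, s, dt),
                  character(1)))
  }
  res <- run_trial(decoder, spike_input, dt, learn = FALSE)
  decode_counts(res$out_counts, decoder$classes, decoder$teaching_rate,
                ncol(spike_input) * dt, dt, decoder$lif_out$t_ref,
                threshold = if (is.null(decoder$count_threshold)) NA_real_
                            else decoder$count_threshold,
                positive_high = !isFALSE(decoder$positive_high))
}
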