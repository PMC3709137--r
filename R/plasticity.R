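#' Asymmetric STDP rule parameters
#'
#' A pre/post spike pair with timing difference `dt = t_pre - t_post`
#' changes the synaptic weight magnitude by
#' \deqn{dt \le 0:\quad +\Delta W^+ \frac{\tau_+}{\tau_- + \tau_+}
#'   e^{-|dt|/\tau_+}}
#' \deqn{dt > 0:\quad -\Delta W^- \left(1 - \frac{\tau_-}{\tau_- +
#'   \tau_+}\right) e^{-dt/\tau_-}}
#' i.e. a presynaptic spike preceding the target cell's spike potentiates
#' the synapse, otherwise it depresses; pairs closer in time act more
#' strongly. With the default equal time constants both prefactors are 1/2.
#' Adaptation applies only to ORN->LN and LN->LN synapses.
#'
#' @param dw_plus,dw_minus LTP / LTD magnitudes.
#' @param tau_plus,tau_minus Kernel time constants (ms).
#' @param w_min,w_max Clipping bounds of the stored weight (signed 16-bit
#'   range by default). Updates are sign-preserving: a pathway's weight
#'   magnitude is clipped to `[max(0, w_min), w_max]`, so an inhibitory
#'   synapse never becomes excitatory.
#' @param pairing Spike pairing scheme; `"nearest"` pairs each spike with
#'   the most recent opposite spike.
#' @export
stdp_params <- function(dw_plus = 150, dw_minus = 150, tau_plus = 20,
                        tau_minus = 20, w_min = -32768, w_max = 32767,
                        pairing = c("nearest")) {
  if (tau_plus <= 0 || tau_minus <= 0) {
    stop("kernel time constants must be positive", call. = FALSE)
  }
  if (w_min >= w_max) stop("`w_min` must be below `w_max`", call. = FALSE)
  structure(
    list(dw_plus = dw_plus, dw_minus = dw_minus, tau_plus = tau_plus,
         tau_minus = tau_minus, w_min = w_min, w_max = w_max,
         pairing = match.arg(pairing)),
    class = "stdp_params")
}

#' STDP weight increment for a spike-timing difference
#'
#' @param delta_t `t_pre - t_post` (ms); vectorized.
#' @param params An [stdp_params()].
#' @return Signed weight increment (positive = potentiation).
#' @export
stdp_delta <- function(delta_t, params = stdp_params()) {
  tp <- params$tau_plus
  tm <- params$tau_minus
  ifelse(delta_t <= 0,
         params$dw_plus * (tp / (tm + tp)) * exp(-abs(delta_t) / tp),
         -params$dw_minus * (1 - tm / (tm + tp)) * exp(-delta_t / tm))
}

#' Apply one step of STDP to a connectome (reference implementation)
#'
#' Pure-R mirror of the compiled engine's per-step plasticity update, using
#' nearest-spike pairing with per-neuron last-spike memory. Potentiation
#' events (a target LN spikes now) pair with the most recent presynaptic
#' spike, including one on the same step (`dt = 0`); depression events (a
#' presynaptic cell spikes now) pair with the most recent strictly earlier
#' postsynaptic spike.
#'
#' @param connectome An [build_mgc()] result.
#' @param spikes_now List with integer vectors `orn` and `ln` of cells
#'   spiking this step.
#' @param params An [stdp_params()].
#' @param memory List with `last_orn`, `last_ln` last-spike step indices
#'   (-1 = none); use [stdp_memory()] to initialize.
#' @param step Current step index (0-based).
#' @return List with the updated `connectome` and `memory`.
#' @export
apply_stdp_step <- function(connectome, spikes_now, params, memory, step) {
  cfg <- connectome$config
  clip <- function(m) pmin(params$w_max, pmax(max(0, params$w_min), m))
  delta <- cfg$delta
  orn_now <- rep(FALSE, cfg$n_orn); orn_now[spikes_now$orn] <- TRUE
  ln_now <- rep(FALSE, cfg$n_ln); ln_now[spikes_now$ln] <- TRUE

  for (i in spikes_now$ln) {   # potentiation onto spiking LN targets
    for (j in seq_len(cfg$n_orn)) {
      tp <- if (orn_now[j]) step else memory$last_orn[j]
      if (tp < 0) next
      dw <- stdp_delta((tp - step) * delta, params)
      connectome$W_ol[i, j] <- clip(connectome$W_ol[i, j] + dw)
    }
    for (j in seq_len(cfg$n_ln)) {
      if (j == i || !connectome$A_ll[i, j]) next
      tp <- if (ln_now[j]) step else memory$last_ln[j]
      if (tp < 0) next
      dw <- stdp_delta((tp - step) * delta, params)
      connectome$W_ll[i, j] <- -clip(-connectome$W_ll[i, j] + dw)
    }
  }
  for (j in spikes_now$orn) {  # depression from spiking presynaptic cells
    for (i in seq_len(cfg$n_ln)) {
      if (ln_now[i] || memory$last_ln[i] < 0) next
      dw <- stdp_delta((step - memory$last_ln[i]) * delta, params)
      connectome$W_ol[i, j] <- clip(connectome$W_ol[i, j] + dw)
    }
  }
  for (j in spikes_now$ln) {
    for (i in seq_len(cfg$n_ln)) {
      if (i == j || !connectome$A_ll[i, j] || ln_now[i] ||
          memory$last_ln[i] < 0) next
      dw <- stdp_delta((step - memory$last_ln[i]) * delta, params)
      connectome$W_ll[i, j] <- -clip(-connectome$W_ll[i, j] + dw)
    }
  }
  memory$last_orn[spikes_now$orn] <- step
  memory$last_ln[spikes_now$ln] <- step
  list(connectome = connectome, memory = memory)
}

#' @rdname apply_stdp_step
#' @export
stdp_memory <- function(connectome) {
  list(last_orn = rep(-1L, connectome$config$n_orn),
       last_ln = rep(-1L, connectome$config$n_ln))
}

#' Train a connectome with STDP on the randomized ratio sequence
#'
#' Each epoch simulates one full randomized ratio pulse train with
#' plasticity active on the ORN->LN and LN->LN pathways, carrying the
#' weights across epochs. The per-epoch summed absolute weight change is
#' recorded; the stability epoch is the first epoch whose change meets the
#' criterion. The default strict criterion (no weight changes at all) is the
#' hardware definition of a stable configuration and is reached once the
#' adapted LN layer no longer emits pairable spikes on the training
#' sequence; a relaxed criterion (summed change below `tol` of the total
#' weight magnitude) is available for partially converged states.
#'
#' @param connectome An [build_mgc()] result.
#' @param spec A [ratio_train_spec()].
#' @param epochs Maximum training epochs.
#' @param params An [stdp_params()].
#' @param seed Integer seed (per-epoch pulse order and noise derive from it).
#' @param snapshot_every Record full weight snapshots every this many epochs
#'   (plus the initial and final state).
#' @param stability `"strict"` or `"relaxed"`.
#' @param tol Relative tolerance of the relaxed criterion.
#' @param stop_at_stability Stop training once the criterion is met.
#' @return A list of class `stdp_history`: the trained `connectome`,
#'   `epoch` tibble (`epoch`, `abs_change`, `total_w`), weight `snapshots`,
#'   and `stability_epoch` (NA if never reached).
#' @export
train_stdp <- function(connectome, spec = ratio_train_spec(), epochs = 3000,
                       params = stdp_params(), seed = 1,
                       snapshot_every = 100,
                       stability = c("strict", "relaxed"), tol = 1e-3,
                       stop_at_stability = FALSE) {
  stopifnot(inherits(connectome, "mgc_connectome"))
  if (epochs < 0) stop("`epochs` must be non-negative", call. = FALSE)
  stability <- match.arg(stability)
  cfg <- connectome$config

  snapshots <- list(`0` = list(W_ol = connectome$W_ol, W_ll = connectome$W_ll))
  ep_change <- numeric(epochs)
  ep_total <- numeric(epochs)
  stability_epoch <- NA_integer_

  for (ep in seq_len(epochs)) {
    episode <- make_ratio_pulse_train(spec, seed = derive_seed(seed, ep))
    set.seed(derive_seed(seed, ep) + 1L)
    res <- mgc_sim_core(
      connectome$W_ol, connectome$W_op, connectome$W_ll, connectome$W_lp,
      connectome$W_pp, connectome$A_ll, episode$currents, cfg$delta,
      cfg$tau_m_orn, cfg$tau_m_ln, cfg$tau_m_pn, cfg$tau_e, cfg$tau_i,
      cfg$v_theta, cfg$v_ahp, cfg$c_m, cfg$b, cfg$noise_sigma,
      TRUE, params$dw_plus, params$dw_minus, params$tau_plus,
      params$tau_minus, params$w_min, params$w_max, FALSE)
    connectome$W_ol <- res$W_ol
    connectome$W_ll <- res$W_ll
    ep_change[ep] <- res$abs_change
    ep_total[ep] <- sum(abs(res$W_ol)) + sum(abs(res$W_ll))
    if (ep %% snapshot_every == 0 || ep == epochs) {
      snapshots[[as.character(ep)]] <-
        list(W_ol = connectome$W_ol, W_ll = connectome$W_ll)
    }
    stable <- if (stability == "strict") {
      ep_change[ep] == 0
    } else {
      ep_change[ep] < tol * ep_total[ep]
    }
    if (stable && is.na(stability_epoch)) {
      stability_epoch <- ep
      if (stop_at_stability) {
        ep_change <- ep_change[seq_len(ep)]
        ep_total <- ep_total[seq_len(ep)]
        break
      }
    }
  }
  structure(
    list(connectome = connectome,
         epoch = tibble::tibble(epoch = seq_along(ep_change),
                                abs_change = ep_change, total_w = ep_total),
         snapshots = snapshots, stability_epoch = stability_epoch,
         params = params, spec = spec, seed = seed, criterion = stability,
         tol = tol),
    class = "stdp_history")
}

#' @export
print.stdp_history <- function(x, ...) {
  cat("<stdp_history>", nrow(x$epoch), "epochs; stability epoch:",
      x$stability_epoch, sprintf("(%s criterion)\n", x$criterion))
  invisible(x)
}

#' LN input-ratio tuning from afferent weights
#'
#' Each LN's ORN weight pair, normalized to the unit simplex segment
#' `w1 + w2 = 1`; the preferred input ratio is `w1 / w2`. After STDP
#' training the tunings spread to cover the space of trained input ratios.
#'
#' @param connectome An [build_mgc()] result (possibly trained).
#' @return A tibble: `ln`, `w1`, `w2`, `w1_norm`, `w2_norm`,
#'   `preferred_ratio`, `angle_deg` (direction in ORN weight space),
#'   `untuned` (both weights zero).
#' @export
ln_tuning <- function(connectome) {
  stopifnot(inherits(connectome, "mgc_connectome"))
  w <- connectome$W_ol
  tot <- rowSums(w)
  tibble::tibble(
    ln = seq_len(nrow(w)), w1 = w[, 1], w2 = w[, 2],
    w1_norm = ifelse(tot > 0, w[, 1] / tot, NA_real_),
    w2_norm = ifelse(tot > 0, w[, 2] / tot, NA_real_),
    preferred_ratio = ifelse(w[, 2] > 0, w[, 1] / w[, 2], Inf),
    angle_deg = atan2(w[, 2], w[, 1]) * 180 / pi,
    untuned = tot == 0)
}

#' Mean pairwise correlation of LN rate traces
#'
#' Smooths every LN spike train on a probe episode and returns the mean
#' pairwise Pearson correlation among the active (non-silent) LNs. After
#' STDP training the afferent weights are both reduced and spread, so the
#' probe amplitude should sit above the training range to recruit the
#' adapted layer; symmetry breaking then shows up as reduced correlation.
#'
#' @param connectome An [build_mgc()] result.
#' @param episode Probe `stimulus_episode` (default: a suprathreshold 1:2
#'   square pulse at three times the training amplitude scale).
#' @param seed Seed for input noise.
#' @return Mean pairwise correlation, or `NA` if fewer than two LNs are
#'   active.
#' @export
ln_rate_correlation <- function(connectome,
                                episode = square_ratio_episode(c(2, 4)),
                                seed = 1) {
  sim <- simulate_mgc(connectome, episode, seed = seed)
  r <- estimate_rates(sim, "ln")
  live <- apply(r, 2, stats::sd) > 0
  if (sum(live) < 2) return(NA_real_)
  cc <- stats::cor(r[, live])
  mean(cc[upper.tri(cc)])
}
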