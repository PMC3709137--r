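# shared small fixtures; everything is generated in code

tiny_config <- function(regime = "lca", ...) {
  mgc_config(regime = regime, ...)
}

tiny_sawr_spec <- function(...) {
  sawr_spec(trials_per_class = 4, t_total_s = 60, t_on_s = 5, t_vent_s = 45,
            ...)
}

# brute-force reference for the affine LIF recursion fixed point
lif_fixed_point_brute <- function(current, params, n = 1e5) {
  a <- 1 - params$delta / params$tau_m_corrected
  g <- params$delta / params$c_m
  v <- 0
  for (k in seq_len(n)) v <- v * a + g * current
  v
}

# closed-form single-spike EPSC trace (exact-integration kernel)
epsc_closed_form <- function(bw, tau, delta, n_steps, spike_step = 0) {
  k <- seq_len(n_steps) - 1
  out <- numeric(n_steps)
  idx <- k >= spike_step
  out[idx] <- bw * exp(-(k[idx] - spike_step) * delta / tau)
  out
}

new_episode_for_test <- function(currents, delta = 1) {
  seg <- tibble::tibble(segment = 1L, amp1 = NA_real_, amp2 = NA_real_,
                        label = "test", start_step = 0L,
                        end_step = nrow(currents) - 1L)
  ratiolobe:::new_stimulus_episode(currents, seg, delta)
}

# normalized afferent weight pair of one LN via the tuning operation
ln_tuning_pair <- function(w1, w2) {
  net <- build_mgc(mgc_config("lca"), seed = 1)
  net$W_ol[1, ] <- c(w1, w2)
  tun <- ln_tuning(net)
  c(tun$w1_norm[1], tun$w2_norm[1])
}

# pure-R network simulation with STDP, mirroring the engine's update order:
# pathway currents decay and inject spikes from the previous step, somata
# update via lif_step, then apply_stdp_step with the current step's spikes.
reference_sim_stdp <- function(net, input, p) {
  cfg <- net$config
  n_orn <- cfg$n_orn
  n_ln <- cfg$n_ln
  n_pn <- cfg$n_glom * cfg$n_pn_per_glom
  b <- cfg$b
  a_e <- synapse_params(cfg$tau_e, delta = cfg$delta)$decay
  a_i <- synapse_params(cfg$tau_i, delta = cfg$delta)$decay
  p_orn <- lif_params(cfg$tau_m_orn, cfg$c_m, cfg$v_theta, cfg$v_ahp,
                      cfg$delta)
  p_ln <- lif_params(cfg$tau_m_ln, cfg$c_m, cfg$v_theta, cfg$v_ahp,
                     cfg$delta)
  p_pn <- lif_params(cfg$tau_m_pn, cfg$c_m, cfg$v_theta, cfg$v_ahp,
                     cfg$delta)
  st <- list(orn = replicate(n_orn, lif_state(), simplify = FALSE),
             ln = replicate(n_ln, lif_state(), simplify = FALSE),
             pn = replicate(n_pn, lif_state(), simplify = FALSE))
  I_ol <- I_ll <- numeric(n_ln)
  I_op <- I_lp <- I_pp <- numeric(n_pn)
  mem <- stdp_memory(net)
  prev <- list(orn = integer(), ln = integer(), pn = integer())
  rec_n <- integer()
  rec_k <- integer()
  for (k in 0:(nrow(input) - 1)) {
    I_ol <- I_ol * a_e; I_ll <- I_ll * a_i
    I_op <- I_op * a_e; I_lp <- I_lp * a_i; I_pp <- I_pp * a_e
    for (j in prev$orn) {
      I_ol <- I_ol + b[1] * net$W_ol[, j]
      I_op <- I_op + b[2] * net$W_op[, j]
    }
    for (j in prev$ln) {
      I_ll <- I_ll + b[3] * net$W_ll[, j]
      I_lp <- I_lp + b[4] * net$W_lp[, j]
    }
    for (j in prev$pn) I_pp <- I_pp + b[5] * net$W_pp[, j]
    sp <- list(orn = integer(), ln = integer(), pn = integer())
    for (j in seq_len(n_orn)) {
      st$orn[[j]] <- lif_step(st$orn[[j]], p_orn, input[k + 1, j])
      if (st$orn[[j]]$spiked) sp$orn <- c(sp$orn, j)
    }
    for (i in seq_len(n_ln)) {
      st$ln[[i]] <- lif_step(st$ln[[i]], p_ln, I_ol[i] + I_ll[i])
      if (st$ln[[i]]$spiked) sp$ln <- c(sp$ln, i)
    }
    for (i in seq_len(n_pn)) {
      st$pn[[i]] <- lif_step(st$pn[[i]], p_pn, I_op[i] + I_lp[i] + I_pp[i])
      if (st$pn[[i]]$spiked) sp$pn <- c(sp$pn, i)
    }
    upd <- apply_stdp_step(net, list(orn = sp$orn, ln = sp$ln), p, mem, k)
    net <- upd$connectome
    mem <- upd$memory
    rec_n <- c(rec_n, sp$orn, n_orn + sp$ln, n_orn + n_ln + sp$pn)
    rec_k <- c(rec_k, rep(k, length(sp$orn) + length(sp$ln) + length(sp$pn)))
    prev <- sp
  }
  list(W_ol = net$W_ol, W_ll = net$W_ll,
       spikes = tibble::tibble(neuron = rec_n, step = rec_k))
}
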