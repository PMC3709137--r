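#' MGC network configuration
#'
#' Describes one macroglomerular-complex instance: 2 ORN input channels, 2
#' glomeruli of 15 PNs each, and a population of 30 LNs. Every LN receives
#' excitation from both ORNs; the PNs of a glomerulus are driven only by
#' their own ORN. LNs inhibit each other and PNs of any glomerulus; PNs of
#' the same glomerulus excite each other. The LN-LN connection probability
#' selects the dynamical regime: sparse asymmetric inhibition
#' (`p_ln_ln = 0.25`, `"lca"`) yields limit-cycle / winnerless-competition
#' dynamics, all-to-all symmetric inhibition (`p_ln_ln = 1`, `"fpa"`) a
#' winner-takes-all fixed point.
#'
#' Weight ranges for the afferent LN pathway (1000-3000) and the mutual LN
#' pathway (100-400) follow the hardware initialization; the remaining
#' pathways are not constrained by anatomy and default to the same
#' magnitudes, scaled into soma drive by the per-pathway current constants
#' `b` (order: ORN->LN, ORN->PN, LN->LN, LN->PN, PN->PN).
#'
#' @param regime `"lca"` or `"fpa"`; sets `p_ln_ln` and weight symmetry
#'   unless overridden.
#' @param n_orn,n_glom,n_pn_per_glom,n_ln Population sizes.
#' @param p_ln_ln,p_ln_pn,p_pn_pn Connection probabilities.
#' @param w_orn_ln,w_orn_pn,w_ln_ln,w_ln_pn,w_pn_pn Uniform init ranges for
#'   weight magnitudes, `c(lo, hi)`.
#' @param symmetric_ll All LN-LN weights equal to the midpoint of `w_ln_ln`
#'   (the symmetric configuration of the FPA regime).
#' @param tau_m_orn,tau_m_pn,tau_m_ln Membrane time constants (ms).
#' @param tau_e,tau_i Excitatory / inhibitory synaptic decay constants (ms).
#' @param v_theta,v_ahp,c_m LIF threshold, reset, capacitance.
#' @param delta Step duration (ms).
#' @param b Length-5 vector of current-pulse scale constants per pathway.
#' @param noise_sigma Gaussian input-noise s.d. added to the ORN drive each
#'   step (current units; default 5% of the unit-amplitude pulse current).
#' @return A list of class `mgc_config`.
#' @export
mgc_config <- function(regime = c("lca", "fpa"),
                       n_orn = 2, n_glom = 2, n_pn_per_glom = 15, n_ln = 30,
                       p_ln_ln = NULL, p_ln_pn = 0.5, p_pn_pn = 0.5,
                       w_orn_ln = c(1000, 3000), w_orn_pn = c(1000, 3000),
                       w_ln_ln = c(100, 400), w_ln_pn = c(100, 400),
                       w_pn_pn = c(100, 400),
                       symmetric_ll = NULL,
                       tau_m_orn = 10, tau_m_pn = 10, tau_m_ln = 20,
                       tau_e = 5, tau_i = 10,
                       v_theta = 1, v_ahp = 0, c_m = 1, delta = 1,
                       b = c(4e-5, 1e-4, 8e-4, 1e-4, 4e-5),
                       noise_sigma = 0.0125) {
  regime <- match.arg(regime)
  if (is.null(p_ln_ln)) p_ln_ln <- if (regime == "fpa") 1 else 0.25
  if (is.null(symmetric_ll)) symmetric_ll <- regime == "fpa"
  probs <- c(p_ln_ln = p_ln_ln, p_ln_pn = p_ln_pn, p_pn_pn = p_pn_pn)
  if (any(probs < 0 | probs > 1)) {
    stop("connection probabilities must lie in [0, 1]: ",
         paste(names(probs)[probs < 0 | probs > 1], collapse = ", "),
         call. = FALSE)
  }
  counts <- c(n_orn = n_orn, n_glom = n_glom,
              n_pn_per_glom = n_pn_per_glom, n_ln = n_ln)
  if (any(counts < 1)) stop("population counts must be positive", call. = FALSE)
  if (n_orn != n_glom) stop("one ORN type per glomerulus is required", call. = FALSE)
  if (length(b) != 5) stop("`b` must have 5 pathway entries", call. = FALSE)
  structure(
    list(regime = regime, n_orn = n_orn, n_glom = n_glom,
         n_pn_per_glom = n_pn_per_glom, n_ln = n_ln,
         p_ln_ln = p_ln_ln, p_ln_pn = p_ln_pn, p_pn_pn = p_pn_pn,
         w_orn_ln = w_orn_ln, w_orn_pn = w_orn_pn, w_ln_ln = w_ln_ln,
         w_ln_pn = w_ln_pn, w_pn_pn = w_pn_pn, symmetric_ll = symmetric_ll,
         tau_m_orn = tau_m_orn, tau_m_pn = tau_m_pn, tau_m_ln = tau_m_ln,
         tau_e = tau_e, tau_i = tau_i, v_theta = v_theta, v_ahp = v_ahp,
         c_m = c_m, delta = delta, b = b, noise_sigma = noise_sigma),
    class = "mgc_config")
}

#' Sensor-matched MGC configuration
#'
#' The chemosensor-driven ORNs run at 0-50 Hz (the calibrated in-vivo
#' ceiling), an order of magnitude below the synthetic pulse-train rates the
#' default gains are scaled for. This constructor rescales the per-pathway
#' current constants so that the mean synaptic drive at sensor input rates
#' matches the drive the default configuration receives at pulse-train
#' rates (mean drive per pathway is `b * w * f * tau_syn / 1000`, so `b`
#' scales inversely with the presynaptic rate ratio): the dynamic-range
#' matching between the peripheral chemosensor and the neuronal core.
#'
#' @param regime Dynamical regime, as in [mgc_config()].
#' @param ... Further overrides passed to [mgc_config()].
#' @return An `mgc_config`.
#' @export
sensor_mgc_config <- function(regime = "lca", ...) {
  mgc_config(regime = regime,
             b = c(4e-4, 5e-4, 8e-4, 1e-4, 2e-4), ...)
}

#' Build a probabilistic MGC connectome
#'
#' Draws every candidate directed edge independently with its pathway
#' probability and every weight magnitude uniformly from its pathway range;
#' deterministic given `seed`. Inhibitory pathways (LN->LN, LN->PN) are
#' stored with negative sign; there are no self-connections and no
#' cross-glomerular ORN->PN or PN->PN edges.
#'
#' @param config An [mgc_config()].
#' @param seed Integer seed.
#' @return A list of class `mgc_connectome` holding the five pathway weight
#'   matrices (`W_ol`, `W_op`, `W_ll`, `W_lp`, `W_pp`, rows = targets), the
#'   LN-LN adjacency `A_ll`, a `neurons` tibble and the provenance seed.
#' @export
build_mgc <- function(config = mgc_config(), seed = 1) {
  stopifnot(inherits(config, "mgc_config"))
  set.seed(seed)
  n_ln <- config$n_ln
  n_orn <- config$n_orn
  n_pn <- config$n_glom * config$n_pn_per_glom
  glom <- rep(seq_len(config$n_glom), each = config$n_pn_per_glom)

  runif_mat <- function(n, m, range) {
    matrix(stats::runif(n * m, range[1], range[2]), n, m)
  }

  # ORN -> LN: all-to-all excitatory (both ORNs innervate every LN)
  W_ol <- runif_mat(n_ln, n_orn, config$w_orn_ln)
  # ORN -> PN: glomerulus-specific excitatory drive
  W_op <- matrix(0, n_pn, n_orn)
  for (g in seq_len(config$n_glom)) {
    W_op[glom == g, g] <- stats::runif(config$n_pn_per_glom,
                                       config$w_orn_pn[1], config$w_orn_pn[2])
  }
  # LN -> LN: probabilistic inhibition, no self-loops
  A_ll <- matrix(stats::runif(n_ln^2) < config$p_ln_ln, n_ln, n_ln)
  diag(A_ll) <- FALSE
  W_ll <- if (config$symmetric_ll) {
    -mean(config$w_ln_ln) * A_ll
  } else {
    -runif_mat(n_ln, n_ln, config$w_ln_ln) * A_ll
  }
  # LN -> PN: probabilistic inhibition onto either glomerulus
  A_lp <- matrix(stats::runif(n_pn * n_ln) < config$p_ln_pn, n_pn, n_ln)
  W_lp <- -runif_mat(n_pn, n_ln, config$w_ln_pn) * A_lp
  # PN -> PN: within-glomerulus excitation, no self-loops
  A_pp <- matrix(stats::runif(n_pn^2) < config$p_pn_pn, n_pn, n_pn) &
    outer(glom, glom, "==")
  diag(A_pp) <- FALSE
  W_pp <- runif_mat(n_pn, n_pn, config$w_pn_pn) * A_pp

  neurons <- tibble::tibble(
    neuron = seq_len(n_orn + n_ln + n_pn),
    population = rep(c("orn", "ln", "pn"), c(n_orn, n_ln, n_pn)),
    cell = c(seq_len(n_orn), seq_len(n_ln), seq_len(n_pn)),
    glomerulus = c(seq_len(n_orn), rep(NA_integer_, n_ln), glom))

  structure(
    list(config = config, seed = seed,
         W_ol = W_ol, W_op = W_op, W_ll = W_ll, W_lp = W_lp, W_pp = W_pp,
         A_ll = A_ll, neurons = neurons),
    class = "mgc_connectome")
}

#' @export
print.mgc_connectome <- function(x, ...) {
  cfg <- x$config
  cat("<mgc_connectome> regime:", cfg$regime, " seed:", x$seed, "\n")
  cat(sprintf("  %d ORNs, %d LNs, %d glomeruli x %d PNs\n",
              cfg$n_orn, cfg$n_ln, cfg$n_glom, cfg$n_pn_per_glom))
  cat(sprintf("  LN-LN edges: %d (p = %.2f%s)\n", sum(x$A_ll), cfg$p_ln_ln,
              if (cfg$symmetric_ll) ", symmetric" else ""))
  invisible(x)
}

#' Simulate an MGC connectome on a stimulus episode
#'
#' Synchronous per-step update: all synapses advance first (injecting pulses
#' from the previous step's spikes), then all somata. ORN somata are driven
#' by the episode currents plus seeded Gaussian noise; LN and PN somata by
#' their summed synaptic currents.
#'
#' @param connectome An [build_mgc()] result.
#' @param episode A `stimulus_episode` (see [make_ratio_pulse_train()]).
#' @param noise_sigma Override of the config input-noise s.d.
#' @param record_v Also record membrane traces.
#' @param seed Optional seed for the input noise.
#' @return A list of class `mgc_sim` with a `spikes` tibble (`neuron`,
#'   `population`, `cell`, `step`, `time_ms`; 0-based steps), the grid and
#'   provenance. With identically zero input the raster is empty: the model
#'   has no spontaneous activity.
#' @export
simulate_mgc <- function(connectome, episode, noise_sigma = NULL,
                         record_v = FALSE, seed = NULL) {
  stopifnot(inherits(connectome, "mgc_connectome"))
  cfg <- connectome$config
  if (ncol(episode$currents) != cfg$n_orn) {
    stop("episode has ", ncol(episode$currents),
         " input channels but the connectome expects ", cfg$n_orn,
         call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  if (is.null(noise_sigma)) noise_sigma <- cfg$noise_sigma
  res <- mgc_sim_core(
    connectome$W_ol, connectome$W_op, connectome$W_ll, connectome$W_lp,
    connectome$W_pp, connectome$A_ll, episode$currents, cfg$delta,
    cfg$tau_m_orn, cfg$tau_m_ln, cfg$tau_m_pn, cfg$tau_e, cfg$tau_i,
    cfg$v_theta, cfg$v_ahp, cfg$c_m, cfg$b, noise_sigma,
    FALSE, 0, 0, 20, 20, 0, 0, record_v)
  new_mgc_sim(res, connectome, episode, record_v)
}

new_mgc_sim <- function(res, connectome, episode, record_v) {
  cfg <- connectome$config
  neurons <- connectome$neurons
  spikes <- tibble::tibble(neuron = res$neuron + 1L, step = res$step) |>
    dplyr::left_join(neurons, by = "neuron") |>
    dplyr::mutate(time_ms = .data$step * cfg$delta) |>
    dplyr::select("neuron", "population", "cell", "glomerulus",
                  "step", "time_ms") |>
    dplyr::arrange(.data$step, .data$neuron)
  out <- list(spikes = spikes, n_steps = nrow(episode$currents),
              delta = cfg$delta, neurons = neurons,
              config = cfg, episode_segments = episode$segments)
  if (record_v) out$v <- res$v
  structure(out, class = "mgc_sim")
}

#' @export
print.mgc_sim <- function(x, ...) {
  cat("<mgc_sim>", x$n_steps, "steps x", nrow(x$neurons), "neurons,",
      nrow(x$spikes), "spikes\n")
  invisible(x)
}

#' Winner dominance statistics of the LN population
#'
#' Smooths each LN spike train with the discrete Gaussian kernel
#' (`d = tau_m_ln / delta`), finds the dominant (maximal-rate) LN in
#' consecutive windows, and counts winner changes after a settling period.
#' Fixed-point-attractor dynamics yield a single sustained winner (0
#' switches); limit-cycle dynamics yield winnerless competition with
#' recurring switches.
#'
#' @param sim An [simulate_mgc()] result.
#' @param window Window length (ms).
#' @param settle Initial period (ms) excluded from the switch count.
#' @param stimulus_only Count switches only in windows inside the labeled
#'   stimulation period (dominance is defined while the stimulus is
#'   maintained; the offset decay is excluded).
#' @return A list of class `regime_summary`: `windows` tibble (window start,
#'   winner, peak rate), `switch_count` (NA with an `no_activity` flag when
#'   the LN raster is empty).
#' @export
regime_statistics <- function(sim, window = 50, settle = 200,
                              stimulus_only = TRUE) {
  stopifnot(inherits(sim, "mgc_sim"))
  if (window <= 0) stop("`window` must be positive", call. = FALSE)
  ln_spikes <- dplyr::filter(sim$spikes, .data$population == "ln")
  if (nrow(ln_spikes) == 0) {
    return(structure(list(windows = tibble::tibble(), switch_count = NA_integer_,
                          no_activity = TRUE), class = "regime_summary"))
  }
  n_ln <- sim$config$n_ln
  rates <- rates_from_spikes(ln_spikes$cell, ln_spikes$step, n_ln,
                             sim$n_steps, d = sim$config$tau_m_ln / sim$delta,
                             delta = sim$delta)
  wsteps <- max(1L, round(window / sim$delta))
  starts <- seq(1L, sim$n_steps, by = wsteps)
  win <- purrr::map_dfr(starts, function(s) {
    e <- min(s + wsteps - 1L, sim$n_steps)
    m <- colMeans(rates[s:e, , drop = FALSE])
    tibble::tibble(t_start = (s - 1) * sim$delta,
                   winner = if (max(m) > 0) which.max(m) else NA_integer_,
                   rate = max(m))
  })
  t_max <- Inf
  if (stimulus_only && !is.null(sim$episode_segments)) {
    seg <- sim$episode_segments
    on <- if (all(is.na(seg$amp1))) rep(TRUE, nrow(seg)) else
      (seg$amp1 + seg$amp2) > 0
    if (any(on)) t_max <- max(seg$end_step[on]) * sim$delta - window
  }
  act <- win[!is.na(win$winner) & win$t_start >= settle &
               win$t_start <= t_max, ]
  switches <- if (nrow(act) > 1) sum(diff(act$winner) != 0) else 0L
  structure(list(windows = win, switch_count = as.integer(switches),
                 no_activity = FALSE),
            class = "regime_summary")
}

#' @export
print.regime_summary <- function(x, ...) {
  if (isTRUE(x$no_activity)) {
    cat("<regime_summary> no LN activity; switch count undefined\n")
  } else {
    cat("<regime_summary>", x$switch_count, "winner switches over",
        nrow(x$windows), "windows\n")
  }
  invisible(x)
}
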