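#' Single square ratio pulse episode
#'
#' The stimulation protocol of the regime comparison: a square two-channel
#' pulse with amplitudes `amp` (concentration units, scaled by
#' `drive_gain`), on from `t_on` to `t_off` within an episode of `t_total`
#' ms.
#'
#' @param amp Length-2 amplitudes (ORN1, ORN2).
#' @param t_on,t_off,t_total Pulse timing (ms); defaults 100-600 ms within
#'   700 ms.
#' @param drive_gain Current per unit amplitude.
#' @param delta Step (ms).
#' @return A `stimulus_episode`.
#' @export
square_ratio_episode <- function(amp = c(1, 2), t_on = 100, t_off = 600,
                                 t_total = 700, drive_gain = 0.25,
                                 delta = 1) {
  n <- round(t_total / delta)
  k_on <- round(t_on / delta) + 1L
  k_off <- round(t_off / delta)
  cur <- matrix(0, n, 2)
  cur[k_on:k_off, ] <- matrix(amp * drive_gain, k_off - k_on + 1L, 2,
                              byrow = TRUE)
  seg <- tibble::tibble(segment = 1L, amp1 = amp[1], amp2 = amp[2],
                        label = paste(amp, collapse = ":"),
                        start_step = k_on - 1L, end_step = k_off - 1L)
  new_stimulus_episode(cur, seg, delta)
}

#' Regime-comparison pipeline
#'
#' Simulates the same ratio pulse on an FPA (all-to-all symmetric LN
#' inhibition) and an LCA (sparse asymmetric) connectome and summarizes LN
#' winner dominance in each.
#'
#' @param seed Integer seed.
#' @param amp Ratio pulse amplitudes.
#' @param window,settle Dominance window and settling period (ms; see
#'   [regime_statistics()]).
#' @param out_dir Optional output directory for rasters (CSV) and the
#'   metrics report (JSON).
#' @return A list: `report` tibble (one row per regime with spike counts and
#'   winner-switch counts), `sims`, `stats`.
#' @export
run_regimes <- function(seed = 1, amp = c(1, 2), window = 50, settle = 200,
                        out_dir = NULL) {
  episode <- square_ratio_episode(amp)
  regimes <- c("fpa", "lca")
  sims <- purrr::map(regimes, function(rg) {
    net <- build_mgc(mgc_config(regime = rg), seed = derive_seed(seed, 1))
    simulate_mgc(net, episode, seed = derive_seed(seed, 2))
  })
  names(sims) <- regimes
  stats <- purrr::map(sims, regime_statistics, window = window,
                      settle = settle)
  report <- tibble::tibble(
    regime = regimes,
    n_spikes = purrr::map_int(sims, ~ nrow(.x$spikes)),
    n_pn_spikes = purrr::map_int(
      sims, ~ sum(.x$spikes$population == "pn")),
    winner_switches = purrr::map_int(stats, "switch_count"))
  if (!is.null(out_dir)) {
    ensure_dir(out_dir)
    for (rg in regimes) {
      utils::write.csv(
        data.frame(neuron_id = sims[[rg]]$spikes$neuron - 1L,
                   spike_step = sims[[rg]]$spikes$step),
        file.path(out_dir, paste0("raster_", rg, ".csv")),
        row.names = FALSE)
    }
    jsonlite::write_json(report, file.path(out_dir, "regimes_report.json"),
                         dataframe = "rows", auto_unbox = TRUE, digits = NA)
  }
  list(report = report, sims = sims, stats = stats)
}

#' STDP training pipeline
#'
#' Trains an LCA connectome on the randomized ratio sequence and quantifies
#' what learning changed: the stability epoch, the LN ratio-tuning spread,
#' the PCA compactness of the PN trajectories for the probe ratios 1:3, 1:1
#' and 3:1, and the mean inter-class template separation before vs after
#' training.
#'
#' @param seed Integer seed.
#' @param epochs Training epochs.
#' @param trials_per_ratio Probe trials per ratio.
#' @param spec A [ratio_train_spec()].
#' @param out_dir Optional output directory.
#' @param ... Passed to [train_stdp()].
#' @return A list: `report` (metrics list), `history`, `tuning`, `pca_post`,
#'   and the pre/post trajectory sets.
#' @export
run_stdp_training <- function(seed = 1, epochs = 300, trials_per_ratio = 6,
                              spec = ratio_train_spec(), out_dir = NULL,
                              ...) {
  net0 <- build_mgc(mgc_config(regime = "lca"), seed = derive_seed(seed, 1))
  probe <- probe_episodes(spec, trials_per_ratio, seed = derive_seed(seed, 2))
  pre <- model_trajectories(net0, probe$episodes, probe$labels,
                            seed = derive_seed(seed, 3))
  history <- train_stdp(net0, spec, epochs = epochs,
                        seed = derive_seed(seed, 4), ...)
  post <- model_trajectories(history$connectome, probe$episodes,
                             probe$labels, seed = derive_seed(seed, 3))
  pca_post <- project_pca(post, 3)
  tuning <- ln_tuning(history$connectome)
  report <- list(
    epochs = nrow(history$epoch),
    stability_epoch = history$stability_epoch,
    pca_top3_variance_pct = 100 * pca_post$cum_var,
    separation_pre = template_separation(pre),
    separation_post = template_separation(post),
    tuning_cv_pre = tuning_spread(ln_tuning(net0)),
    tuning_cv_post = tuning_spread(tuning),
    ln_correlation_pre = ln_rate_correlation(net0, seed = derive_seed(seed, 5)),
    ln_correlation_post = ln_rate_correlation(history$connectome,
                                              seed = derive_seed(seed, 5)))
  if (!is.null(out_dir)) {
    ensure_dir(out_dir)
    utils::write.csv(history$epoch, file.path(out_dir, "stdp_epochs.csv"),
                     row.names = FALSE)
    utils::write.csv(tuning, file.path(out_dir, "ln_tuning.csv"),
                     row.names = FALSE)
    jsonlite::write_json(report, file.path(out_dir, "stdp_report.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  list(report = report, history = history, tuning = tuning,
       pca_post = pca_post, pre = pre, post = post)
}

# probe episodes at ratios 1:3, 1:1, 3:1 drawn from the training amplitudes
probe_episodes <- function(spec, trials_per_ratio, seed) {
  pairs <- list(`1:3` = c(0.5, 1.5), `1:1` = c(1, 1), `3:1` = c(1.5, 0.5))
  eps <- list(); labs <- character()
  i <- 0L
  for (lab in names(pairs)) {
    for (tr in seq_len(trials_per_ratio)) {
      i <- i + 1L
      eps[[i]] <- ratio_probe_episode(pairs[[lab]], spec,
                                      seed = derive_seed(seed, i))
      labs[i] <- lab
    }
  }
  list(episodes = eps, labels = labs)
}

# one RC-filtered noisy pulse at a fixed amplitude pair
ratio_probe_episode <- function(amp, spec, seed) {
  set.seed(seed)
  seg_steps <- round((spec$pulse_ms + spec$gap_ms) / spec$delta)
  pulse_steps <- round(spec$pulse_ms / spec$delta)
  square <- matrix(0, seg_steps, 2)
  square[seq_len(pulse_steps), ] <- matrix(amp * spec$drive_gain,
                                           pulse_steps, 2, byrow = TRUE)
  cur <- apply(square, 2, rc_filter, tau = spec$rc_tau_ms, delta = spec$delta)
  cur <- cur + matrix(stats::rnorm(length(cur), 0, spec$noise_sigma),
                      nrow(cur))
  seg <- tibble::tibble(segment = 1L, amp1 = amp[1], amp2 = amp[2],
                        label = paste(amp, collapse = ":"),
                        start_step = 0L, end_step = pulse_steps - 1L)
  new_stimulus_episode(cur, seg, spec$delta, seed)
}

# mean pairwise Eq.-10-style distance between class templates (full length)
template_separation <- function(tset) {
  tm <- class_templates(tset)
  labs <- names(tm)
  if (length(labs) < 2) return(NA_real_)
  prs <- utils::combn(labs, 2)
  mean(apply(prs, 2, function(p)
    trajectory_distance(tm[[p[1]]]$mean, tm[[p[2]]]$mean,
                        T_ms = tset$n_steps * tset$delta, delta = tset$delta)))
}

# coefficient of variation of LN preferred-ratio angles
tuning_spread <- function(tuning) {
  a <- tuning$angle_deg[!tuning$untuned]
  stats::sd(a) / mean(a)
}

#' Ratiometric chemosensor pipeline
#'
#' End-to-end decoding of the synthetic SAWR dataset: generate traces,
#' calibrate `beta`, select the best of a pool of LCA connectomes by greedy
#' scoring, and compare the classification-over-time curve of the model's PN
#' trajectories against the normalized raw-sensor baseline.
#'
#' @param seed Integer seed.
#' @param spec A [sawr_spec()].
#' @param pool Size of the connectome candidate pool.
#' @param times_s Decision times (sensor seconds).
#' @param compression Model ms per sensor second.
#' @param out_dir Optional output directory.
#' @return A list: `report` (times above chance, mean accuracies, beta),
#'   `curve_model`, `curve_sensor`, `selection`, `beta`.
#' @export
run_ratiometric <- function(seed = 1, spec = sawr_spec(), pool = 8,
                            times_s = seq(15, 145, by = 10),
                            compression = 10, out_dir = NULL) {
  traces <- make_synthetic_sawr(spec, seed = derive_seed(seed, 1))
  beta <- calibrate_beta(traces)
  se <- sensor_episodes(traces, beta, compression = compression)
  times_ms <- times_s * compression

  candidates <- purrr::map(seq_len(pool), function(i)
    build_mgc(sensor_mgc_config("lca"), seed = derive_seed(seed, 100 + i)))
  sel <- greedy_select(candidates, se$episodes, se$labels, times = times_ms,
                       seed = derive_seed(seed, 5))

  tset_model <- model_trajectories(sel$best, se$episodes, se$labels,
                                   seed = derive_seed(seed, 6))
  curve_model <- classification_curve(tset_model, times_ms)
  tset_sensor <- sensor_trajectories(traces, beta, compression = compression)
  curve_sensor <- classification_curve(tset_sensor, times_ms,
                                       normalize = TRUE)
  report <- list(
    beta = beta$beta,
    chance = attr(curve_model, "chance"),
    mean_p_model = mean(curve_model$p_correct),
    mean_p_sensor = mean(curve_sensor$p_correct),
    t_above_chance_model_s = time_above_chance(curve_model) / compression,
    t_above_chance_sensor_s = time_above_chance(curve_sensor) / compression)
  if (!is.null(out_dir)) {
    ensure_dir(out_dir)
    utils::write.csv(
      dplyr::bind_rows(model = curve_model, sensor = curve_sensor,
                       .id = "input"),
      file.path(out_dir, "decision_curves.csv"), row.names = FALSE)
    jsonlite::write_json(report, file.path(out_dir, "ratiometric_report.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  list(report = report, curve_model = curve_model,
       curve_sensor = curve_sensor, selection = sel, beta = beta,
       tset_model = tset_model, tset_sensor = tset_sensor)
}

ensure_dir <- function(path) {
  if (!dir.exists(path)) dir.create(path, recursive = TRUE)
  invisible(path)
}

#' Run a named pipeline from a configuration
#'
#' Configuration-driven entry point: a YAML file or list with a `pipeline`
#' field (`"regimes"`, `"stdp-train"` or `"ratiometric"`), a global `seed`,
#' an optional `out_dir`, and a `params` block passed to the pipeline
#' function. Unknown top-level or parameter keys are rejected with the
#' offending field path. Identical configuration and seed reproduce the
#' identical report.
#'
#' @param config Path to a YAML file, or a list.
#' @return The pipeline's result list.
#' @export
run_experiment <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  known <- c("pipeline", "seed", "out_dir", "params")
  extra <- setdiff(names(config), known)
  if (length(extra)) {
    stop("unknown config field(s): ", paste(extra, collapse = ", "),
         call. = FALSE)
  }
  if (is.null(config$pipeline)) stop("config$pipeline is required", call. = FALSE)
  fun <- switch(config$pipeline,
                regimes = run_regimes,
                `stdp-train` = run_stdp_training,
                ratiometric = run_ratiometric,
                stop("config$pipeline must be one of 'regimes', ",
                     "'stdp-train', 'ratiometric'", call. = FALSE))
  params <- config$params %||% list()
  allowed <- setdiff(names(formals(fun)), "...")
  bad <- setdiff(names(params), allowed)
  if (length(bad)) {
    stop("unknown config field(s): ",
         paste0("params.", bad, collapse = ", "), call. = FALSE)
  }
  args <- c(list(seed = config$seed %||% 1, out_dir = config$out_dir), params)
  do.call(fun, args)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
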