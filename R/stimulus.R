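#' Specification of the randomized ratio pulse-train training set
#'
#' One training epoch is a train of ten square pulses, one per
#' concentration-ratio pair ORN1:ORN2, presented in randomized order, each
#' low-pass filtered by a first-order RC response and perturbed by Gaussian
#' noise at every step. Amplitudes are in normalized concentration units and
#' are converted to ORN soma current by `drive_gain`.
#'
#' @param pulse_ms Pulse duration (ms).
#' @param gap_ms Inter-pulse interval (ms).
#' @param rc_tau_ms RC filter time constant (ms).
#' @param amplitude_pairs Two-column matrix of ORN1/ORN2 amplitudes; the
#'   default is the canonical ten-ratio set 0:0 ... 1.5:1.5.
#' @param drive_gain Soma current per unit amplitude. The default (0.25)
#'   places the three nonzero amplitudes at roughly 65/180/330 Hz ORN rates,
#'   comfortably inside the model's dynamic range.
#' @param noise_sigma Gaussian noise s.d. in current units (default 2% of
#'   the largest pulse current).
#' @param delta Step duration (ms).
#' @return A list of class `ratio_train_spec`.
#' @export
ratio_train_spec <- function(pulse_ms = 100, gap_ms = 100, rc_tau_ms = 10,
                             amplitude_pairs = NULL, drive_gain = 0.25,
                             noise_sigma = NULL, delta = 1) {
  if (pulse_ms <= 0 || gap_ms <= 0) {
    stop("pulse and gap durations must be positive", call. = FALSE)
  }
  if (is.null(amplitude_pairs)) {
    a <- c(0, 0.5, 1, 1.5)
    amplitude_pairs <- rbind(
      c(0, 0),
      as.matrix(expand.grid(a1 = a[-1], a2 = a[-1])))
    dimnames(amplitude_pairs) <- NULL
  }
  if (is.null(noise_sigma)) {
    noise_sigma <- 0.02 * max(amplitude_pairs) * drive_gain
  }
  structure(
    list(pulse_ms = pulse_ms, gap_ms = gap_ms, rc_tau_ms = rc_tau_ms,
         amplitude_pairs = amplitude_pairs, drive_gain = drive_gain,
         noise_sigma = noise_sigma, delta = delta),
    class = "ratio_train_spec")
}

rc_filter <- function(x, tau, delta) {
  # first-order low-pass with exact per-step decay; step response 1 - e^(-t/tau)
  a <- exp(-delta / tau)
  stats::filter(x * (1 - a), filter = a, method = "recursive", init = 0) |>
    as.numeric()
}

new_stimulus_episode <- function(currents, segments, delta, seed = NULL) {
  structure(list(currents = currents, segments = segments,
                 delta = delta, n_steps = nrow(currents), seed = seed),
            class = "stimulus_episode")
}

#' @export
print.stimulus_episode <- function(x, ...) {
  cat("<stimulus_episode>", x$n_steps, "steps x", ncol(x$currents),
      "channels,", nrow(x$segments), "labeled segments\n")
  invisible(x)
}

#' One epoch of the randomized ratio pulse train
#'
#' @param spec A [ratio_train_spec()].
#' @param seed Integer seed (pulse order and noise).
#' @param randomize Shuffle pulse order (the training protocol); `FALSE`
#'   presents the pairs in listed order.
#' @return A `stimulus_episode`: per-ORN current matrix on the model grid
#'   plus a `segments` tibble (one labeled segment per pulse, label
#'   `"a1:a2"`).
#' @export
make_ratio_pulse_train <- function(spec = ratio_train_spec(), seed = 1,
                                   randomize = TRUE) {
  stopifnot(inherits(spec, "ratio_train_spec"))
  set.seed(seed)
  n_pair <- nrow(spec$amplitude_pairs)
  ord <- if (randomize) sample.int(n_pair) else seq_len(n_pair)
  seg_steps <- round((spec$pulse_ms + spec$gap_ms) / spec$delta)
  pulse_steps <- round(spec$pulse_ms / spec$delta)
  n_steps <- n_pair * seg_steps

  square <- matrix(0, n_steps, 2)
  for (s in seq_len(n_pair)) {
    rows <- (s - 1) * seg_steps + seq_len(pulse_steps)
    square[rows, ] <- matrix(spec$amplitude_pairs[ord[s], ] * spec$drive_gain,
                             pulse_steps, 2, byrow = TRUE)
  }
  currents <- apply(square, 2, rc_filter, tau = spec$rc_tau_ms,
                    delta = spec$delta)
  if (spec$noise_sigma > 0) {
    currents <- currents + matrix(stats::rnorm(length(currents), 0,
                                               spec$noise_sigma),
                                  nrow(currents))
  }
  segments <- tibble::tibble(
    segment = seq_len(n_pair),
    amp1 = spec$amplitude_pairs[ord, 1], amp2 = spec$amplitude_pairs[ord, 2],
    label = paste(amp1, amp2, sep = ":"),
    start_step = (seq_len(n_pair) - 1L) * seg_steps,
    end_step = seq_len(n_pair) * seg_steps - 1L)
  new_stimulus_episode(currents, segments, spec$delta, seed)
}

#' Ratio classes of the binary-blend experiment
#'
#' Five volumetric ratio classes of the two fruit volatiles
#' (3-methylbutan-1-ol : ethyl acetate), constant total volume.
#'
#' @return A tibble with class id, ratio label and per-component volumes
#'   (microlitres).
#' @export
ratio_classes <- function() {
  tibble::tibble(
    class = paste0("R", 1:5),
    ratio = c("1:4", "1:2", "1:1", "2:1", "4:1"),
    vol1 = c(4, 6.7, 10, 13.3, 16),
    vol2 = c(16, 13.3, 10, 6.7, 4))
}

#' Specification of the synthetic dual-channel SAWR dataset
#'
#' Emulates the laboratory recordings: for each trial and ratio class, the
#' polymer-coated resonator of each channel pair loses resonant frequency
#' following a first-order rise toward a steady state proportional to that
#' channel's analyte volume (plus a small cross-sensitivity to the other
#' analyte), and relaxes first-order after venting; the uncoated reference
#' of the pair carries only the shared baseline drift and noise. Traces are
#' stored as deviations (Hz) from the carrier frequency. Per-trial
#' common-mode concentration jitter models delivery variability; it scales
#' both channels together and so preserves the ratio.
#'
#' The transient completes within roughly 50-80 s (first-order time
#' constants of 15 and 20 s per channel), with equilibrium reached by
#' about 100 s post-stimulus.
#'
#' @param classes Ratio-class table (see [ratio_classes()]).
#' @param trials_per_class Repeat trials per class.
#' @param tau_rise_s,tau_decay_s Length-2 rise/decay time constants (s) per
#'   channel.
#' @param tau_jitter_sd Lognormal s.d. of per-trial time-constant jitter.
#' @param amp_per_ul Steady-state coated-channel frequency shift per
#'   microlitre (Hz).
#' @param cross_sensitivity Fraction of the other analyte's volume sensed by
#'   a channel's polymer.
#' @param gain_jitter_sd Lognormal s.d. of the per-trial common-mode
#'   concentration factor.
#' @param drift_sd S.d. of the per-trial linear baseline drift slope (Hz/s),
#'   common to the coated and uncoated device of a pair (cancelled exactly by
#'   the differential).
#' @param diff_drift_sd Step s.d. (Hz per sample) of the residual random-walk
#'   drift on the coated device that the reference does not track: the
#'   differential reduces ambient interference but does not eliminate it.
#' @param noise_sigma Per-sample white frequency noise s.d. (Hz) on each
#'   device.
#' @param t_total_s,t_on_s,t_vent_s Episode length, stimulus onset and
#'   venting time (s).
#' @param dt_s Sensor sampling interval (s).
#' @return A list of class `sawr_spec`.
#' @export
sawr_spec <- function(classes = ratio_classes(), trials_per_class = 10,
                      tau_rise_s = c(15, 20), tau_decay_s = c(15, 20),
                      tau_jitter_sd = 0.05, amp_per_ul = 100,
                      cross_sensitivity = 0.1, gain_jitter_sd = 0.05,
                      drift_sd = 0.5, diff_drift_sd = 8, noise_sigma = 50,
                      t_total_s = 150, t_on_s = 10, t_vent_s = 110,
                      dt_s = 1) {
  if (any(c(tau_rise_s, tau_decay_s) <= 0)) {
    stop("time constants must be positive", call. = FALSE)
  }
  if (nrow(classes) < 2) stop("need at least two ratio classes", call. = FALSE)
  structure(
    list(classes = classes, trials_per_class = trials_per_class,
         tau_rise_s = tau_rise_s, tau_decay_s = tau_decay_s,
         tau_jitter_sd = tau_jitter_sd, amp_per_ul = amp_per_ul,
         cross_sensitivity = cross_sensitivity,
         gain_jitter_sd = gain_jitter_sd, drift_sd = drift_sd,
         diff_drift_sd = diff_drift_sd, noise_sigma = noise_sigma, t_total_s = t_total_s, t_on_s = t_on_s,
         t_vent_s = t_vent_s, dt_s = dt_s),
    class = "sawr_spec")
}

#' Generate the synthetic SAWR chemosensor dataset
#'
#' @param spec A [sawr_spec()].
#' @param seed Integer seed.
#' @return A tibble of class `sawr_traces`, long over trials and channels:
#'   `class`, `trial`, `channel`, `time_s`, `f_coated`, `f_uncoated` (Hz,
#'   deviation from carrier).
#' @export
make_synthetic_sawr <- function(spec = sawr_spec(), seed = 1) {
  stopifnot(inherits(spec, "sawr_spec"))
  set.seed(seed)
  time_s <- seq(0, spec$t_total_s, by = spec$dt_s)
  n_t <- length(time_s)
  cls <- spec$classes
  vols <- as.matrix(cls[, c("vol1", "vol2")])

  rows <- purrr::map_dfr(seq_len(nrow(cls)), function(ci) {
    purrr::map_dfr(seq_len(spec$trials_per_class), function(tr) {
      gain <- stats::rlnorm(1, 0, spec$gain_jitter_sd)
      purrr::map_dfr(1:2, function(ch) {
        # effective analyte load seen by this channel's polymer
        load <- vols[ci, ch] + spec$cross_sensitivity * vols[ci, 3 - ch]
        a_ss <- gain * spec$amp_per_ul * load
        tr_rise <- spec$tau_rise_s[ch] * stats::rlnorm(1, 0, spec$tau_jitter_sd)
        tr_dec <- spec$tau_decay_s[ch] * stats::rlnorm(1, 0, spec$tau_jitter_sd)
        resp <- numeric(n_t)
        on <- time_s >= spec$t_on_s & time_s < spec$t_vent_s
        resp[on] <- a_ss * (1 - exp(-(time_s[on] - spec$t_on_s) / tr_rise))
        post <- time_s >= spec$t_vent_s
        r_vent <- a_ss * (1 - exp(-(spec$t_vent_s - spec$t_on_s) / tr_rise))
        resp[post] <- r_vent * exp(-(time_s[post] - spec$t_vent_s) / tr_dec)
        drift <- stats::rnorm(1, 0, spec$drift_sd) * time_s
        wander <- if (spec$diff_drift_sd > 0)
          cumsum(stats::rnorm(n_t, 0, spec$diff_drift_sd)) else 0
        noise <- function() if (spec$noise_sigma > 0)
          stats::rnorm(n_t, 0, spec$noise_sigma) else 0
        tibble::tibble(
          class = cls$class[ci], trial = tr, channel = ch, time_s = time_s,
          f_coated = drift + wander - resp + noise(),  # sorption lowers f
          f_uncoated = drift + noise())
      })
    })
  })
  structure(rows, class = c("sawr_traces", class(tibble::tibble())),
            spec = spec, seed = seed)
}

#' Differential ORN drive from a dual-resonator pair
#'
#' The per-channel ORN current is `beta * (f_uncoated - f_coated)`, clamped
#' at zero from below (no inhibitory sensory drive). Analyte sorption lowers
#' the coated device's frequency, so the differential is positive during
#' stimulation, and any common-mode drift or interference cancels exactly.
#'
#' @param traces A `sawr_traces` tibble (or any tibble with `f_coated`,
#'   `f_uncoated` aligned on one time axis per channel).
#' @param beta Current-per-Hz scale constant (see [calibrate_beta()]).
#' @return The input tibble with a `current` column added.
#' @export
differential_current <- function(traces, beta) {
  stopifnot(all(c("f_coated", "f_uncoated") %in% names(traces)))
  dplyr::mutate(traces,
                current = pmax(0, beta * (.data$f_uncoated - .data$f_coated)))
}

#' Calibrate the sensor-to-current scale constant
#'
#' Chooses `beta` so that the dataset-maximum differential frequency change,
#' applied as a constant current, drives the ORN soma at `target_rate`
#' (default ca. 50 Hz, the in-vivo ORN ceiling). The continuous closed-form
#' f-I relation gives the current; when the target interspike interval is a
#' whole number of grid steps the current is then centred inside the
#' interval of currents whose discrete-time interspike interval equals it
#' (`method = "grid"`), so the simulated rate matches the target exactly on
#' the grid.
#'
#' @param traces A `sawr_traces` tibble.
#' @param lif ORN soma parameters ([lif_params()]).
#' @param target_rate Target steady firing rate (Hz).
#' @param method `"grid"` (default) or `"closed_form"`.
#' @return A list of class `beta_calibration`: `beta`, `max_differential`
#'   (Hz), `current_max`, `target_rate`, and the closed-form `predicted_rate`
#'   at the calibrated maximum.
#' @export
calibrate_beta <- function(traces, lif = lif_params(), target_rate = 50,
                           method = c("grid", "closed_form")) {
  method <- match.arg(method)
  d_max <- max(traces$f_uncoated - traces$f_coated)
  if (!is.finite(d_max) || d_max <= 0) {
    stop("all-zero (or negative) differentials; cannot calibrate",
         call. = FALSE)
  }
  r_m <- lif$tau_m / lif$c_m
  q <- 1000 / (target_rate * lif$tau_m)
  i_cont <- lif$v_theta / (r_m * (1 - exp(-q)))   # closed-form inversion
  i_max <- i_cont
  if (method == "grid") {
    # the discrete recursion's steady-state gain is tau_m_corrected / c_m
    # (decay is exact but the input term integrates as delta * I / c_m)
    r_c <- lif$tau_m_corrected / lif$c_m
    k_star <- 1000 / (target_rate * lif$delta)
    if (abs(k_star - round(k_star)) < 1e-9 && round(k_star) >= 2) {
      k_star <- round(k_star)
      i_k <- function(k) lif$v_theta /
        (r_c * (1 - exp(-k * lif$delta / lif$tau_m)))
      # currents in [i_k(k_star), i_k(k_star - 1)) spike every k_star steps
      i_max <- sqrt(i_k(k_star) * i_k(k_star - 1))
    }
  }
  structure(
    list(beta = i_max / d_max, max_differential = d_max, current_max = i_max,
         target_rate = target_rate, method = method,
         predicted_rate = lif_rate_closed_form(i_max, lif)),
    class = "beta_calibration")
}

#' @export
print.beta_calibration <- function(x, ...) {
  cat(sprintf(
    "<beta_calibration> beta = %.4g (max differential %.4g Hz -> %.3g Hz)\n",
    x$beta, x$max_differential, x$predicted_rate))
  invisible(x)
}

#' Resample a sensor-time series onto the model grid
#'
#' Maps sensor seconds onto model milliseconds by linear interpolation: one
#' sensor second becomes `compression` model milliseconds (default 10), the
#' clock-matching used to couple slow chemosensor dynamics to the fast
#' neuronal core. A 150 s trace then spans 1500 steps at `delta` = 1 ms.
#'
#' @param time_s Sensor time axis (s).
#' @param values Numeric vector or matrix (rows = samples) to resample.
#' @param compression Model milliseconds per sensor second.
#' @param delta Model step (ms).
#' @return Matrix of resampled values on the model grid.
#' @export
resample_to_grid <- function(time_s, values, compression = 10, delta = 1) {
  if (compression <= 0) stop("`compression` must be positive", call. = FALSE)
  if (length(time_s) == 0) stop("empty trace", call. = FALSE)
  values <- as.matrix(values)
  if (nrow(values) != length(time_s)) stop("alignment error", call. = FALSE)
  t_model <- time_s * compression
  grid <- seq(0, max(t_model), by = delta)
  apply(values, 2, function(col) {
    stats::approx(t_model, col, xout = grid, rule = 2)$y
  })
}

#' Convert SAWR traces into per-trial stimulus episodes
#'
#' Applies [differential_current()] with the calibrated `beta`, resamples
#' each trial's two channel currents onto the model grid, and returns one
#' `stimulus_episode` per trial together with its class label.
#'
#' With `normalize = "trial"` (default) each trial's differential pair is
#' rescaled by that trial's maximum differential before conversion to
#' current, so the dominant channel of every trial reaches the calibrated
#' ORN ceiling: the drive encodes the blend ratio, not the absolute
#' concentration. `"none"` feeds the raw differentials (the drive then
#' scales with concentration and sub-maximal trials may stay below the ORN
#' threshold).
#'
#' @param traces A `sawr_traces` tibble.
#' @param beta Scale constant (number or [calibrate_beta()] result).
#' @param normalize `"trial"` or `"none"`.
#' @inheritParams resample_to_grid
#' @return A list with `episodes` (list of `stimulus_episode`) and `labels`
#'   (character vector of ratio classes).
#' @export
sensor_episodes <- function(traces, beta, compression = 10, delta = 1,
                            normalize = c("trial", "none")) {
  normalize <- match.arg(normalize)
  max_diff <- max(traces$f_uncoated - traces$f_coated)
  if (inherits(beta, "beta_calibration")) beta <- beta$beta
  cur <- differential_current(traces, beta)
  if (normalize == "trial") {
    cur <- cur |>
      dplyr::group_by(.data$class, .data$trial) |>
      dplyr::mutate(current = if (max(.data$current) > 0)
        .data$current * beta * max_diff / max(.data$current)
        else .data$current) |>
      dplyr::ungroup()
  }
  keys <- dplyr::distinct(cur, .data$class, .data$trial)
  eps <- purrr::map(seq_len(nrow(keys)), function(i) {
    tr <- dplyr::filter(cur, .data$class == keys$class[i],
                        .data$trial == keys$trial[i])
    wide <- tidyr::pivot_wider(tr[, c("time_s", "channel", "current")],
                               names_from = "channel",
                               values_from = "current")
    m <- resample_to_grid(wide$time_s, as.matrix(wide[, c("1", "2")]),
                          compression, delta)
    colnames(m) <- NULL
    seg <- tibble::tibble(segment = 1L, label = keys$class[i],
                          amp1 = NA_real_, amp2 = NA_real_,
                          start_step = 0L, end_step = nrow(m) - 1L)
    new_stimulus_episode(m, seg, delta)
  })
  list(episodes = eps, labels = keys$class, trials = keys$trial)
}
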