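#' Discrete Gaussian kernel for firing-rate estimation
#'
#' `T(n, d) = exp(-d) I_n(d)` with `I_n` the modified Bessel function of
#' integer order: the discrete analogue of a Gaussian of variance `d` (in
#' steps), normalized so the full kernel sums to one. The width parameter
#' `d` is matched to the cell's membrane time constant by default
#' (`d = tau_m / delta`). The kernel is truncated at the smallest radius
#' holding at least 99.9% of its mass.
#'
#' @param d Width parameter (steps), `>= 0`; `d = 0` gives the delta kernel.
#' @param half_width Truncation radius (steps); default smallest radius with
#'   mass `>= mass_min`.
#' @param mass_min Minimum retained kernel mass.
#' @return A list of class `rate_kernel`: `values` (for offsets
#'   `-half_width ... half_width`), `offsets`, `d`, `mass`.
#' @export
rate_kernel <- function(d, half_width = NULL, mass_min = 0.999) {
  if (d < 0) stop("`d` must be non-negative", call. = FALSE)
  if (d == 0) {
    return(structure(list(values = 1, offsets = 0L, d = 0, mass = 1),
                     class = "rate_kernel"))
  }
  t_at <- function(n) besselI(d, abs(n), expon.scaled = TRUE)
  if (is.null(half_width)) {
    h <- ceiling(3 * sqrt(d))
    while (t_at(0) + 2 * sum(t_at(seq_len(h))) < mass_min) h <- h + 1L
    half_width <- h
  }
  offs <- seq.int(-half_width, half_width)
  vals <- t_at(offs)
  structure(list(values = vals, offsets = offs, d = d, mass = sum(vals)),
            class = "rate_kernel")
}

# smoothed per-channel rates (Hz) from spike (cell, step) pairs; steps 0-based
rates_from_spikes <- function(cells, steps, n_channels, n_steps, d, delta,
                              mode = "symmetric") {
  ind <- matrix(0, n_steps, n_channels)
  if (length(cells)) {
    tab <- table(factor(steps, levels = 0:(n_steps - 1)),
                 factor(cells, levels = seq_len(n_channels)))
    ind <- matrix(as.numeric(tab), n_steps, n_channels)
  }
  kern <- rate_kernel(d)
  h <- max(kern$offsets)
  out <- apply(ind, 2, function(x) {
    if (h == 0) return(x)
    padded <- c(numeric(h), x, numeric(h))
    v <- stats::filter(padded, rev(kern$values), method = "convolution",
                       sides = 2)
    as.numeric(v[(h + 1):(h + n_steps)])
  })
  if (mode == "causal") {
    # one-sided renormalized kernel for real-time semantics
    kvals <- kern$values[kern$offsets >= 0]
    kvals <- kvals / sum(kvals)
    out <- apply(ind, 2, function(x) {
      as.numeric(stats::filter(c(numeric(length(kvals) - 1), x), rev(kvals),
                               method = "convolution",
                               sides = 1)[length(kvals):(length(kvals) + n_steps - 1)])
    })
  }
  out * (1000 / delta)   # spikes/step -> Hz
}

#' Estimate firing-rate trajectories from a simulation
#'
#' Convolves each neuron's 0/1 spike indicator with the discrete Gaussian
#' kernel and scales to Hz. The symmetric (offline) kernel is the default; a
#' causal one-sided renormalized variant is available for real-time
#' semantics.
#'
#' @param sim An [simulate_mgc()] result.
#' @param population `"pn"`, `"ln"` or `"orn"`.
#' @param d Kernel width (steps); default the population's `tau_m / delta`.
#' @param mode `"symmetric"` or `"causal"`.
#' @return A numeric matrix, steps x channels (Hz).
#' @export
estimate_rates <- function(sim, population = "pn", d = NULL,
                           mode = c("symmetric", "causal")) {
  mode <- match.arg(mode)
  stopifnot(inherits(sim, "mgc_sim"))
  cfg <- sim$config
  n_ch <- switch(population, orn = cfg$n_orn, ln = cfg$n_ln,
                 pn = cfg$n_glom * cfg$n_pn_per_glom,
                 stop("unknown population", call. = FALSE))
  if (is.null(d)) {
    d <- switch(population, orn = cfg$tau_m_orn, ln = cfg$tau_m_ln,
                pn = cfg$tau_m_pn) / cfg$delta
  }
  sp <- dplyr::filter(sim$spikes, .data$population == !!population)
  rates_from_spikes(sp$cell, sp$step, n_ch, sim$n_steps, d, cfg$delta, mode)
}

#' Bundle rate trajectories into a labeled set
#'
#' @param trials List of steps x channels rate matrices (equal dimensions).
#' @param labels Class label per trial.
#' @param delta Step duration (ms).
#' @return A list of class `trajectory_set`.
#' @export
trajectory_set <- function(trials, labels, delta = 1) {
  stopifnot(length(trials) == length(labels), length(trials) >= 1)
  dims <- vapply(trials, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
    stop("all trials must share the same steps x channels dimensions",
         call. = FALSE)
  }
  structure(list(trials = trials, labels = as.character(labels),
                 delta = delta, n_steps = dims[1, 1], n_channels = dims[2, 1]),
            class = "trajectory_set")
}

#' @export
print.trajectory_set <- function(x, ...) {
  cat("<trajectory_set>", length(x$trials), "trials,", x$n_steps, "steps x",
      x$n_channels, "channels;", length(unique(x$labels)), "classes\n")
  invisible(x)
}

#' Project a trajectory set onto its principal components
#'
#' Pools all time samples of all trials, mean-centres, and extracts the top
#' principal components of the channel covariance. Variance fractions are
#' reported in descending order.
#'
#' @param tset A [trajectory_set()].
#' @param n_components Components to keep.
#' @return A list of class `trajectory_pca`: `scores` (list of projected
#'   trials), `var_frac`, `cum_var`, `loadings`, `degenerate` flag.
#' @export
project_pca <- function(tset, n_components = 3) {
  stopifnot(inherits(tset, "trajectory_set"))
  if (tset$n_channels < n_components) {
    stop("need at least `n_components` channels", call. = FALSE)
  }
  pooled <- do.call(rbind, tset$trials)
  if (all(apply(pooled, 2, stats::var) == 0)) {
    return(structure(list(scores = NULL, var_frac = rep(NA_real_, n_components),
                          cum_var = NA_real_, loadings = NULL,
                          degenerate = TRUE, labels = tset$labels),
                     class = "trajectory_pca"))
  }
  pc <- stats::prcomp(pooled, center = TRUE, scale. = FALSE)
  vf <- pc$sdev^2 / sum(pc$sdev^2)
  ctr <- pc$center
  rot <- pc$rotation[, seq_len(n_components), drop = FALSE]
  scores <- purrr::map(tset$trials, ~ sweep(.x, 2, ctr) %*% rot)
  structure(list(scores = scores, var_frac = vf[seq_len(n_components)],
                 cum_var = sum(vf[seq_len(n_components)]), loadings = rot,
                 all_var_frac = vf, degenerate = FALSE, labels = tset$labels,
                 delta = tset$delta),
            class = "trajectory_pca")
}

#' @export
print.trajectory_pca <- function(x, ...) {
  if (isTRUE(x$degenerate)) {
    cat("<trajectory_pca> degenerate (zero-variance) input\n")
  } else {
    cat(sprintf("<trajectory_pca> top %d components capture %.1f%% variance\n",
                length(x$var_frac), 100 * x$cum_var))
  }
  invisible(x)
}
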