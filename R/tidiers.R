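#' Tidy a simulation into its spike raster
#'
#' @param x An `mgc_sim`.
#' @param ... Unused.
#' @return The spikes tibble (`neuron`, `population`, `cell`, `glomerulus`,
#'   `step`, `time_ms`).
#' @export
tidy.mgc_sim <- function(x, ...) x$spikes

#' @rdname tidy.mgc_sim
#' @export
glance.mgc_sim <- function(x, ...) {
  tibble::tibble(
    n_steps = x$n_steps, delta = x$delta, n_neurons = nrow(x$neurons),
    n_spikes = nrow(x$spikes),
    n_pn_spikes = sum(x$spikes$population == "pn"))
}

#' Tidy a connectome into an edge list
#'
#' @param x An `mgc_connectome`.
#' @param ... Unused.
#' @return A tibble with one row per synapse: `pathway`, `pre`, `post`,
#'   `weight` (signed).
#' @export
tidy.mgc_connectome <- function(x, ...) {
  edge_tbl <- function(w, pathway) {
    idx <- which(w != 0, arr.ind = TRUE)
    tibble::tibble(pathway = pathway, pre = idx[, 2], post = idx[, 1],
                   weight = w[idx])
  }
  dplyr::bind_rows(
    edge_tbl(x$W_ol, "orn_ln"), edge_tbl(x$W_op, "orn_pn"),
    edge_tbl(x$W_ll, "ln_ln"), edge_tbl(x$W_lp, "ln_pn"),
    edge_tbl(x$W_pp, "pn_pn"))
}

#' @rdname tidy.mgc_connectome
#' @export
glance.mgc_connectome <- function(x, ...) {
  tibble::tibble(
    regime = x$config$regime, seed = x$seed,
    n_neurons = nrow(x$neurons), n_ln_ln_edges = sum(x$A_ll),
    mean_w_orn_ln = mean(x$W_ol),
    mean_w_ln_ln = mean(-x$W_ll[x$A_ll]))
}

#' Tidy a trajectory set into long format
#'
#' @param x A `trajectory_set`.
#' @param ... Unused.
#' @return A tibble: `trial`, `label`, `step`, `time_ms`, `channel`, `rate`.
#' @export
tidy.trajectory_set <- function(x, ...) {
  purrr::imap_dfr(x$trials, function(m, i) {
    tibble::tibble(
      trial = i, label = x$labels[i],
      step = rep(seq_len(nrow(m)) - 1L, ncol(m)),
      time_ms = (rep(seq_len(nrow(m)), ncol(m)) - 1) * x$delta,
      channel = rep(seq_len(ncol(m)), each = nrow(m)),
      rate = as.vector(m))
  })
}

#' Tidy an STDP training history
#'
#' @param x An `stdp_history`.
#' @param ... Unused.
#' @return The per-epoch tibble (`epoch`, `abs_change`, `total_w`).
#' @export
tidy.stdp_history <- function(x, ...) x$epoch

#' @rdname tidy.stdp_history
#' @export
glance.stdp_history <- function(x, ...) {
  tibble::tibble(
    epochs = nrow(x$epoch), stability_epoch = x$stability_epoch,
    criterion = x$criterion,
    final_abs_change = x$epoch$abs_change[nrow(x$epoch)],
    final_total_w = x$epoch$total_w[nrow(x$epoch)])
}

#' Tidy a PCA projection
#'
#' @param x A `trajectory_pca`.
#' @param ... Unused.
#' @return A tibble with per-component variance fractions.
#' @export
tidy.trajectory_pca <- function(x, ...) {
  tibble::tibble(component = seq_along(x$all_var_frac),
                 var_frac = x$all_var_frac)
}

#' @rdname tidy.trajectory_pca
#' @export
glance.trajectory_pca <- function(x, ...) {
  tibble::tibble(n_components = length(x$var_frac), cum_var = x$cum_var,
                 degenerate = x$degenerate)
}

#' Tidy a decision curve
#'
#' @param x A `decision_curve`.
#' @param ... Unused.
#' @return The underlying tibble with a `chance` column added.
#' @export
tidy.decision_curve <- function(x, ...) {
  out <- tibble::as_tibble(x)
  out$chance <- attr(x, "chance")
  out
}

#' @rdname tidy.decision_curve
#' @export
glance.decision_curve <- function(x, ...) {
  tibble::tibble(chance = attr(x, "chance"),
                 mean_p = mean(x$p_correct), max_p = max(x$p_correct),
                 t_above_chance = time_above_chance(x))
}
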