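#' Raster plot of a simulation
#'
#' @param object An `mgc_sim`.
#' @param ... Unused.
#' @return A ggplot: spike times by neuron, panelled by population.
#' @export
autoplot.mgc_sim <- function(object, ...) {
  sp <- object$spikes
  sp$population <- factor(sp$population, levels = c("orn", "ln", "pn"))
  ggplot2::ggplot(sp, ggplot2::aes(x = .data$time_ms, y = .data$cell)) +
    ggplot2::geom_point(shape = "|", size = 1.5) +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$population),
                        scales = "free_y", space = "free_y") +
    ggplot2::labs(x = "time (ms)", y = "cell") +
    ggplot2::theme_minimal()
}

#' Decision-curve plot
#'
#' @param object A `decision_curve`.
#' @param ... Unused.
#' @return A ggplot of P(classification) against decision time with the
#'   chance level dashed.
#' @export
autoplot.decision_curve <- function(object, ...) {
  ggplot2::ggplot(tidy(object),
                  ggplot2::aes(x = .data$T_ms, y = .data$p_correct)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = attr(object, "chance"),
                        linetype = "dashed") +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "decision time (ms)", y = "P(classification)") +
    ggplot2::theme_minimal()
}

#' STDP convergence plot
#'
#' @param object An `stdp_history`.
#' @param ... Unused.
#' @return A ggplot of the per-epoch summed absolute weight change.
#' @export
autoplot.stdp_history <- function(object, ...) {
  ggplot2::ggplot(object$epoch,
                  ggplot2::aes(x = .data$epoch, y = .data$abs_change)) +
    ggplot2::geom_line() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "epoch", y = "summed |weight change|") +
    ggplot2::theme_minimal()
}

#' Low-dimensional trajectory plot
#'
#' @param object A `trajectory_pca`.
#' @param components Which two components to draw.
#' @param ... Unused.
#' @return A ggplot of the projected trajectories coloured by class.
#' @export
autoplot.trajectory_pca <- function(object, components = c(1, 2), ...) {
  if (isTRUE(object$degenerate)) stop("degenerate projection", call. = FALSE)
  df <- purrr::imap_dfr(object$scores, function(s, i) {
    tibble::tibble(trial = i, label = object$labels[i],
                   step = seq_len(nrow(s)),
                   x = s[, components[1]], y = s[, components[2]])
  })
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   colour = .data$label,
                                   group = .data$trial)) +
    ggplot2::geom_path(alpha = 0.7) +
    ggplot2::labs(x = paste0("PC", components[1]),
                  y = paste0("PC", components[2]), colour = "ratio") +
    ggplot2::theme_minimal()
}

#' LN ratio-tuning plot
#'
#' Normalized ORN weight pairs of every LN on the unit simplex segment; after
#' training the points spread across the space of input ratios.
#'
#' @param tuning An [ln_tuning()] tibble.
#' @return A ggplot.
#' @export
plot_ln_tuning <- function(tuning) {
  ggplot2::ggplot(tuning[!tuning$untuned, ],
                  ggplot2::aes(x = .data$w1_norm, y = .data$w2_norm)) +
    ggplot2::geom_abline(intercept = 1, slope = -1, colour = "grey70") +
    ggplot2::geom_point(colour = "steelblue", size = 2) +
    ggplot2::coord_equal(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(x = "normalized ORN1 weight", y = "normalized ORN2 weight") +
    ggplot2::theme_minimal()
}
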