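#' Mean class trajectory (template)
#'
#' Pointwise arithmetic mean of all trial trajectories of one class.
#'
#' @param tset A [trajectory_set()].
#' @param class Class label.
#' @return A list of class `class_template`: `label`, `mean` (steps x
#'   channels), `n_trials`.
#' @export
mean_class_trajectory <- function(tset, class) {
  stopifnot(inherits(tset, "trajectory_set"))
  idx <- which(tset$labels == class)
  if (length(idx) == 0) stop("no trials of class ", class, call. = FALSE)
  m <- Reduce(`+`, tset$trials[idx]) / length(idx)
  structure(list(label = class, mean = m, n_trials = length(idx)),
            class = "class_template")
}

#' @rdname mean_class_trajectory
#' @return For `class_templates()`: a named list of templates, one per class
#'   (sorted by label).
#' @export
class_templates <- function(tset) {
  labs <- sort(unique(tset$labels))
  stats::setNames(purrr::map(labs, ~ mean_class_trajectory(tset, .x)), labs)
}

#' Time-averaged Euclidean distance between trajectories
#'
#' `D = (1/T) \int_0^T || r(t) - r_template(t) || dt`, discretized as the
#' step-weighted mean of per-step Euclidean norms over the first
#' `T / delta` steps. A genuine metric for fixed `T` (non-negative,
#' symmetric, triangle inequality).
#'
#' @param trajectory Steps x channels matrix.
#' @param template A `class_template` or a matrix of equal dimensions.
#' @param T_ms Decision time (ms), `0 < T <= trajectory length`.
#' @param delta Step duration (ms).
#' @return The scalar distance.
#' @export
trajectory_distance <- function(trajectory, template, T_ms, delta = 1) {
  tm <- if (inherits(template, "class_template")) template$mean else template
  if (T_ms <= 0) stop("`T_ms` must be positive", call. = FALSE)
  k <- round(T_ms / delta)
  if (k > nrow(trajectory) || k > nrow(tm)) {
    stop("decision time exceeds trajectory length", call. = FALSE)
  }
  d <- trajectory[seq_len(k), , drop = FALSE] - tm[seq_len(k), , drop = FALSE]
  mean(sqrt(rowSums(d^2)))
}

#' Nearest-mean-trajectory classification
#'
#' Assigns the label of the template minimizing the time-averaged Euclidean
#' distance up to the decision time. Ties are broken in favour of the
#' lowest class index (template order).
#'
#' @param trajectory Steps x channels matrix.
#' @param templates Named list of `class_template`s (see
#'   [class_templates()]).
#' @inheritParams trajectory_distance
#' @return The winning class label.
#' @export
classify_nearest <- function(trajectory, templates, T_ms, delta = 1) {
  if (length(templates) == 0) stop("empty template set", call. = FALSE)
  d <- vapply(templates, function(tm)
    trajectory_distance(trajectory, tm, T_ms, delta), numeric(1))
  names(templates)[which.min(d)]
}

#' Classification probability over decision time (leave-one-out)
#'
#' For every decision time `T`, rotates through the trials leave-one-out:
#' class templates are rebuilt from the remaining trials, the held-out trial
#' is classified by nearest mean trajectory, and the fraction correct is
#' reported. With equal priors over `K` classes the chance level is `1/K`.
#'
#' @param tset A [trajectory_set()].
#' @param times Decision times (ms).
#' @param normalize Per-channel max-absolute scaling estimated on the
#'   training split of each rotation (used for the raw-sensor baseline).
#' @param shuffle_labels Permute class labels before evaluation (chance
#'   control); uses `seed`.
#' @param seed Seed for the label shuffle.
#' @return A tibble of class `decision_curve`: `T_ms`, `p_correct`,
#'   `n_correct`, `n_trials`; attribute `chance`.
#' @export
classification_curve <- function(tset, times = NULL, normalize = FALSE,
                                 shuffle_labels = FALSE, seed = 1) {
  stopifnot(inherits(tset, "trajectory_set"))
  delta <- tset$delta
  if (is.null(times)) {
    times <- round(seq(0.1, 1, length.out = 10) * tset$n_steps * delta)
  }
  labels <- tset$labels
  if (shuffle_labels) {
    set.seed(seed)
    labels <- sample(labels)
  }
  labs <- sort(unique(labels))
  counts <- table(factor(labels, levels = labs))
  if (any(counts < 2)) {
    stop("leave-one-out needs at least two trials per class", call. = FALSE)
  }
  n_trials <- length(tset$trials)
  k_idx <- pmin(pmax(1L, round(times / delta)), tset$n_steps)

  class_sums <- purrr::map(labs, function(l)
    Reduce(`+`, tset$trials[labels == l]))
  names(class_sums) <- labs

  correct <- matrix(FALSE, n_trials, length(times))
  for (y in seq_len(n_trials)) {
    tr_y <- tset$trials[[y]]
    scale_y <- NULL
    if (normalize) {
      # per-channel max-abs over the training split (all trials but y)
      train_max <- purrr::reduce(
        tset$trials[-y], function(acc, m) pmax(acc, apply(abs(m), 2, max)),
        .init = rep(0, tset$n_channels))
      scale_y <- ifelse(train_max > 0, train_max, 1)
    }
    dist_cum <- vapply(labs, function(l) {
      n_l <- counts[[l]]
      tmpl <- if (labels[y] == l) {
        (class_sums[[l]] - tr_y) / (n_l - 1)
      } else {
        class_sums[[l]] / n_l
      }
      dmat <- tr_y - tmpl
      if (normalize) dmat <- sweep(dmat, 2, scale_y, "/")
      cumsum(sqrt(rowSums(dmat^2)))
    }, numeric(tset$n_steps))
    picked <- labs[apply(dist_cum[k_idx, , drop = FALSE] /
                           k_idx, 1, which.min)]
    correct[y, ] <- picked == labels[y]
  }
  out <- tibble::tibble(
    T_ms = times, n_correct = colSums(correct), n_trials = n_trials,
    p_correct = colSums(correct) / n_trials)
  structure(out, class = c("decision_curve", class(out)),
            chance = 1 / length(labs), scheme = "leave-one-out")
}

#' First decision time reliably above chance
#'
#' Smallest `T` at which the classification probability exceeds chance by
#' more than two binomial standard errors; `Inf` if never.
#'
#' @param curve A [classification_curve()] result.
#' @return Decision time (ms).
#' @export
time_above_chance <- function(curve) {
  ch <- attr(curve, "chance")
  se <- sqrt(ch * (1 - ch) / curve$n_trials)
  hit <- curve$p_correct > ch + 2 * se
  if (any(hit)) curve$T_ms[which(hit)[1]] else Inf
}

#' Simulate rate trajectories for a list of stimulus episodes
#'
#' Runs the connectome on each episode (seeded per trial) and collects the
#' smoothed PN population rate trajectories into a labeled set.
#'
#' @param connectome An [build_mgc()] result.
#' @param episodes List of `stimulus_episode`s.
#' @param labels Class label per episode.
#' @param seed Integer seed; trial noise seeds derive from it.
#' @param d Kernel width for rate estimation (default `tau_m_pn / delta`).
#' @return A [trajectory_set()] of PN trajectories.
#' @export
model_trajectories <- function(connectome, episodes, labels, seed = 1,
                               d = NULL) {
  trials <- purrr::imap(episodes, function(ep, i) {
    sim <- simulate_mgc(connectome, ep, seed = derive_seed(seed, i))
    estimate_rates(sim, "pn", d = d)
  })
  trajectory_set(trials, labels, delta = episodes[[1]]$delta)
}

#' Raw-sensor baseline trajectories
#'
#' The two-channel differential sensor currents of each trial, resampled to
#' the model grid, used directly as trajectories. Combined with
#' `classification_curve(normalize = TRUE)` this is the standard
#' nearest-mean baseline the model output is compared against.
#'
#' @inheritParams sensor_episodes
#' @return A [trajectory_set()] with 2 channels.
#' @export
sensor_trajectories <- function(traces, beta, compression = 10, delta = 1) {
  se <- sensor_episodes(traces, beta, compression, delta)
  trajectory_set(purrr::map(se$episodes, "currents"), se$labels, delta)
}

#' Greedy selection of an MGC model over a candidate pool
#'
#' Scores every candidate connectome by its training-set classification
#' performance (the decision curve integrated over the supplied times, with
#' plasticity disabled) and returns the maximizer; the first encountered
#' wins ties.
#'
#' @param candidates List of `mgc_connectome`s.
#' @param episodes,labels Training episodes and class labels.
#' @param times Decision times (ms) to integrate over.
#' @param seed Integer seed for simulation noise.
#' @return A list of class `greedy_selection`: `best` (connectome),
#'   `best_index`, `scores` tibble.
#' @export
greedy_select <- function(candidates, episodes, labels, times = NULL,
                          seed = 1) {
  if (length(candidates) == 0) stop("empty candidate set", call. = FALSE)
  scores <- purrr::imap_dbl(candidates, function(cand, i) {
    tset <- model_trajectories(cand, episodes, labels,
                               seed = derive_seed(seed, 1000 + i))
    mean(classification_curve(tset, times)$p_correct)
  })
  best <- which.max(scores)
  structure(
    list(best = candidates[[best]], best_index = best,
         scores = tibble::tibble(candidate = seq_along(candidates),
                                 score = scores)),
    class = "greedy_selection")
}

#' @export
print.greedy_selection <- function(x, ...) {
  cat("<greedy_selection> best candidate:", x$best_index,
      sprintf("(score %.3f of %d candidates)\n", max(x$scores$score),
              nrow(x$scores)))
  invisible(x)
}
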