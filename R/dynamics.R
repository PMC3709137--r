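#' Exact-integration correction of a decay time constant
#'
#' Forward-Euler integration of a linear decay `dv/dt = -v/tau` on a grid of
#' step `delta` uses the factor `1 - delta/tau`, which undershoots the true
#' per-step decay `exp(-delta/tau)`. Replacing `tau` by the corrected constant
#' `delta / (1 - exp(-delta/tau))` makes the forward-Euler recursion reproduce
#' the exact exponential at every grid point, so the subthreshold solution is
#' independent of step size.
#'
#' @param tau Time constant (ms), `> 0`.
#' @param delta Step duration (ms), `> 0`.
#' @return Corrected time constant (ms), always `>= tau` and converging to
#'   `tau` as `delta -> 0`.
#' @examples
#' correct_tau(10, 1)                       # 10.508...
#' 1 - 1 / correct_tau(10, 1)               # equals exp(-1/10)
#' @export
correct_tau <- function(tau, delta) {
  if (any(tau <= 0) || any(delta <= 0)) {
    stop("`tau` and `delta` must be positive", call. = FALSE)
  }
  delta / (1 - exp(-delta / tau))
}

#' Leaky integrate-and-fire soma parameters
#'
#' Membrane dynamics are `v_{k+1} = v_k (1 - delta/tau_m_corrected) +
#' (delta/c_m) I_k`; when `v` reaches `v_theta` the soma emits a spike and is
#' reset to `v_ahp` on the same step. There is no refractory period and no
#' spontaneous activity. Potentials and currents are in arbitrary units
#' relative to `v_theta = 1`, `c_m = 1`.
#'
#' @param tau_m Membrane time constant (ms). 10 ms for ORNs and PNs, 20 ms for
#'   LNs.
#' @param c_m Membrane capacitance (arbitrary units).
#' @param v_theta Spike threshold.
#' @param v_ahp After-hyperpolarization (reset) value; must be `< v_theta`.
#' @param delta Step duration (ms) used for the exact-integration correction.
#' @return A list of class `lif_params` with the corrected constant
#'   `tau_m_corrected` attached.
#' @export
lif_params <- function(tau_m = 10, c_m = 1, v_theta = 1, v_ahp = 0,
                       delta = 1) {
  if (tau_m <= 0) stop("`tau_m` must be positive", call. = FALSE)
  if (v_theta <= v_ahp) stop("`v_theta` must exceed `v_ahp`", call. = FALSE)
  structure(
    list(tau_m = tau_m, c_m = c_m, v_theta = v_theta, v_ahp = v_ahp,
         delta = delta, tau_m_corrected = correct_tau(tau_m, delta),
         decay = exp(-delta / tau_m)),   # == 1 - delta/tau_m_corrected
    class = "lif_params")
}

#' Advance a LIF soma by one step
#'
#' Pure-R reference implementation of the per-step soma update; the network
#' engine ([simulate_mgc()]) runs the identical recursion in compiled code.
#'
#' @param state List with `v` (membrane potential) and `spiked` (logical).
#'   Use `lif_state()` for a resting soma.
#' @param params A [lif_params()] object.
#' @param input_current Total dendritic current for this step.
#' @return Updated state; after a spike step `v == v_ahp` and `spiked == TRUE`.
#' @export
lif_step <- function(state, params, input_current) {
  # params$decay caches 1 - delta/tau_m_corrected = exp(-delta/tau_m)
  v <- state$v * params$decay +
    (params$delta / params$c_m) * input_current
  if (v >= params$v_theta) {
    list(v = params$v_ahp, spiked = TRUE)
  } else {
    list(v = v, spiked = FALSE)
  }
}

#' @rdname lif_step
#' @param v Initial membrane potential.
#' @export
lif_state <- function(v = 0) list(v = v, spiked = FALSE)

#' Exponential-decay synapse parameters
#'
#' A presynaptic spike injects a current pulse of magnitude `b * w`, which
#' then decays with constant `tau_syn` (corrected for exact integration).
#' Inhibitory synapses carry negative `w` and therefore deliver negative
#' current.
#'
#' @param tau_syn Decay constant (ms): excitatory `tau_e` or inhibitory
#'   `tau_i`.
#' @param b Current-pulse scale constant.
#' @param w Signed synaptic efficacy.
#' @param delta Step duration (ms).
#' @export
synapse_params <- function(tau_syn, b = 1, w = 1, delta = 1) {
  if (tau_syn <= 0) stop("`tau_syn` must be positive", call. = FALSE)
  structure(
    list(tau_syn = tau_syn, b = b, w = w, delta = delta,
         tau_syn_corrected = correct_tau(tau_syn, delta),
         decay = exp(-delta / tau_syn)),
    class = "synapse_params")
}

#' Advance an exponential-decay synapse by one step
#'
#' @param state List with `i`, the instantaneous postsynaptic current. Use
#'   `synapse_state()` for a quiescent synapse.
#' @param params A [synapse_params()] object.
#' @param presyn_spike Logical: did the presynaptic soma spike this step?
#' @return Updated state: `i_{k+1} = b w [spike] + i_k (1 -
#'   delta/tau_syn_corrected)`.
#' @export
synapse_step <- function(state, params, presyn_spike) {
  list(i = params$b * params$w * as.numeric(isTRUE(presyn_spike)) +
         state$i * params$decay)
}

#' @rdname synapse_step
#' @param i Initial postsynaptic current.
#' @export
synapse_state <- function(i = 0) list(i = i)

#' Closed-form steady firing rate of a LIF soma under constant current
#'
#' For constant `I` with `I R_m > v_theta` (`R_m = tau_m / c_m`) the
#' interspike interval is `tau_m log(I R_m / (I R_m - v_theta))` and the rate
#' its reciprocal; below rheobase the rate is 0.
#'
#' @param current Constant input current (vectorized).
#' @param params A [lif_params()] object.
#' @return Firing rate in Hz.
#' @export
lif_rate_closed_form <- function(current, params = lif_params()) {
  r_m <- params$tau_m / params$c_m
  drive <- current * r_m
  rate <- numeric(length(current))
  sup <- drive > params$v_theta
  rate[sup] <- 1000 / (params$tau_m *
                         log(drive[sup] / (drive[sup] - params$v_theta)))
  rate
}

#' Simulate a single LIF soma on a current series
#'
#' Runs the exact-integration recursion in compiled code and returns the
#' membrane trace and spike steps. Used to verify rate calibrations against
#' the closed form.
#'
#' @param current Numeric vector of per-step input current.
#' @param params A [lif_params()] object.
#' @return A list with `v` (trace) and `spike_steps` (0-based step indices).
#' @export
lif_run <- function(current, params = lif_params()) {
  lif_run_core(as.numeric(current), params$delta, params$tau_m,
               params$v_theta, params$v_ahp, params$c_m)
}

#' Fixed-point state representation for the verification mode
#'
#' Describes the quantized state used by [decay_error_lsb()]: a signed
#' `word_length`-bit register whose most positive value maps to `full_scale`.
#' `rounding = "guard"` models a register backed by a guard-bit accumulator
#' that preserves the rounding residual between steps (first-order error
#' feedback), so quantization error never propagates; `"nearest"` models
#' plain per-step round-to-nearest-even, which exhibits a stall plateau at
#' small state values.
#'
#' @param word_length Bits of the signed state; 16 or 32.
#' @param full_scale Real value represented by the maximum positive integer.
#' @param rounding `"guard"` or `"nearest"`.
#' @export
fixed_point_spec <- function(word_length = 32, full_scale = 1,
                             rounding = c("guard", "nearest")) {
  if (!word_length %in% c(16L, 32L)) {
    stop("`word_length` must be 16 or 32", call. = FALSE)
  }
  structure(
    list(word_length = as.integer(word_length), full_scale = full_scale,
         rounding = match.arg(rounding),
         lsb = full_scale / 2^(word_length - 1)),
    class = "fixed_point_spec")
}

#' Quantization error of the exact-integration decay
#'
#' Runs the membrane decay recursion from full scale with zero input in
#' quantized arithmetic and compares it step by step against the rounded
#' closed form `v_0 exp(-k delta / tau_m)`. The maximum absolute discrepancy
#' is reported in LSB units. With the corrected time constant and
#' residual-preserving (`"guard"`) rounding the error stays within half an
#' LSB at every step; with the uncorrected forward-Euler factor
#' `1 - delta/tau_m` the quantized state drifts away from the exponential and
#' the error grows without bound.
#'
#' @param params A [lif_params()] object.
#' @param spec A [fixed_point_spec()].
#' @param horizon Number of steps (`> 0`).
#' @param corrected Use the exact-integration decay factor (default) or the
#'   raw forward-Euler factor.
#' @return A list: `max_error_lsb`, per-step `error_lsb`, and the quantized
#'   trace `v_lsb` (in LSB units).
#' @export
decay_error_lsb <- function(params = lif_params(), spec = fixed_point_spec(),
                            horizon = 1000, corrected = TRUE) {
  if (horizon <= 0) stop("`horizon` must be positive", call. = FALSE)
  v0 <- 2^(spec$word_length - 1) - 1
  alpha <- if (corrected) {
    1 - params$delta / params$tau_m_corrected
  } else {
    1 - params$delta / params$tau_m
  }
  alpha_true <- exp(-params$delta / params$tau_m)
  k <- seq_len(horizon)
  exact <- v0 * alpha_true^k

  v_lsb <- numeric(horizon)
  if (spec$rounding == "guard") {
    h <- v0   # accumulator with guard bits: residual carried between steps
    for (j in k) {
      h <- h * alpha
      v_lsb[j] <- round(h)
    }
  } else {
    v <- v0
    for (j in k) {
      v <- round(v * alpha)
      v_lsb[j] <- v
    }
  }
  err <- v_lsb - round(exact)
  list(max_error_lsb = max(abs(err)), error_lsb = err, v_lsb = v_lsb)
}
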