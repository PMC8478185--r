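#' Gating-variable kinetics specification
#'
#' Describes one Hodgkin-Huxley gating variable by its sigmoid steady-state
#' curve and bell-shaped voltage-dependent time constant. The steady state is
#' \eqn{x_\infty(V) = 1/2 + 1/2\,\tanh((V - V_{1/2})/V_{sl})} and the time
#' constant is
#' \eqn{\tau_x(V) = (\tau_{max}-\tau_{min})[1-\tanh^2((V-V_{\tau,1/2})/V_{\tau,sl})] + \tau_{min}}.
#'
#' @param v_half Midpoint of the steady-state sigmoid (mV).
#' @param v_slope Slope factor of the sigmoid (mV); negative for variables
#'   that activate with hyperpolarization (Kir) or for inactivation gates.
#' @param tau_max,tau_min Maximum and minimum of the bell-shaped time
#'   constant (ms); `tau_max >= tau_min > 0`.
#' @param v_tau_half Voltage of the time-constant peak (mV).
#' @param v_tau_slope Width parameter of the bell (mV), nonzero.
#' @param p Integer exponent applied to the activation variable in the
#'   current equation (ignored for inactivation gates).
#' @return An object of class `gating_spec`.
#' @seealso [steady_state()], [time_constant()], [gating_step()]
#' @export
gating_spec <- function(v_half, v_slope, tau_max, tau_min, v_tau_half,
                        v_tau_slope, p = 1L) {
  stopifnot(is.numeric(v_half), is.numeric(v_slope), v_slope != 0,
            v_tau_slope != 0, tau_max >= tau_min, tau_min > 0,
            p >= 1, p == as.integer(p))
  structure(list(v_half = as.numeric(v_half), v_slope = as.numeric(v_slope),
                 tau_max = as.numeric(tau_max), tau_min = as.numeric(tau_min),
                 v_tau_half = as.numeric(v_tau_half),
                 v_tau_slope = as.numeric(v_tau_slope), p = as.integer(p)),
            class = "gating_spec")
}

#' @export
print.gating_spec <- function(x, ...) {
  cat(sprintf(
    "<gating_spec> x_inf: V1/2 = %g mV, slope = %g mV, p = %d\n", x$v_half,
    x$v_slope, x$p))
  cat(sprintf("  tau: %g-%g ms, peak at %g mV (width %g mV)\n", x$tau_min,
              x$tau_max, x$v_tau_half, x$v_tau_slope))
  invisible(x)
}

#' Steady-state activation/inactivation level
#'
#' @param v Membrane potential (mV), vectorized.
#' @param spec A [gating_spec()].
#' @return Level in (0, 1).
#' @export
steady_state <- function(v, spec) {
  0.5 + 0.5 * tanh((v - spec$v_half) / spec$v_slope)
}

#' Voltage-dependent gating time constant
#'
#' @inheritParams steady_state
#' @return Time constant in ms, within `[tau_min, tau_max]`.
#' @export
time_constant <- function(v, spec) {
  th <- tanh((v - spec$v_tau_half) / spec$v_tau_slope)
  (spec$tau_max - spec$tau_min) * (1 - th^2) + spec$tau_min
}

#' Exponential-Euler update of a gating variable
#'
#' Advances `x` toward `steady_state(v, spec)` by the exact exponential
#' relaxation over one time step at fixed voltage:
#' `x_inf + (x - x_inf) * exp(-dt / tau(v))`.
#'
#' @param x Current gating level in `[0, 1]`.
#' @inheritParams steady_state
#' @param dt Time step (ms), positive.
#' @return Updated level.
#' @export
gating_step <- function(x, v, spec, dt) {
  stopifnot(dt > 0)
  xi <- steady_state(v, spec)
  xi + (x - xi) * exp(-dt / time_constant(v, spec))
}

#' Synaptic connection specification
#'
#' First-order transmitter-release kinetics: the activation `S` relaxes toward
#' `S_inf(V_pre) = tanh((V_pre - v_th)/v_slope)` (0 when `V_pre <= v_th`) with
#' effective time constant `tau_syn * (1 - S_inf)`, and the postsynaptic
#' current is `g_syn * S * (e_syn - V)`.
#'
#' @param g_syn Maximal synaptic conductance (nS).
#' @param e_syn Reversal potential (mV).
#' @param tau_syn Release time constant (ms), positive.
#' @param v_th Presynaptic release threshold (mV).
#' @param v_slope Presynaptic activation slope (mV), positive.
#' @return An object of class `synapse_spec`.
#' @export
synapse_spec <- function(g_syn, e_syn, tau_syn = 10, v_th = -30,
                         v_slope = 20) {
  stopifnot(tau_syn > 0, v_slope > 0, g_syn >= 0)
  structure(list(g_syn = g_syn, e_syn = e_syn, tau_syn = tau_syn,
                 v_th = v_th, v_slope = v_slope), class = "synapse_spec")
}

# S_inf is clamped below 1 so the effective time constant stays positive.
syn_steady <- function(v_pre, spec) {
  s <- ifelse(v_pre > spec$v_th, tanh((v_pre - spec$v_th) / spec$v_slope), 0)
  pmin(s, 1 - 1e-6)
}

#' Exponential-Euler update of the synaptic activation
#'
#' @param s Current activation in `[0, 1)`.
#' @param v_pre Presynaptic membrane potential (mV).
#' @param spec A [synapse_spec()].
#' @param dt Time step (ms), positive.
#' @return Updated activation in `[0, 1)`.
#' @export
synaptic_state_step <- function(s, v_pre, spec, dt) {
  stopifnot(dt > 0, s >= 0, s < 1)
  si <- syn_steady(v_pre, spec)
  si + (s - si) * exp(-dt / (spec$tau_syn * (1 - si)))
}

#' Postsynaptic current
#'
#' @param v_post Postsynaptic membrane potential (mV).
#' @param s Synaptic activation in `[0, 1]`.
#' @param spec A [synapse_spec()].
#' @return Current in pA; positive values depolarize.
#' @export
synaptic_current <- function(v_post, s, spec) {
  spec$g_syn * s * (spec$e_syn - v_post)
}
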