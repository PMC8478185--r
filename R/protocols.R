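# The two stimulation protocols used throughout: somatic current steps
# (static excitability) and simulated synaptic bombardment through the
# conductance-clamp rate law (dynamic excitability).

#' Current-step stimulation protocol
#'
#' Steps of `duration` ms delivered once per `cycle` ms, from `start` to
#' `max_current` in `increment` steps; the default grid (-160 to +200 pA in
#' 5 pA steps) yields 73 sweeps. `pre` ms of rest precede each step so each
#' sweep carries its own baseline.
#'
#' @param start First (most hyperpolarizing) amplitude (pA).
#' @param increment Amplitude increment per sweep (pA), positive.
#' @param max_current Last amplitude (pA).
#' @param duration Step duration (ms), shorter than `cycle`.
#' @param cycle Sweep cycle period (ms).
#' @param pre Pre-step baseline within the cycle (ms).
#' @return An object of class `current_step_protocol`.
#' @export
current_step_protocol <- function(start = -160, increment = 5,
                                  max_current = 200, duration = 400,
                                  cycle = 1250, pre = 100) {
  stopifnot(increment > 0, duration < cycle, pre + duration <= cycle,
            max_current >= start)
  structure(list(start = start, increment = increment,
                 max_current = max_current, duration = duration,
                 cycle = cycle, pre = pre,
                 amplitudes = seq(start, max_current, by = increment)),
            class = "current_step_protocol")
}

#' Synaptic-bombardment (conductance clamp) protocol
#'
#' Sweep `k` (k = 0, 1, ...) applies `g_AMPA = k * g_exc_step` and
#' `g_GABA = k * g_inh_step` through the synaptic release rate law driven by
#' replayed presynaptic waveforms, for `on` ms followed by `rest` ms of
#' silence. The default excitatory schedule 0 to 25 nS in 0.5 nS increments
#' (inhibition 1 nS per sweep) yields 51 sweeps of 5 s cycles.
#'
#' @param g_exc_max Largest excitatory conductance (nS).
#' @param g_exc_step Excitatory increment per sweep (nS).
#' @param g_inh_step Inhibitory increment per sweep (nS).
#' @param tau_syn Synaptic time constant for both receptor types (ms).
#' @param e_exc,e_inh Excitatory/inhibitory reversal potentials (mV).
#' @param on On-phase duration (ms).
#' @param rest Silent rest after the on-phase (ms).
#' @param v_th,v_slope Presynaptic release threshold and slope (mV).
#' @return An object of class `synaptic_protocol`.
#' @export
synaptic_protocol <- function(g_exc_max = 25, g_exc_step = 0.5,
                              g_inh_step = 1, tau_syn = 10, e_exc = 0,
                              e_inh = -72, on = 2500, rest = 2500,
                              v_th = -30, v_slope = 20) {
  stopifnot(g_exc_max >= 0, g_exc_step > 0, g_inh_step >= 0, on > 0,
            rest >= 0)
  k <- 0:round(g_exc_max / g_exc_step)
  structure(list(g_exc = k * g_exc_step, g_inh = k * g_inh_step,
                 tau_syn = tau_syn, e_exc = e_exc, e_inh = e_inh, on = on,
                 rest = rest, v_th = v_th, v_slope = v_slope),
            class = "synaptic_protocol")
}

#' Run the current-step protocol on a model
#'
#' Settles the model to rest, then delivers all steps in order with state
#' carried over between sweeps. Spikes are counted within the step window
#' only.
#'
#' @param model A [neuron_model()].
#' @param protocol A [current_step_protocol()].
#' @param dt Integration step (ms).
#' @param record_trace Keep full somatic traces.
#' @param label Instance label for diagnostics.
#' @return A `vc_recording` (see [simulate_neuron()]) whose
#'   `stimulus$amplitude` column holds the step amplitudes.
#' @export
run_static_protocol <- function(model, protocol = current_step_protocol(),
                                dt = 0.025, record_trace = FALSE,
                                label = "model") {
  stopifnot(inherits(protocol, "current_step_protocol"))
  st <- settle_to_rest(model, dt = dt)
  sweeps <- lapply(protocol$amplitudes, function(a)
    sweep_def(len = protocol$cycle,
              t_end = c(protocol$pre, protocol$pre + protocol$duration),
              amp = c(0, a), win0 = protocol$pre,
              win1 = protocol$pre + protocol$duration))
  rec <- simulate_neuron(model, sweeps, dt = dt,
                         record_trace = record_trace,
                         init_state = st$state, label = label)
  rec$stimulus$amplitude <- protocol$amplitudes
  rec$protocol <- "static"
  rec$v_rest <- st$v_rest
  rec$settled <- st$converged
  rec
}

#' Run the synaptic-bombardment protocol on a model
#'
#' Settles the model to rest, then delivers the conductance schedule with the
#' two presynaptic waveforms replayed identically in every sweep, state
#' carried over between sweeps. Spikes are counted during the on-phase only.
#'
#' @inheritParams run_static_protocol
#' @param protocol A [synaptic_protocol()].
#' @param waveforms List with `exc` and `inh` presynaptic waveforms
#'   ([generate_presynaptic_waveform()]) covering the on-phase.
#' @return A `vc_recording`; `stimulus$g_ampa` / `stimulus$g_gaba` hold the
#'   conductance schedule.
#' @export
run_dynamic_protocol <- function(model, protocol = synaptic_protocol(),
                                 waveforms, dt = 0.025,
                                 record_trace = FALSE, label = "model") {
  stopifnot(inherits(protocol, "synaptic_protocol"))
  st <- settle_to_rest(model, dt = dt)
  len <- protocol$on + protocol$rest
  sweeps <- mapply(function(ge, gi)
    sweep_def(len = len, g_exc = ge, g_inh = gi, on_len = protocol$on,
              win0 = 0, win1 = protocol$on),
    protocol$g_exc, protocol$g_inh, SIMPLIFY = FALSE)
  syn <- default_synapse_params(tau = protocol$tau_syn,
                                e_exc = protocol$e_exc,
                                e_inh = protocol$e_inh,
                                v_th = protocol$v_th,
                                v_slope = protocol$v_slope)
  rec <- simulate_neuron(model, sweeps, dt = dt,
                         record_trace = record_trace,
                         init_state = st$state, waveforms = waveforms,
                         synapse = syn, label = label)
  rec$protocol <- "dynamic"
  rec$v_rest <- st$v_rest
  rec$settled <- st$converged
  rec
}
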