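# Simulation front end over the compiled fixed-step integrator.

#' Shared synaptic kinetics parameters
#'
#' @param tau Synaptic time constant (ms).
#' @param e_exc,e_inh Excitatory and inhibitory reversal potentials (mV).
#' @param v_th,v_slope Presynaptic release threshold and slope (mV).
#' @return Plain list consumed by [simulate_neuron()].
#' @export
default_synapse_params <- function(tau = 10, e_exc = 0, e_inh = -72,
                                   v_th = -30, v_slope = 20) {
  list(e_exc = e_exc, e_inh = e_inh, tau = tau, v_th = v_th,
       v_slope = v_slope)
}

#' Define one stimulus sweep
#'
#' Injected somatic current is piecewise constant: amplitude `amp[j]` holds
#' until time `t_end[j]` (ms from sweep start), zero afterwards. Synaptic
#' sweeps set `g_exc`/`g_inh` and the on-phase length; `win0`/`win1` bound
#' the analysis window used for spike counting and voltage summaries.
#'
#' @param len Sweep length (ms).
#' @param t_end,amp Segment end times (ms) and amplitudes (pA).
#' @param g_exc,g_inh Synaptic conductances (nS).
#' @param on_len Synaptic on-phase length (ms).
#' @param win0,win1 Analysis window bounds (ms).
#' @return Plain list consumed by [simulate_neuron()].
#' @export
sweep_def <- function(len, t_end = numeric(), amp = numeric(), g_exc = 0,
                      g_inh = 0, on_len = 0, win0 = 0, win1 = len) {
  stopifnot(length(t_end) == length(amp), len > 0)
  list(len = len, seg_t = as.numeric(t_end), seg_a = as.numeric(amp),
       g_exc = g_exc, g_inh = g_inh, on_len = on_len, win0 = win0,
       win1 = win1)
}

#' Relax a model to its resting state
#'
#' Integrates the model with zero input until the largest voltage derivative
#' falls below `tol`, returning the settled state. Models that do not
#' converge (e.g. spontaneously active instances) are returned with
#' `converged = FALSE` and a `spiked` flag.
#'
#' @param model A [neuron_model()].
#' @param max_time Maximum settling time (ms).
#' @param dt Integration step (ms).
#' @param tol Convergence tolerance on `|dV/dt|` (mV/ms).
#' @return List with `state`, `v_rest`, `converged`, `spiked`, `time`.
#' @export
settle_to_rest <- function(model, max_time = 8000, dt = 0.025, tol = 1e-5) {
  stopifnot(max_time > 0)
  cpp_settle(model_to_clist(model), dt, max_time, tol)
}

#' Simulate a model neuron over a sequence of stimulus sweeps
#'
#' Integrates all compartment voltages, gating variables, calcium pool and
#' synaptic activation states across the given sweeps with state carried over
#' from each sweep to the next (continuous-cycle stimulation). The first
#' sweep starts from `init_state` (typically a settled resting state).
#'
#' This is the low-level engine; use [run_static_protocol()] and
#' [run_dynamic_protocol()] for the two standard protocols.
#'
#' @param model A [neuron_model()].
#' @param sweeps List of sweep definitions (see [run_static_protocol()]).
#' @param dt Integration step (ms); must divide `record_interval`.
#' @param record_interval Sampling interval of recorded traces (ms).
#' @param record_trace Keep the somatic voltage traces (memory-heavy for
#'   long protocols; feature extraction only needs spike times and the
#'   per-sweep voltage summaries).
#' @param init_state State vector from [settle_to_rest()] or a previous run;
#'   `NULL` starts from the leak equilibrium.
#' @param waveforms List with elements `exc` and `inh`
#'   ([generate_presynaptic_waveform()]) for synaptically driven sweeps.
#' @param synapse Synaptic kinetics parameters shared by both receptor types
#'   (time constant, reversal potentials, release threshold and slope).
#' @param spike_threshold Somatic spike-detection threshold (mV).
#' @param refractory Spike-detection refractory guard (ms).
#' @param label Instance label used in diagnostics.
#' @return A `vc_recording` with per-sweep spike times, voltage summaries
#'   (`v_base`, `v_min`, `v_steady`, `v_end`), optional traces, and the final
#'   state.
#' @export
simulate_neuron <- function(model, sweeps, dt = 0.025,
                            record_interval = 0.05, record_trace = TRUE,
                            init_state = NULL, waveforms = NULL,
                            synapse = default_synapse_params(),
                            spike_threshold = -10, refractory = 2,
                            label = "model") {
  stopifnot(inherits(model, "neuron_model"), length(sweeps) >= 1, dt > 0)
  k <- record_interval / dt
  if (abs(k - round(k)) > 1e-8)
    stop("dt must divide record_interval")
  ml <- model_to_clist(model)
  if (is.null(init_state)) init_state <- cpp_init_state(ml)
  we <- if (!is.null(waveforms)) waveforms$exc$v else numeric()
  wi <- if (!is.null(waveforms)) waveforms$inh$v else numeric()
  wdt <- if (!is.null(waveforms)) waveforms$exc$dt else dt
  needs_syn <- any(vapply(sweeps, function(s) s$g_exc > 0 || s$g_inh > 0,
                          logical(1)))
  if (needs_syn && is.null(waveforms))
    stop("synaptic sweeps require presynaptic waveforms")
  if (needs_syn) {
    on_max <- max(vapply(sweeps, function(s) s$on_len, numeric(1)))
    if (length(we) * wdt < on_max || length(wi) * wdt < on_max)
      stop("presynaptic waveform shorter than the stimulation on-phase")
  }
  res <- cpp_simulate(ml, sweeps, we, wi, wdt, synapse, dt, record_interval,
                      record_trace, init_state, spike_threshold, refractory,
                      200)
  if (res$diverged > 0)
    stop(sprintf(
      "numerical divergence (|V| > 200 mV) for instance '%s' in sweep %d",
      label, res$diverged))
  structure(list(
    dt = record_interval,
    stimulus = data.frame(
      amplitude = vapply(sweeps, function(s)
        if (length(s$seg_a)) max(abs(s$seg_a)) * sign(s$seg_a[which.max(abs(s$seg_a))]) else 0,
        numeric(1)),
      g_ampa = vapply(sweeps, function(s) s$g_exc, numeric(1)),
      g_gaba = vapply(sweeps, function(s) s$g_inh, numeric(1))),
    window = cbind(win0 = vapply(sweeps, function(s) s$win0, numeric(1)),
                   win1 = vapply(sweeps, function(s) s$win1, numeric(1))),
    spikes = res$spikes, summary = res$summary,
    traces = if (record_trace) res$trace,
    state = res$state, label = label,
    spike_threshold = spike_threshold, refractory = refractory),
    class = "vc_recording")
}

#' @export
print.vc_recording <- function(x, ...) {
  n <- length(x$spikes)
  counts <- sweep_spike_counts(x)
  cat(sprintf("<vc_recording> %d sweeps, sample interval %g ms\n", n, x$dt))
  cat(sprintf("  spikes in analysis windows: %d (per sweep: %s%s)\n",
              sum(counts), paste(utils::head(counts, 12), collapse = " "),
              if (n > 12) " ..." else ""))
  invisible(x)
}

#' @export
plot.vc_recording <- function(x, sweep = 1, ...) {
  if (is.null(x$traces))
    stop("recording was made with record_trace = FALSE")
  v <- x$traces[[sweep]]
  t <- (seq_along(v) - 1) * x$dt
  graphics::plot(t, v, type = "l", xlab = "time (ms)",
                 ylab = "somatic V (mV)",
                 main = sprintf("%s, sweep %d", x$label, sweep), ...)
  graphics::abline(v = x$window[sweep, ], lty = 3, col = "grey50")
  invisible(x)
}

# Spike counts inside each sweep's analysis window.
sweep_spike_counts <- function(rec) {
  vapply(seq_along(rec$spikes), function(i) {
    s <- rec$spikes[[i]]
    sum(s >= rec$window[i, 1] & s <= rec$window[i, 2])
  }, integer(1))
}
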