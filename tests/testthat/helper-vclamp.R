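# Shared fixtures built in code.

# A minimal recording object carrying given per-sweep spike times, for
# feature-extraction tests that do not need a simulation.
fake_recording <- function(spikes, amplitude = NULL, g_ampa = NULL,
                           window = c(0, 400), protocol = "static") {
  n <- length(spikes)
  if (is.null(amplitude)) amplitude <- seq_len(n)
  if (is.null(g_ampa)) g_ampa <- rep(0, n)
  structure(list(
    dt = 0.05, protocol = protocol,
    stimulus = data.frame(amplitude = amplitude, g_ampa = g_ampa,
                          g_gaba = rep(0, n)),
    window = cbind(win0 = rep(window[1], n), win1 = rep(window[2], n)),
    spikes = lapply(spikes, as.numeric),
    summary = NULL, traces = NULL, label = "fake"),
    class = "vc_recording")
}

# Passive three-compartment cell (no voltage-gated currents).
passive_model <- function(g_leak = c(2, 0, 0), e_leak = -70,
                          capacitance = c(16, 3, 8), g_sx = 0, g_sd = 0) {
  neuron_model(capacitance, g_leak, e_leak, g_sx, g_sd, currents = list())
}

# A compact step protocol for desk-scale runs.
coarse_steps <- function(increment = 20)
  current_step_protocol(increment = increment)

run_counts <- function(rec) cumulative_spike_count(io_curve(rec))
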