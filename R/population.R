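# Population synthesis: Gaussian parameter variation around the canonical
# phenotype models, and the leaky integrate-and-fire control population.

#' Sample a biophysically diverse model population
#'
#' Draws `n` model instances with each varied parameter taken from a
#' Gaussian with the distribution table's mean and SD. Draws that would be
#' negative for nonnegative parameters (conductances, capacitance scale,
#' couplings) are resampled rather than clipped, which preserves the mean
#' approximately. Identical seeds give identical populations.
#'
#' @param dist A [phenotype_distribution()] or a phenotype name.
#' @param n Number of instances, at least 1.
#' @param seed Integer seed.
#' @return List of [neuron_model()] objects; each carries an
#'   `instance` attribute, and the list carries a `manifest` attribute (one
#'   row per instance with all sampled parameter values and the seed).
#' @export
sample_population <- function(dist, n, seed = 1) {
  if (is.character(dist)) dist <- phenotype_distribution(dist)
  stopifnot(inherits(dist, "phenotype_distribution"), n >= 1)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed))
  tab <- dist$table
  nonneg <- tab$parameter != "e_leak"
  draws <- matrix(NA_real_, n, nrow(tab),
                  dimnames = list(NULL, tab$parameter))
  for (j in seq_len(nrow(tab))) {
    x <- stats::rnorm(n, tab$mean[j], tab$sd[j])
    if (nonneg[j]) {
      bad <- which(x < 0)
      while (length(bad)) {
        x[bad] <- stats::rnorm(length(bad), tab$mean[j], tab$sd[j])
        bad <- bad[x[bad] < 0]
      }
    }
    draws[, j] <- x
  }
  models <- lapply(seq_len(n), function(i) {
    m <- dist$model
    for (cur in names(m$currents))
      m$currents[[cur]]$g_total <- draws[[i, paste0("g_", cur)]]
    m$capacitance <- m$capacitance * draws[[i, "cap_scale"]]
    m$e_leak <- draws[[i, "e_leak"]]
    m$g_sx <- draws[[i, "g_sx"]]
    m$g_sd <- draws[[i, "g_sd"]]
    attr(m, "instance") <- i
    m
  })
  attr(models, "manifest") <- data.frame(phenotype = dist$phenotype,
                                         instance = seq_len(n), seed = seed,
                                         draws, check.names = FALSE)
  attr(models, "phenotype") <- dist$phenotype
  models
}

#' Write a population manifest as delimited text
#'
#' One row per instance with all sampled parameter values and the seed.
#'
#' @param models Result of [sample_population()].
#' @param path Output path (tab-separated).
#' @export
write_population_manifest <- function(models, path) {
  man <- attr(models, "manifest")
  if (is.null(man)) stop("population has no manifest")
  utils::write.table(man, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

# --- leaky integrate-and-fire control ---------------------------------------

#' Leaky integrate-and-fire model
#'
#' Passive RC subthreshold dynamics with a hard spike threshold, reset and
#' absolute refractory period. Used as the passive-membrane control
#' population: a model family whose excitability is set only by passive
#' parameters and a threshold.
#'
#' @param cap Membrane capacitance (pF), positive.
#' @param g_leak Leak conductance (nS), positive.
#' @param e_leak Leak reversal potential (mV).
#' @param v_th Spike threshold (mV), above `v_reset`.
#' @param v_reset Post-spike reset potential (mV).
#' @param t_ref Absolute refractory period (ms).
#' @return An object of class `lif_model`.
#' @export
lif_model <- function(cap = 80, g_leak = 4, e_leak = -65, v_th = -45,
                      v_reset = -60, t_ref = 3) {
  stopifnot(cap > 0, g_leak > 0, v_th > v_reset, t_ref >= 0)
  structure(list(cap = cap, g_leak = g_leak, e_leak = e_leak, v_th = v_th,
                 v_reset = v_reset, t_ref = t_ref), class = "lif_model")
}

#' Sample a LIF control population
#'
#' Varies exactly four parameters: membrane capacitance, leak conductance,
#' leak reversal potential and spike threshold. Capacitance and conductance
#' use the relative coefficient of variation `cv`; the two voltages use the
#' absolute SDs `sd_e_leak` and `sd_v_th` (mV). Draws violating positivity
#' or `v_th > v_reset` are resampled. Reset and refractory period are fixed.
#'
#' @param nominal A [lif_model()] with the nominal parameter values.
#' @param cv Coefficient of variation of capacitance and leak conductance.
#' @param n Number of instances.
#' @param seed Integer seed.
#' @param sd_e_leak,sd_v_th Absolute SDs of the varied voltages (mV).
#' @return List of `lif_model` objects with a `manifest` attribute.
#' @export
sample_lif_population <- function(nominal = lif_model(), cv = 0.05, n = 200,
                                  seed = 1, sd_e_leak = 1, sd_v_th = 4) {
  stopifnot(inherits(nominal, "lif_model"), n >= 1, cv >= 0)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed))
  draw_pos <- function(n, mean, sd) {
    x <- stats::rnorm(n, mean, sd)
    bad <- which(x <= 0)
    while (length(bad)) {
      x[bad] <- stats::rnorm(length(bad), mean, sd)
      bad <- bad[x[bad] <= 0]
    }
    x
  }
  cap <- draw_pos(n, nominal$cap, cv * nominal$cap)
  g_l <- draw_pos(n, nominal$g_leak, cv * nominal$g_leak)
  e_l <- stats::rnorm(n, nominal$e_leak, sd_e_leak)
  v_th <- stats::rnorm(n, nominal$v_th, sd_v_th)
  bad <- which(v_th <= nominal$v_reset)
  while (length(bad)) {
    v_th[bad] <- stats::rnorm(length(bad), nominal$v_th, sd_v_th)
    bad <- bad[v_th[bad] <= nominal$v_reset]
  }
  models <- lapply(seq_len(n), function(i) {
    m <- lif_model(cap[i], g_l[i], e_l[i], v_th[i], nominal$v_reset,
                   nominal$t_ref)
    attr(m, "instance") <- i
    m
  })
  attr(models, "manifest") <- data.frame(instance = seq_len(n), seed = seed,
                                         cap = cap, g_leak = g_l,
                                         e_leak = e_l, v_th = v_th)
  models
}

#' Simulate a LIF model over stimulus sweeps
#'
#' Subthreshold dynamics are a passive RC membrane (plus conductance-clamp
#' synaptic current for synaptic sweeps); a spike is emitted when the
#' voltage crosses threshold, after which the voltage is held at the reset
#' value for the refractory period. State carries over between sweeps.
#'
#' @param model A [lif_model()].
#' @param sweeps Sweep definitions as in [simulate_neuron()].
#' @param dt Integration step (ms).
#' @param waveforms,synapse As in [simulate_neuron()].
#' @param label Instance label.
#' @return A `vc_recording` (no traces, no voltage summaries).
#' @export
lif_simulate <- function(model, sweeps, dt = 0.025, waveforms = NULL,
                         synapse = default_synapse_params(),
                         label = "lif") {
  stopifnot(inherits(model, "lif_model"))
  we <- if (!is.null(waveforms)) waveforms$exc$v else numeric()
  wi <- if (!is.null(waveforms)) waveforms$inh$v else numeric()
  wdt <- if (!is.null(waveforms)) waveforms$exc$dt else dt
  res <- cpp_lif_simulate(unclass(model), sweeps, we, wi, wdt, synapse, dt)
  structure(list(
    dt = dt,
    stimulus = data.frame(
      amplitude = vapply(sweeps, function(s)
        if (length(s$seg_a)) s$seg_a[length(s$seg_a)] else 0, numeric(1)),
      g_ampa = vapply(sweeps, function(s) s$g_exc, numeric(1)),
      g_gaba = vapply(sweeps, function(s) s$g_inh, numeric(1))),
    window = cbind(win0 = vapply(sweeps, function(s) s$win0, numeric(1)),
                   win1 = vapply(sweeps, function(s) s$win1, numeric(1))),
    spikes = res$spikes, summary = NULL, traces = NULL, label = label),
    class = "vc_recording")
}

#' Run the two standard protocols on a LIF model
#'
#' @param model A [lif_model()].
#' @param protocol A [current_step_protocol()] or [synaptic_protocol()].
#' @param waveforms Required for the synaptic protocol.
#' @param dt Integration step (ms).
#' @param label Instance label.
#' @return A `vc_recording`.
#' @export
run_lif_protocol <- function(model, protocol, waveforms = NULL, dt = 0.025,
                             label = "lif") {
  if (inherits(protocol, "current_step_protocol")) {
    sweeps <- lapply(protocol$amplitudes, function(a)
      sweep_def(len = protocol$cycle,
                t_end = c(protocol$pre, protocol$pre + protocol$duration),
                amp = c(0, a), win0 = protocol$pre,
                win1 = protocol$pre + protocol$duration))
    rec <- lif_simulate(model, sweeps, dt = dt, label = label)
    rec$stimulus$amplitude <- protocol$amplitudes
    rec$protocol <- "static"
  } else if (inherits(protocol, "synaptic_protocol")) {
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
    rec <- lif_simulate(model, sweeps, dt = dt, waveforms = waveforms,
                        synapse = syn, label = label)
    rec$protocol <- "dynamic"
  } else stop("unknown protocol class")
  rec
}
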