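COMPARTMENTS <- c("soma", "axon", "dend")

#' Ionic membrane current specification
#'
#' One Hodgkin-Huxley-type current
#' \eqn{I_i = g_i\, m^p\, h\, (E_i - V)} with activation `m` (exponent `p`
#' taken from the activation [gating_spec()]), optional inactivation `h`, and
#' a fixed split of the total conductance over the soma, axon and dendrite
#' compartments. Calcium-activated currents (`kca = TRUE`) replace the
#' voltage-gated activation by the saturating function
#' `Ca / (Ca + kca_half)` of the local calcium level.
#'
#' @param name Current identifier, e.g. `"Na"`, `"Kd"`, `"Kir"`, `"D"`,
#'   `"h"`, `"CaT"`, `"KCa"`.
#' @param g_total Total maximal conductance (nS), nonnegative.
#' @param e_rev Reversal potential (mV).
#' @param activation A [gating_spec()] (ignored when `kca = TRUE`).
#' @param inactivation Optional [gating_spec()] for the inactivation gate.
#' @param split Length-3 numeric, fractions of `g_total` on
#'   soma/axon/dendrite; must sum to 1.
#' @param kca Calcium-activated current (no voltage gating).
#' @param ca_source Whether this current carries the calcium influx feeding
#'   the intracellular pool (e.g. `"CaT"`).
#' @return An object of class `ionic_current_spec`.
#' @export
ionic_current_spec <- function(name, g_total, e_rev, activation = NULL,
                               inactivation = NULL,
                               split = c(1, 0, 0), kca = FALSE,
                               ca_source = FALSE) {
  stopifnot(is.character(name), g_total >= 0, length(split) == 3,
            all(split >= 0), all(split <= 1),
            abs(sum(split) - 1) < 1e-9)
  if (!kca && !inherits(activation, "gating_spec"))
    stop("a voltage-gated current needs an activation gating_spec")
  if (!is.null(inactivation) && !inherits(inactivation, "gating_spec"))
    stop("inactivation must be a gating_spec or NULL")
  structure(list(name = name, g_total = as.numeric(g_total),
                 e_rev = as.numeric(e_rev), activation = activation,
                 inactivation = inactivation,
                 split = stats::setNames(as.numeric(split), COMPARTMENTS),
                 kca = isTRUE(kca), ca_source = isTRUE(ca_source)),
            class = "ionic_current_spec")
}

#' Intracellular calcium dynamics specification
#'
#' Minimal first-order pool: influx proportional to the (depolarizing part of
#' the) calcium current, exponential removal toward a resting level, and a
#' saturating half-activation constant for calcium-activated K-currents.
#'
#' @param gain Influx gain (concentration units per pA per ms).
#' @param rest Resting calcium level (concentration units), nonnegative.
#' @param tau Removal time constant (ms), positive.
#' @param kca_half Half-activation calcium level of the KCa current.
#' @return An object of class `calcium_spec`.
#' @export
calcium_spec <- function(gain = 0.002, rest = 0.05, tau = 150,
                         kca_half = 1) {
  stopifnot(tau > 0, rest >= 0, gain >= 0, kca_half > 0)
  structure(list(gain = gain, rest = rest, tau = tau, kca_half = kca_half),
            class = "calcium_spec")
}

#' Three-compartment conductance-based neuron model
#'
#' A somatic, axonic and dendritic compartment, each with its own capacitance
#' and leak conductance, electrically coupled soma-axon (`g_sx`) and
#' soma-dendrite (`g_sd`), carrying a set of [ionic_current_spec()] currents.
#'
#' @param capacitance Length-3 numeric (pF) for soma, axon, dendrite.
#' @param g_leak Length-3 numeric leak conductances (nS).
#' @param e_leak Leak reversal potential (mV).
#' @param g_sx Soma-axon coupling conductance (nS).
#' @param g_sd Soma-dendrite coupling conductance (nS).
#' @param currents List of [ionic_current_spec()].
#' @param calcium Optional [calcium_spec()]; required when any current is
#'   calcium-activated or a calcium source.
#' @param phenotype One of `"regular"`, `"delayed"`, `"stuttering"` or `NA`.
#' @return An object of class `neuron_model`.
#' @export
neuron_model <- function(capacitance, g_leak, e_leak, g_sx, g_sd,
                         currents = list(), calcium = NULL,
                         phenotype = NA_character_) {
  stopifnot(length(capacitance) == 3, length(g_leak) == 3,
            all(capacitance > 0), all(g_leak >= 0), g_sx >= 0, g_sd >= 0)
  nm <- vapply(currents, function(x) {
    stopifnot(inherits(x, "ionic_current_spec"))
    x$name
  }, character(1))
  if (anyDuplicated(nm)) stop("duplicate current names")
  needs_ca <- any(vapply(currents, function(x) x$kca || x$ca_source,
                         logical(1)))
  if (needs_ca && is.null(calcium))
    stop("calcium dynamics required by a KCa or Ca-source current")
  if (!is.na(phenotype))
    phenotype <- match.arg(phenotype, c("regular", "delayed", "stuttering"))
  structure(list(
    capacitance = stats::setNames(as.numeric(capacitance), COMPARTMENTS),
    g_leak = stats::setNames(as.numeric(g_leak), COMPARTMENTS),
    e_leak = as.numeric(e_leak), g_sx = as.numeric(g_sx),
    g_sd = as.numeric(g_sd),
    currents = stats::setNames(currents, nm), calcium = calcium,
    phenotype = phenotype), class = "neuron_model")
}

#' @export
print.neuron_model <- function(x, ...) {
  cat(sprintf("<neuron_model> phenotype: %s\n", x$phenotype))
  cat(sprintf("  C_m (pF): soma %g, axon %g, dend %g; E_L = %g mV\n",
              x$capacitance[1], x$capacitance[2], x$capacitance[3],
              x$e_leak))
  cat(sprintf("  g_leak (nS): %s; coupling g_sx = %g, g_sd = %g nS\n",
              paste(signif(x$g_leak, 3), collapse = "/"), x$g_sx, x$g_sd))
  for (cur in x$currents)
    cat(sprintf("  I_%-4s g = %7.2f nS, E = %6.1f mV, split %s\n",
                cur$name, cur$g_total, cur$e_rev,
                paste(signif(cur$split, 2), collapse = "/")))
  invisible(x)
}

#' Somatic/axonal/dendritic current carried by one ionic current
#'
#' Evaluates \eqn{I = g\, m^p\, h\, (E - V)} for the compartment's allocated
#' share of the total conductance. Positive values depolarize.
#'
#' @param v Membrane potential (mV).
#' @param m Activation level in `[0, 1]`.
#' @param h Inactivation level in `[0, 1]`; use 1 for currents without
#'   inactivation.
#' @param spec An [ionic_current_spec()].
#' @param compartment `"soma"`, `"axon"` or `"dend"`.
#' @return Current in pA.
#' @export
ionic_current <- function(v, m, h = 1, spec,
                          compartment = c("soma", "axon", "dend")) {
  compartment <- match.arg(compartment)
  stopifnot(all(m >= 0 & m <= 1), all(h >= 0 & h <= 1))
  p <- if (is.null(spec$activation)) 1L else spec$activation$p
  g <- spec$g_total * spec$split[[compartment]]
  g * m^p * h * (spec$e_rev - v)
}

# --- virtual pharmacology and kinetic manipulations -------------------------

#' Remove a current from a model (virtual pharmacology)
#'
#' Returns a copy of the model with the named current's total conductance set
#' to zero, emulating a complete pharmacological block.
#'
#' @param model A [neuron_model()].
#' @param name Current name present in the model.
#' @return The modified model; the input is untouched.
#' @export
block_current <- function(model, name) {
  cur <- find_current(model, name)
  model$currents[[name]]$g_total <- 0
  model
}

#' Shift the activation midpoint of a current
#'
#' Sets the activation `V_1/2` to `v_half`; with `couple_inactivation = TRUE`
#' the inactivation midpoint is shifted by the same amount, preserving the
#' overlap of the steady-state activation and inactivation curves.
#'
#' @inheritParams block_current
#' @param v_half New activation midpoint (mV).
#' @param couple_inactivation Shift the inactivation curve synchronously.
#' @return The modified model.
#' @export
shift_activation_midpoint <- function(model, name, v_half,
                                      couple_inactivation = FALSE) {
  cur <- find_current(model, name)
  if (is.null(cur$activation)) stop("current has no voltage-gated activation")
  dv <- v_half - cur$activation$v_half
  model$currents[[name]]$activation$v_half <- v_half
  if (couple_inactivation) {
    if (is.null(cur$inactivation))
      stop(sprintf("current '%s' has no inactivation to couple", name))
    model$currents[[name]]$inactivation$v_half <-
      cur$inactivation$v_half + dv
  }
  model
}

#' Rescale the time constants of a current
#'
#' Multiplies the activation `tau_max` and `tau_min` by
#' `tau_max / old tau_max`; with `couple_inactivation = TRUE` the inactivation
#' time constants are scaled by the same factor so their ratio to the
#' activation kinetics is preserved.
#'
#' @inheritParams block_current
#' @param tau_max New maximal activation time constant (ms), positive.
#' @param couple_inactivation Co-scale the inactivation kinetics.
#' @return The modified model.
#' @export
scale_time_constants <- function(model, name, tau_max,
                                 couple_inactivation = FALSE) {
  stopifnot(tau_max > 0)
  cur <- find_current(model, name)
  if (is.null(cur$activation)) stop("current has no voltage-gated activation")
  f <- tau_max / cur$activation$tau_max
  model$currents[[name]]$activation$tau_max <- cur$activation$tau_max * f
  model$currents[[name]]$activation$tau_min <- cur$activation$tau_min * f
  if (couple_inactivation) {
    if (is.null(cur$inactivation))
      stop(sprintf("current '%s' has no inactivation to couple", name))
    model$currents[[name]]$inactivation$tau_max <- cur$inactivation$tau_max * f
    model$currents[[name]]$inactivation$tau_min <- cur$inactivation$tau_min * f
  }
  model
}

find_current <- function(model, name) {
  stopifnot(inherits(model, "neuron_model"))
  if (!name %in% names(model$currents))
    stop(sprintf("model has no current named '%s'", name))
  model$currents[[name]]
}

# Convert a neuron_model to the flat list consumed by the compiled core.
model_to_clist <- function(model) {
  list(
    cap = unname(model$capacitance),
    g_leak = unname(model$g_leak),
    e_leak = model$e_leak, g_sx = model$g_sx, g_sd = model$g_sd,
    currents = lapply(unname(model$currents), function(cur) {
      gate_vec <- function(g)
        c(g$v_half, g$v_slope, g$tau_max, g$tau_min, g$v_tau_half,
          g$v_tau_slope)
      list(e_rev = cur$e_rev,
           p = if (is.null(cur$activation)) 1L else cur$activation$p,
           kca = cur$kca, ca_source = cur$ca_source,
           g = unname(cur$g_total * cur$split),
           act = if (!cur$kca) gate_vec(cur$activation) else rep(0, 6),
           inact = if (!is.null(cur$inactivation))
             gate_vec(cur$inactivation) else NULL)
    }),
    calcium = if (!is.null(model$calcium))
      list(gain = model$calcium$gain, rest = model$calcium$rest,
           tau = model$calcium$tau, kca_half = model$calcium$kca_half)
  )
}
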