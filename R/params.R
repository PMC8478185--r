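# Canonical phenotype parameter tables.
#
# These tables are synthetic: they were designed and calibrated within this
# package so that the three canonical models reproduce the published
# qualitative signatures of cultured hippocampal phenotypes (continuous
# monotone I-O with sag for regular firing; inward rectification, voltage
# ramp and long first-spike latency for delayed firing; low input
# resistance, single spike near rheobase, discontinuous I-O and a
# repetitive-firing transition near +195 pA for stuttering), with the Kir
# kinetics anchored at V_1/2 = -91 mV and tau_max = 10 ms and the D-current
# activation time constant within the 2-18 ms range spanned by the kinetic
# sweeps. See the methods vignette for the design rationale.

e_na <- 50
e_k <- -90
e_h <- -35
e_ca <- 120

na_current <- function(g_total) {
  ionic_current_spec(
    "Na", g_total, e_na,
    activation = gating_spec(-35, 7, 0.15, 0.04, -40, 25, p = 3L),
    inactivation = gating_spec(-45, -6, 4, 0.3, -50, 18),
    split = c(0.4, 0.6, 0))
}

kd_current <- function(g_total) {
  ionic_current_spec(
    "Kd", g_total, e_k,
    activation = gating_spec(-33, 11, 3, 0.4, -40, 30, p = 4L),
    split = c(0.4, 0.5, 0.1))
}

h_current <- function(g_total) {
  ionic_current_spec(
    "h", g_total, e_h,
    activation = gating_spec(-82, -9, 500, 60, -85, 20),
    split = c(0.5, 0, 0.5))
}

kir_current <- function(g_total) {
  ionic_current_spec(
    "Kir", g_total, e_k,
    activation = gating_spec(-91, -22, 10, 10, -90, 30),
    split = c(0.1, 0, 0.9))
}

d_current <- function(g_total) {
  ionic_current_spec(
    "D", g_total, e_k,
    activation = gating_spec(-40, 10, 10, 2, -50, 30),
    inactivation = gating_spec(-62, -9, 600, 450, -60, 40),
    split = c(0.6, 0.2, 0.2))
}

cat_current <- function(g_total) {
  ionic_current_spec(
    "CaT", g_total, e_ca,
    activation = gating_spec(-52, 7, 5, 1, -60, 20, p = 2L),
    inactivation = gating_spec(-72, -7, 40, 15, -70, 20),
    split = c(0.5, 0, 0.5), ca_source = TRUE)
}

kca_current <- function(g_total) {
  ionic_current_spec("KCa", g_total, e_k, split = c(1, 0, 0), kca = TRUE)
}

# high-threshold Ca current: engages only during spikes, feeding the Ca pool
# that drives spike-frequency adaptation through KCa
cah_current <- function(g_total) {
  ionic_current_spec(
    "CaH", g_total, e_ca,
    activation = gating_spec(-20, 6, 1.5, 0.5, -30, 20, p = 2L),
    split = c(1, 0, 0), ca_source = TRUE)
}

#' Canonical (mean-parameter) phenotype models
#'
#' Deterministic parameter sets for the three phenotypes: the regular firing
#' model carries Na, Kd, I_h and a small CaT/KCa pair; the delayed firing
#' model adds the inward-rectifier K-current (I_Kir, activation midpoint
#' -91 mV); the stuttering model carries a potent slowly
#' activating/inactivating D-current plus I_h. The tables are synthetic
#' calibrations, not published values (see the package vignette).
#'
#' @param phenotype `"regular"`, `"delayed"` or `"stuttering"`.
#' @return A [neuron_model()].
#' @export
canonical_model <- function(phenotype = c("regular", "delayed",
                                          "stuttering")) {
  phenotype <- match.arg(phenotype)
  switch(phenotype,
    regular = neuron_model(
      capacitance = c(16, 3, 8), g_leak = c(1.2, 0.2, 0.8), e_leak = -70,
      g_sx = 25, g_sd = 6,
      currents = list(na_current(450), kd_current(250), h_current(3),
                      cat_current(2), kca_current(5)),
      calcium = calcium_spec(gain = 0.001, rest = 0.05, tau = 600,
                             kca_half = 1),
      phenotype = "regular"),
    delayed = neuron_model(
      capacitance = c(16, 3, 8), g_leak = c(0.8, 0.15, 0.5), e_leak = -50,
      g_sx = 25, g_sd = 6,
      currents = list(na_current(450), kd_current(250), kir_current(35),
                      cah_current(2), kca_current(3)),
      calcium = calcium_spec(gain = 0.001, rest = 0.05, tau = 600,
                             kca_half = 1),
      phenotype = "delayed"),
    stuttering = neuron_model(
      capacitance = c(16, 3, 8), g_leak = c(4.2, 0.5, 2.3), e_leak = -62,
      g_sx = 25, g_sd = 6,
      currents = list(na_current(450), kd_current(250), d_current(14),
                      h_current(2.5)),
      phenotype = "stuttering"))
}

#' Gaussian variation table for a phenotype population
#'
#' Mean and standard deviation for every varied parameter: the maximal
#' conductance of each voltage-gated current, the membrane capacitance (one
#' common scale factor over the three compartments), the leak reversal
#' potential, and the two compartment coupling conductances. Non-varied
#' parameters stay at the canonical values. The dispersion values are
#' synthetic design choices (current conductances 25% CV, couplings 15% CV,
#' capacitance 10% CV, leak reversal SD 2 mV).
#'
#' @inheritParams canonical_model
#' @return An object of class `phenotype_distribution`: list with the
#'   canonical `model` and a data.frame `table` of `parameter`, `mean`,
#'   `sd`.
#' @export
phenotype_distribution <- function(phenotype = c("regular", "delayed",
                                                 "stuttering")) {
  phenotype <- match.arg(phenotype)
  model <- canonical_model(phenotype)
  g <- vapply(model$currents, function(x) x$g_total, numeric(1))
  # the inward rectifier is dispersed less than the other currents: its
  # strength sets the delayed-firing resting level, and moderate variation
  # already spans the observed range of rectification
  cv_g <- ifelse(names(model$currents) == "Kir", 0.10, 0.25)
  tab <- data.frame(
    parameter = c(paste0("g_", names(model$currents)), "cap_scale",
                  "e_leak", "g_sx", "g_sd"),
    mean = c(unname(g), 1, model$e_leak, model$g_sx, model$g_sd),
    sd = c(unname(g) * cv_g, 0.10, 2, model$g_sx * 0.15,
           model$g_sd * 0.15))
  structure(list(phenotype = phenotype, model = model, table = tab),
            class = "phenotype_distribution")
}

#' @export
print.phenotype_distribution <- function(x, ...) {
  cat(sprintf("<phenotype_distribution> %s\n", x$phenotype))
  print(x$table, row.names = FALSE)
  invisible(x)
}
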