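# Model construction, virtual pharmacology, kinetic manipulations and the
# structured-text configuration round trip.

test_that("constructors validate their invariants", {
  act <- gating_spec(-40, 10, 5, 1, -50, 20)
  expect_error(ionic_current_spec("Kd", 10, -90, activation = act,
                                  split = c(0.6, 0.6, 0)))
  expect_error(ionic_current_spec("Kd", -1, -90, activation = act))
  expect_error(ionic_current_spec("Kd", 10, -90, activation = NULL))
  cur <- ionic_current_spec("Kd", 10, -90, activation = act)
  expect_error(neuron_model(c(16, 3), c(1, 1, 1), -70, 1, 1))
  expect_error(neuron_model(c(16, 3, 8), c(1, 1, 1), -70, 1, 1,
                            currents = list(cur, cur)))
  expect_error(neuron_model(c(16, 3, 8), c(1, 1, 1), -70, 1, 1,
                            currents = list(
                              ionic_current_spec("KCa", 5, -90,
                                                 kca = TRUE))))
  expect_error(calcium_spec(tau = 0))
  expect_error(lif_model(v_th = -60, v_reset = -50))
})

test_that("block_current zeroes the conductance on a copy only", {
  m <- canonical_model("delayed")
  g0 <- m$currents$Kir$g_total
  mb <- block_current(m, "Kir")
  expect_identical(mb$currents$Kir$g_total, 0)
  expect_identical(m$currents$Kir$g_total, g0)
  expect_error(block_current(m, "D"))
  # blocking an already-zero current leaves behaviour unchanged
  mbb <- block_current(mb, "Kir")
  expect_identical(vclamp:::model_to_clist(mbb),
                   vclamp:::model_to_clist(mb))
})

test_that("midpoint shifts preserve the act/inact overlap when coupled", {
  m <- canonical_model("stuttering")
  gap0 <- m$currents$D$activation$v_half - m$currents$D$inactivation$v_half
  ms <- shift_activation_midpoint(m, "D", -30, couple_inactivation = TRUE)
  expect_equal(ms$currents$D$activation$v_half, -30)
  expect_equal(ms$currents$D$activation$v_half -
                 ms$currents$D$inactivation$v_half, gap0)
  # zero shift leaves the model identical
  m0 <- shift_activation_midpoint(m, "D",
                                  m$currents$D$activation$v_half,
                                  couple_inactivation = TRUE)
  expect_identical(vclamp:::model_to_clist(m0),
                   vclamp:::model_to_clist(m))
  # coupling without an inactivation gate is an error
  expect_error(shift_activation_midpoint(canonical_model("delayed"),
                                         "Kir", -80,
                                         couple_inactivation = TRUE))
})

test_that("time-constant scaling preserves ratios", {
  m <- canonical_model("stuttering")
  d0 <- m$currents$D
  ratio0 <- d0$inactivation$tau_max / d0$activation$tau_max
  minr0 <- d0$activation$tau_min / d0$activation$tau_max
  ms <- scale_time_constants(m, "D", 18, couple_inactivation = TRUE)
  d1 <- ms$currents$D
  expect_equal(d1$activation$tau_max, 18)
  expect_equal(d1$inactivation$tau_max / d1$activation$tau_max, ratio0)
  expect_equal(d1$activation$tau_min / d1$activation$tau_max, minr0)
  # factor one is the identity
  m1 <- scale_time_constants(m, "D", d0$activation$tau_max,
                             couple_inactivation = TRUE)
  expect_identical(vclamp:::model_to_clist(m1),
                   vclamp:::model_to_clist(m))
})

test_that("sweep grids for the kinetic experiments have 9 settings", {
  expect_length(seq(-91, -75, by = 2), 9)
  expect_length(seq(10, 130, by = 15), 9)
  expect_length(seq(2, 18, by = 2), 9)
})

test_that("model configuration round-trips bit-exactly", {
  for (ph in c("regular", "delayed", "stuttering")) {
    m <- canonical_model(ph)
    # perturb with irrational-ish values to exercise full precision
    m$currents$Na$g_total <- m$currents$Na$g_total * (1 + pi * 1e-3)
    m$e_leak <- m$e_leak + sqrt(2) * 1e-6
    path <- withr::local_tempfile(fileext = ".cfg")
    write_model_config(m, path)
    m2 <- read_model_config(path)
    expect_identical(m2$e_leak, m$e_leak)
    expect_identical(m2$capacitance, m$capacitance)
    expect_identical(m2$g_leak, m$g_leak)
    expect_identical(lapply(m2$currents, unclass),
                     lapply(m$currents, unclass))
    expect_identical(vclamp:::model_to_clist(m2),
                     vclamp:::model_to_clist(m))
  }
})

test_that("canonical models carry the phenotype-defining currents", {
  expect_true("Kir" %in% names(canonical_model("delayed")$currents))
  expect_true("D" %in% names(canonical_model("stuttering")$currents))
  expect_true("h" %in% names(canonical_model("regular")$currents))
  expect_true("h" %in% names(canonical_model("stuttering")$currents))
  # deterministic construction
  expect_identical(canonical_model("delayed"), canonical_model("delayed"))
  expect_error(canonical_model("bursting"))
})
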