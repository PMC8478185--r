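# Gating kinetics: sigmoid steady states, bell-shaped time constants,
# exponential-Euler updates, ionic and synaptic currents.

# independent series evaluation of tanh, used as the oracle for the
# sigmoid examples
tanh_series <- function(x) {
  # tanh(x) = (e^x - e^-x)/(e^x + e^-x) with exp from its power series
  exp_series <- function(z) {
    term <- 1
    s <- 1
    for (k in 1:40) {
      term <- term * z / k
      s <- s + term
    }
    s
  }
  (exp_series(x) - exp_series(-x)) / (exp_series(x) + exp_series(-x))
}

test_that("steady state is a sigmoid with the documented anchors", {
  sp <- gating_spec(v_half = -40, v_slope = 10, tau_max = 5, tau_min = 1,
                    v_tau_half = -40, v_tau_slope = 20)
  expect_equal(steady_state(-40, sp), 0.5)
  expect_equal(steady_state(1e4, sp), 1.0)
  expect_equal(steady_state(-1e4, sp), 0.0)
  # one slope-length above midpoint: 1/2 + 1/2 tanh(1), via the series oracle
  expect_equal(steady_state(-30, sp), 0.5 + 0.5 * tanh_series(1),
               tolerance = 1e-12)
  # negative slope reverses the orientation
  spn <- gating_spec(-40, -10, 5, 1, -40, 20)
  expect_equal(steady_state(1e4, spn), 0.0)
  expect_equal(steady_state(-1e4, spn), 1.0)
})

test_that("steady state is monotone in V with the sign of the slope", {
  set.seed(7)
  for (i in 1:20) {
    vs <- sample(c(-1, 1), 1) * runif(1, 5, 30)
    vh <- runif(1, -90, -20)
    # stay inside the floating-point-resolvable flanks of the sigmoid
    v <- seq(vh - 4 * abs(vs), vh + 4 * abs(vs), length.out = 200)
    sp <- gating_spec(vh, vs, 5, 1, -50, 25)
    x <- steady_state(v, sp)
    expect_true(all(x > 0 & x < 1))
    if (vs > 0) expect_true(all(diff(x) > 0)) else
      expect_true(all(diff(x) < 0))
  }
})

test_that("time constant is a bell bounded by tau_min and tau_max", {
  sp <- gating_spec(-40, 10, tau_max = 12, tau_min = 3, v_tau_half = -55,
                    v_tau_slope = 18)
  expect_equal(time_constant(-55, sp), 12)
  expect_equal(time_constant(1e4, sp), 3)
  expect_equal(time_constant(-1e4, sp), 3)
  v <- seq(-150, 80, by = 0.25)
  tau <- time_constant(v, sp)
  expect_true(all(tau >= 3 - 1e-12 & tau <= 12 + 1e-12))
  expect_equal(v[which.max(tau)], -55)
  # degenerate bell
  flat <- gating_spec(-40, 10, 5, 5, -55, 18)
  expect_true(all(time_constant(v, flat) == 5))
})

test_that("gating_step is the exact exponential relaxation", {
  sp <- gating_spec(-40, 10, tau_max = 8, tau_min = 8, v_tau_half = -40,
                    v_tau_slope = 20)
  xinf <- steady_state(-50, sp)
  expect_equal(gating_step(xinf, -50, sp, dt = 0.5), xinf)
  expect_equal(gating_step(0.1, -50, sp, dt = 1e5), xinf, tolerance = 1e-9)
  # x = 0 toward x_inf = 1 over one time constant: 1 - exp(-1)
  spx <- gating_spec(-40, 1e-3, 8, 8, -40, 20) # saturates x_inf at 1
  expect_equal(gating_step(0, 0, spx, dt = 8), 1 - exp(-1),
               tolerance = 1e-9)
  expect_error(gating_step(0.5, -50, sp, dt = 0))
})

test_that("ionic current follows g m^p h (E - V) with compartment split", {
  act <- gating_spec(-40, 10, 5, 1, -50, 20, p = 1L)
  cur <- ionic_current_spec("Kd", g_total = 10, e_rev = -90,
                            activation = act, split = c(1, 0, 0))
  expect_equal(ionic_current(-90, m = 0.7, spec = cur,
                             compartment = "soma"), 0)
  expect_equal(ionic_current(-50, m = 0, spec = cur,
                             compartment = "soma"), 0)
  # 10 nS fully open, driving force +10 mV -> 100 pA
  expect_equal(ionic_current(-100, m = 1, spec = cur,
                             compartment = "soma"), 100)
  expect_equal(ionic_current(-100, m = 1, spec = cur,
                             compartment = "axon"), 0)
  # exponent and inactivation
  act3 <- gating_spec(-40, 10, 5, 1, -50, 20, p = 3L)
  cur3 <- ionic_current_spec("Na", 10, 50, activation = act3,
                             inactivation = gating_spec(-60, -7, 5, 1,
                                                        -50, 20),
                             split = c(0.5, 0.5, 0))
  expect_equal(ionic_current(0, m = 0.5, h = 0.4, spec = cur3,
                             compartment = "soma"),
               10 * 0.5 * 0.5^3 * 0.4 * 50)
})

test_that("synaptic activation obeys the release rate law", {
  sp <- synapse_spec(g_syn = 5, e_syn = 0, tau_syn = 10, v_th = -30,
                     v_slope = 20)
  # no drive below threshold
  expect_equal(synaptic_state_step(0, -65, sp, dt = 1), 0)
  # pure decay over one time constant: S * exp(-1)
  expect_equal(synaptic_state_step(0.8, -65, sp, dt = 10), 0.8 * exp(-1),
               tolerance = 1e-12)
  # one slope above threshold: relax toward tanh(1) with shortened tau
  s_inf <- tanh_series(1)
  s1 <- synaptic_state_step(0, -10, sp, dt = 1)
  expect_equal(s1, s_inf * (1 - exp(-1 / (10 * (1 - s_inf)))),
               tolerance = 1e-9)
  # S_inf is clamped below 1: a huge presynaptic potential must not
  # produce a zero or negative effective time constant
  expect_lt(synaptic_state_step(0, 1e4, sp, dt = 1), 1)
})

test_that("synaptic current follows g S (E - V)", {
  sp <- synapse_spec(g_syn = 5, e_syn = 0, tau_syn = 10)
  expect_equal(synaptic_current(0, 0.5, sp), 0)
  expect_equal(synaptic_current(-60, 0, sp), 0)
  spn <- synapse_spec(g_syn = 5, e_syn = -72, tau_syn = 10)
  expect_equal(synaptic_current(-52, 0.5, spn), -50)
})

test_that("gating_spec rejects invalid parameters", {
  expect_error(gating_spec(-40, 0, 5, 1, -50, 20))
  expect_error(gating_spec(-40, 10, 1, 5, -50, 20))
  expect_error(gating_spec(-40, 10, 5, 0, -50, 20))
  expect_error(gating_spec(-40, 10, 5, 1, -50, 0))
})
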