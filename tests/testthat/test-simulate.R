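# Integrator behaviour: passive physics, settling, determinism, state
# carry-over, divergence guard, and agreement with the RK4 reference
# integrator.

test_that("a leak-only model rests exactly at the leak reversal", {
  m <- passive_model()
  st <- settle_to_rest(m)
  expect_true(st$converged)
  expect_false(st$spiked)
  expect_equal(st$v_rest, -70, tolerance = 1e-9)
  rec <- simulate_neuron(m, list(sweep_def(200)), init_state = st$state)
  expect_true(all(abs(rec$traces[[1]] + 70) < 1e-9))
})

test_that("passive charging matches the RC closed form within 0.1 mV", {
  # single effective compartment: couplings zero, no voltage-gated currents
  m <- passive_model(g_leak = c(2, 0, 0), capacitance = c(16, 3, 8))
  st <- settle_to_rest(m, dt = 0.02)
  rec <- simulate_neuron(m, list(sweep_def(500, t_end = c(100, 500),
                                           amp = c(0, 20), win0 = 100,
                                           win1 = 500)),
                         dt = 0.02, record_interval = 0.1,
                         init_state = st$state)
  v <- rec$traces[[1]]
  t <- (seq_along(v) - 1) * rec$dt
  sel <- t >= 100 & t <= 500
  tau <- 16 / 2                     # C/g in ms
  van <- -70 + 10 * (1 - exp(-(t[sel] - 100) / tau))
  expect_lt(max(abs(v[sel] - van)), 0.1)
})

test_that("settled states are fixed points with consistent gating", {
  m <- canonical_model("regular")
  st <- settle_to_rest(m)
  expect_true(st$converged)
  rec <- simulate_neuron(m, list(sweep_def(100)), init_state = st$state,
                         record_trace = TRUE)
  expect_lt(abs(rec$traces[[1]][length(rec$traces[[1]])] - st$v_rest),
            0.01)
  # gating variables sit at the steady state of the resting voltage
  v_rest <- st$state[1]
  na <- m$currents$Na
  expect_equal(st$state[4], steady_state(v_rest, na$activation),
               tolerance = 1e-4)
})

test_that("identical model and stimulus give bit-identical recordings", {
  m <- canonical_model("stuttering")
  st <- settle_to_rest(m)
  sw <- list(sweep_def(400, t_end = c(50, 350), amp = c(0, 180),
                       win0 = 50, win1 = 350))
  r1 <- simulate_neuron(m, sw, init_state = st$state)
  r2 <- simulate_neuron(m, sw, init_state = st$state)
  expect_identical(r1$traces, r2$traces)
  expect_identical(r1$spikes, r2$spikes)
  expect_identical(r1$state, r2$state)
})

test_that("state carries over between sweeps exactly", {
  m <- canonical_model("delayed")
  st <- settle_to_rest(m)
  sw <- lapply(c(60, 80), function(a)
    sweep_def(300, t_end = c(50, 250), amp = c(0, a), win0 = 50,
              win1 = 250))
  joint <- simulate_neuron(m, sw, init_state = st$state)
  first <- simulate_neuron(m, sw[1], init_state = st$state)
  second <- simulate_neuron(m, sw[2], init_state = first$state)
  expect_identical(joint$traces[[2]], second$traces[[1]])
  expect_identical(joint$spikes[[2]], second$spikes[[1]])
})

test_that("gating variables stay inside (0,1) along a firing trajectory", {
  m <- canonical_model("regular")
  st <- settle_to_rest(m)
  res <- vclamp:::cpp_simulate(
    vclamp:::model_to_clist(m),
    list(sweep_def(400, t_end = c(50, 350), amp = c(0, 150), win0 = 50,
                   win1 = 350)),
    numeric(), numeric(), 0.025, vclamp:::default_synapse_params(),
    0.025, 0.05, FALSE, st$state, -10, 2, 200)
  gate_idx <- 4:(length(res$state) - 5)   # V[3] ... Ca[3], S_e, S_i
  expect_true(all(res$state[gate_idx] > 0 & res$state[gate_idx] < 1))
})

test_that("the divergence guard aborts with a diagnostic", {
  act <- gating_spec(-40, 10, 0.1, 0.1, -50, 20, p = 1L)
  unstable <- neuron_model(
    capacitance = c(0.3, 0.3, 0.3), g_leak = c(0.1, 0.1, 0.1),
    e_leak = -70, g_sx = 0, g_sd = 0,
    currents = list(ionic_current_spec("Na", 4000, 50,
                                       activation = act,
                                       split = c(1, 0, 0))))
  expect_error(
    simulate_neuron(unstable,
                    list(sweep_def(100, t_end = c(10, 90),
                                   amp = c(0, 500))),
                    init_state = vclamp:::cpp_init_state(
                      vclamp:::model_to_clist(unstable)),
                    label = "unstable#1"),
    "divergence.*unstable#1.*sweep 1")
})

test_that("compiled spike detection matches detect_spikes on the trace", {
  m <- canonical_model("regular")
  st <- settle_to_rest(m)
  rec <- simulate_neuron(m, list(sweep_def(600, t_end = c(100, 500),
                                           amp = c(0, 150), win0 = 100,
                                           win1 = 500)),
                         init_state = st$state)
  from_trace <- detect_spikes(rec$traces[[1]], rec$dt,
                              window = c(100, 500))
  online <- rec$spikes[[1]]
  online <- online[online >= 100 & online <= 500]
  expect_equal(length(from_trace), length(online))
  expect_true(all(abs(from_trace - online) <= rec$dt + 1e-9))
})
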