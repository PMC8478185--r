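# Population synthesis: Gaussian parameter variation, Poissonian
# presynaptic waveforms, ASCII waveform files, and the LIF control model.

test_that("population sampling is seeded, truncated and sized", {
  dist <- phenotype_distribution("delayed")
  p1 <- sample_population(dist, 25, seed = 5)
  p2 <- sample_population(dist, 25, seed = 5)
  p3 <- sample_population(dist, 25, seed = 6)
  expect_length(p1, 25)
  man1 <- attr(p1, "manifest")
  expect_identical(man1, attr(p2, "manifest"))
  expect_false(identical(man1, attr(p3, "manifest")))
  # no negative draws for nonnegative parameters
  nonneg <- setdiff(names(man1), c("phenotype", "instance", "seed",
                                   "e_leak"))
  expect_true(all(as.matrix(man1[nonneg]) >= 0))
  # zero dispersion reproduces the canonical model exactly
  d0 <- dist
  d0$table$sd[] <- 0
  flat <- sample_population(d0, 3, seed = 1)
  for (m in flat)
    expect_equal(vclamp:::model_to_clist(m),
                 vclamp:::model_to_clist(dist$model))
})

test_that("sample means approach the table means (law of large numbers)", {
  dist <- phenotype_distribution("stuttering")
  man <- attr(sample_population(dist, 20000, seed = 3), "manifest")
  for (j in seq_len(nrow(dist$table))) {
    p <- dist$table$parameter[j]
    mu <- dist$table$mean[j]
    sd <- dist$table$sd[j]
    if (sd == 0) next
    se <- sd / sqrt(20000)
    # resampling-truncation keeps the mean approximately: allow 3 SE
    # plus the small truncation bias bound
    bias_allow <- if (p == "e_leak") 0 else sd * 0.05
    expect_lt(abs(mean(man[[p]]) - mu), 3 * se + bias_allow)
  }
})

test_that("presynaptic waveforms are seeded Poisson pulse trains", {
  w0 <- generate_presynaptic_waveform(rate = 0, duration = 500, dt = 0.1,
                                      seed = 1)
  expect_true(all(w0$v == w0$v_base))
  w1 <- generate_presynaptic_waveform(rate = 40, duration = 500, dt = 0.1,
                                      seed = 9)
  w2 <- generate_presynaptic_waveform(rate = 40, duration = 500, dt = 0.1,
                                      seed = 9)
  expect_identical(w1$v, w2$v)
  expect_true(all(w1$v %in% c(w1$v_base, w1$v_peak)))
  expect_error(generate_presynaptic_waveform(40, 500, dt = 0.5,
                                             pulse_width = 0.1))
})

test_that("waveform event counts pass a Poisson goodness-of-fit check", {
  rate <- 40; dur <- 500
  lambda <- rate * dur / 1000
  counts <- vapply(1:400, function(s)
    length(generate_presynaptic_waveform(rate, dur, dt = 0.25,
                                         seed = s)$events), numeric(1))
  # bin the Poisson distribution into cells with expected count >= 5
  brk <- stats::qpois(seq(0, 1, length.out = 9), lambda)
  brk <- unique(c(-1, brk[-c(1, length(brk))], Inf))
  obs <- table(cut(counts, brk))
  pr <- diff(stats::ppois(brk, lambda))
  pval <- suppressWarnings(stats::chisq.test(as.vector(obs),
                                             p = pr / sum(pr))$p.value)
  expect_gt(pval, 0.01)
})

test_that("waveform ASCII files round-trip", {
  w <- generate_presynaptic_waveform(rate = 20, duration = 200, dt = 0.1,
                                     seed = 4)
  path <- withr::local_tempfile(fileext = ".asc")
  write_waveform_ascii(w, path)
  w2 <- read_waveform_ascii(path)
  expect_identical(w2$v, w$v)
  expect_identical(w2$dt, w$dt)
  expect_identical(w2$rate, w$rate)
  expect_identical(w2$seed, as.integer(w$seed))
})

test_that("LIF population varies exactly four parameters", {
  pop <- sample_lif_population(n = 100, seed = 2)
  man <- attr(pop, "manifest")
  expect_length(pop, 100)
  expect_true(all(vapply(pop, function(m) m$v_th > m$v_reset,
                         logical(1))))
  expect_true(all(vapply(pop, function(m) m$t_ref == pop[[1]]$t_ref,
                         logical(1))))
  # zero dispersion collapses to the nominal model
  flat <- sample_lif_population(cv = 0, n = 3, seed = 1, sd_e_leak = 0,
                                sd_v_th = 0)
  expect_identical(flat[[1]][names(flat[[1]])], flat[[2]][names(flat[[2]])])
})

test_that("LIF dynamics match the analytic interspike interval", {
  m <- lif_model(cap = 80, g_leak = 4, e_leak = -65, v_th = -45,
                 v_reset = -60, t_ref = 3)
  # subthreshold steady state below threshold: silent
  quiet <- lif_simulate(m, list(sweep_def(1000, t_end = c(0, 1000),
                                          amp = c(60, 60))), dt = 0.02)
  expect_length(quiet$spikes[[1]], 0)
  # zero input from rest: stays at E_L (no spikes)
  rest <- lif_simulate(m, list(sweep_def(500)), dt = 0.02)
  expect_length(rest$spikes[[1]], 0)
  # suprathreshold constant current: closed-form period
  current <- 150
  rec <- lif_simulate(m, list(sweep_def(2000, t_end = c(0, 2000),
                                        amp = c(current, current))),
                      dt = 0.02)
  s <- rec$spikes[[1]]
  expect_gt(length(s), 5)
  tau <- 80 / 4
  drive <- current / 4
  period <- 3 + tau * log((drive - (-60 + 65)) / (drive - (-45 + 65)))
  isi <- diff(s)[-1]
  expect_true(all(abs(isi - period) < 0.1))
})
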