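# Feature extraction: spike detection, I-O curves, rheobase and threshold
# conductance, Belehradek latency fits, input resistance, sag, Spearman.

test_that("detect_spikes counts guarded threshold crossings", {
  dt <- 0.1
  flat <- rep(-70, 1000)
  expect_length(detect_spikes(flat, dt), 0)
  # three well-separated crossings
  tr <- rep(-70, 1000)
  for (i in c(100, 400, 700)) tr[i:(i + 10)] <- 10
  expect_equal(detect_spikes(tr, dt), c(99, 399, 699) * dt)
  # two crossings 0.5 ms apart with a 2 ms guard collapse to one
  tr2 <- rep(-70, 1000)
  tr2[100:101] <- 10
  tr2[105:106] <- 10
  expect_length(detect_spikes(tr2, dt, refractory = 2), 1)
  # window filtering
  expect_length(detect_spikes(tr, dt, window = c(30, 50)), 1)
})

test_that("io_curve, rheobase and cumulative count are consistent", {
  rec <- fake_recording(
    spikes = list(numeric(), numeric(), 120, c(110, 180), c(50, 90, 130)),
    amplitude = c(-10, -5, 0, 5, 10))
  cu <- io_curve(rec)
  expect_s3_class(cu, "io_curve")
  expect_equal(cu$count, c(0, 0, 1, 2, 3))
  expect_equal(cu$latency, c(NA, NA, 120, 110, 50))
  expect_equal(cumulative_spike_count(cu), sum(cu$count))
  expect_equal(rheobase(cu), 0)
  # all-quiet recording
  quiet <- fake_recording(spikes = rep(list(numeric()), 4),
                          amplitude = c(-10, 0, 10, 20))
  expect_equal(io_curve(quiet)$count, rep(0L, 4))
  expect_true(is.na(rheobase(io_curve(quiet))))
  # firing at the lowest level
  low <- fake_recording(spikes = list(5, 10), amplitude = c(-20, -15))
  expect_equal(rheobase(io_curve(low)), -20)
  # cumulative count invariant under sweep reordering
  perm <- fake_recording(
    spikes = list(c(50, 90, 130), numeric(), c(110, 180), numeric(), 120),
    amplitude = c(10, -10, 5, -5, 0))
  expect_equal(cumulative_spike_count(io_curve(perm)),
               cumulative_spike_count(cu))
})

test_that("threshold conductance reads the dynamic axis", {
  rec <- fake_recording(spikes = list(numeric(), numeric(), c(30, 60)),
                        g_ampa = c(0, 0.5, 1.0), protocol = "dynamic",
                        window = c(0, 2500))
  expect_equal(threshold_conductance(io_curve(rec)), 1.0)
  spont <- fake_recording(spikes = list(15, 20), g_ampa = c(0, 0.5),
                          protocol = "dynamic", window = c(0, 2500))
  expect_equal(threshold_conductance(io_curve(spont)), 0)
  quiet <- fake_recording(spikes = rep(list(numeric()), 3),
                          g_ampa = c(0, 0.5, 1), protocol = "dynamic",
                          window = c(0, 2500))
  expect_true(is.na(threshold_conductance(io_curve(quiet))))
})

test_that("Belehradek fits recover known parameters within 1 percent", {
  a <- 500; b <- 20; cc <- -0.8
  currents <- seq(40, 200, by = 10)
  lat <- a * (currents - b)^cc
  fit <- fit_belehradek(currents, lat)
  expect_true(fit$converged)
  expect_lt(abs(fit$a - a) / a, 0.01)
  expect_lt(abs(fit$b - b) / abs(b), 0.01)
  expect_lt(abs(fit$c - cc) / abs(cc), 0.01)
  # fitted curve is strictly decreasing over the fitted range
  grid <- seq(min(currents), max(currents), length.out = 50)
  expect_true(all(diff(predict(fit, grid)) < 0))
  # under-determined inputs raise
  expect_error(fit_belehradek(currents[1:3], lat[1:3]))
})

test_that("latency at 1.3x rheobase evaluates the fitted curve", {
  fit <- structure(list(a = 500, b = 20, c = -0.8, residual = 0,
                        converged = TRUE, range = c(40, 200)),
                   class = "belehradek_fit")
  expect_equal(latency_1_3(fit, 100), 500 * (130 - 20)^-0.8,
               tolerance = 1e-12)
  expect_true(is.na(latency_1_3(fit, NA)))
  expect_error(latency_1_3(fit, 10))
  # degenerate exponent: constant latency
  flat <- structure(list(a = 7, b = 20, c = 0, residual = 0,
                         converged = TRUE, range = c(40, 200)),
                    class = "belehradek_fit")
  expect_equal(latency_1_3(flat, 100), 7)
  expect_equal(latency_1_3(flat, 150), 7)
})

test_that("input resistance reproduces passive values and scales", {
  m <- passive_model(g_leak = c(2, 0, 0))
  rec <- run_static_protocol(m, coarse_steps(increment = 5))
  expect_equal(input_resistance(rec), 500, tolerance = 0.01)
  m2 <- passive_model(g_leak = c(4, 0, 0))
  rec2 <- run_static_protocol(m2, coarse_steps(increment = 5))
  expect_equal(input_resistance(rec2), 250, tolerance = 0.01)
  expect_equal(sag_ratio(rec), 0, tolerance = 1e-6)
})

test_that("sag requires a hyperpolarization-activated current", {
  rec <- run_static_protocol(canonical_model("regular"),
                             current_step_protocol(increment = 40))
  s <- sag_ratio(rec)
  expect_gt(s, 0.05)
  expect_lte(s, 1)
})

test_that("spearman matches a brute-force rank/Pearson oracle", {
  expect_equal(spearman(1:10, (1:10)^3), 1)
  expect_equal(spearman(1:10, -(1:10)), -1)
  expect_equal(spearman(c(1, 2, 3), c(3, 1, 2)), -0.5)
  brute <- function(x, y) {
    rx <- rank(x); ry <- rank(y)
    n <- length(x)
    num <- sum((rx - mean(rx)) * (ry - mean(ry)))
    num / sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  }
  set.seed(11)
  for (i in 1:30) {
    x <- sample(1:8, 25, replace = TRUE)   # plenty of ties
    y <- x + sample(-3:3, 25, replace = TRUE)
    expect_equal(spearman(x, y), brute(x, y), tolerance = 1e-12)
    expect_equal(spearman(x, y),
                 suppressWarnings(stats::cor(x, y, method = "spearman")),
                 tolerance = 1e-12)
  }
  expect_error(spearman(rep(1, 5), 1:5))
  expect_error(spearman(1:2, 1:2))
})

test_that("relative change guards the zero baseline", {
  expect_equal(relative_change(10, 10), 0)
  expect_equal(relative_change(10, 30), 200)
  expect_true(is.na(relative_change(0, 5)))
})

test_that("feature extraction is pure", {
  rec <- run_static_protocol(canonical_model("delayed"), coarse_steps(20))
  f1 <- feature_record(rec)
  f2 <- feature_record(rec)
  expect_identical(f1, f2)
  # missing rheobase implies zero cumulative count and vice versa
  quiet <- fake_recording(spikes = rep(list(numeric()), 5))
  fq <- io_curve(quiet)
  expect_true(is.na(rheobase(fq)) == (cumulative_spike_count(fq) == 0))
})
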