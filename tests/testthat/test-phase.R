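test_that("extract_phases is cosine-referenced and window-exact", {
  fs <- 1000
  t <- seq(0, 1, by = 1 / fs)[-(fs + 1)]
  expect_equal(extract_phases(cos(2 * pi * 10 * t), fs, 10)$measured_phases,
               0, tolerance = 1e-9)
  # a 5-ms delayed cosine: alpha = 2*pi - omega*tau
  m <- extract_phases(cos(2 * pi * 10 * (t - 0.005)), fs, 10)
  expect_equal(m$measured_phases, 2 * pi - 0.1 * pi, tolerance = 1e-9)
  # quadrature reference
  expect_equal(extract_phases(sin(2 * pi * 10 * t), fs, 10)$measured_phases,
               3 * pi / 2, tolerance = 1e-9)
  expect_equal(m$amplitudes, 1, tolerance = 1e-9)
  expect_error(extract_phases(t, fs, 600), "Nyquist")
  expect_error(extract_phases(t, fs, 10, window_length = 0.55),
               "integer multiple")
})

test_that("mean phase error behaves like a chord-length cost", {
  pm <- make_measurement(c(10, 20, 30), 0.017)
  expect_equal(mean_phase_error(pm, 0.017), 0, tolerance = 1e-12)
  expect_gt(mean_phase_error(pm, 0.020), 0.1)
  # single consistent frequency
  expect_equal(mean_phase_error(make_measurement(39, 0.021), 0.021), 0,
               tolerance = 1e-12)
  # uniform phase errors: expectation is the mean chord 4/pi
  set.seed(42)
  pm2 <- phase_measurement(seq_len(4000), stats::runif(4000, 0, 2 * pi))
  expect_equal(mean_phase_error(pm2, 0), 4 / pi, tolerance = 0.03)
  # range invariant
  taus <- seq(0, 0.1, by = 0.001)
  v <- mean_phase_error(pm, taus)
  expect_true(all(v >= 0 & v <= 2))
})

test_that("latency estimation recovers exact latencies and flags ambiguity", {
  # noise-free first subsystem components
  pm <- make_measurement(EX1_F1, 0.051)
  est <- estimate_latency(pm, c(0, 100))
  expect_equal(est$latency_ms, 51, tolerance = 1e-3)
  expect_lt(est$mpe, 1e-6)
  # absolute phase lags recover omega * tau exactly
  expect_equal(est$absolute_phase_lags, 2 * pi * EX1_F1 * 0.051,
               tolerance = 1e-4)
  expect_equal(est$cycle_counts, ceiling(0.051 * EX1_F1))
  # single 39-Hz component: solutions repeat every period
  est39 <- estimate_latency(make_measurement(39, 0), c(0, 100))
  expect_equal(est39$latency_ms, 0, tolerance = 1e-3)
  expect_true(est39$ambiguous)
  expect_true(est39$low_confidence)
  expect_equal(sort(est39$candidate_latencies_ms),
               c(0, 1, 2, 3) * 1000 / 39, tolerance = 1e-2)
  expect_error(estimate_latency(pm, c(50, 50)), "range")
})

test_that("time compensation restores latencies from ongoing windows", {
  expect_equal(time_compensate(-249, 300), 51)
  expect_equal(time_compensate(-279, 300), 21)
  expect_equal(time_compensate(17.3, 0), 17.3)
  # full path: phases measured from a window starting at 300 ms
  rec <- example1_recipe(onset_skip = 0.3)
  sim <- synthesize(rec)
  pm <- extract_phases(sim$signal, 1000, EX1_F1, window_start = 0.3,
                       window_length = 3)
  est <- estimate_latency(pm, c(0, 100))
  expect_equal(est$pseudo_latency_ms, -249, tolerance = 1e-2)
  expect_equal(est$latency_ms, 51, tolerance = 1e-2)
  pm2 <- extract_phases(sim$signal, 1000, EX1_F2, window_start = 0.3,
                        window_length = 3)
  est2 <- estimate_latency(pm2, c(0, 100))
  expect_equal(est2$pseudo_latency_ms, -279, tolerance = 1e-2)
  expect_equal(est2$latency_ms, 21, tolerance = 1e-2)
})

test_that("apparent-latency rule and TC invariance hold on random systems", {
  for (seed in 1:6) {
    rr <- random_recipe(seed, n_sub = 1)
    sim <- synthesize(rr$recipe)
    pm <- extract_phases(sim$signal, 1000, rr$sets[[1]], window_length = 2)
    est <- estimate_latency(pm, c(0, 100))
    # noise-free parameter recovery
    expect_equal(est$latency_ms, rr$latencies[1], tolerance = 1e-2)
    # apparent-latency rule: slope of the lag line reproduces the latency
    expect_equal(1000 * est$slope / (2 * pi) + est$delta_t_ms,
                 est$latency_ms, tolerance = 0.1)
    # TC invariance: a window starting later gives the same latency
    pm2 <- extract_phases(sim$signal, 1000, rr$sets[[1]],
                          window_start = 1, window_length = 2)
    est2 <- estimate_latency(pm2, c(0, 100))
    expect_equal(est2$latency_ms, est$latency_ms, tolerance = 1e-2)
  }
})

test_that("two-stage search matches an exhaustive fine grid", {
  for (seed in 1:3) {
    set.seed(seed)
    f <- sort(sample(5:80, 4))
    alpha <- stats::runif(4, 0, 2 * pi)
    pm <- phase_measurement(f, alpha)
    est <- estimate_latency(pm, c(0, 100))
    grid <- seq(0, 0.1, by = 1e-6)
    cost <- mean_phase_error(pm, grid)
    expect_equal(est$pseudo_latency_ms, 1000 * grid[which.min(cost)],
                 tolerance = 2e-3)
    expect_lte(est$mpe, min(cost) + 1e-6)
  }
})
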