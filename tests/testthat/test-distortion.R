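test_that("published distortion sets are enumerated exactly", {
  # the four-tone design's pairwise beats
  st4 <- stimulus_complex(c(461, 500, 504, 537))
  expect_equal(
    enumerate_distortions(st4, 2, mode = "difference_only")$frequencies,
    c(4, 33, 37, 39, 43, 76))
  # nine 2nd-order products of a three-tone complex
  expect_equal(
    enumerate_distortions(stimulus_complex(c(17, 21, 27)), 2)$frequencies,
    c(4, 6, 10, 34, 38, 42, 44, 48, 54))
  # non-overlapping two-tone counterpart
  expect_equal(
    enumerate_distortions(stimulus_complex(c(41, 49)), 2)$frequencies,
    c(8, 82, 90, 98))
  # single carrier, order 1: identity
  expect_equal(
    enumerate_distortions(stimulus_complex(123), 1)$frequencies, 123)
})

test_that("monaural-beat interaction sets match the design table", {
  # 2nd/3rd-order products of the two principal beats (33, 39 Hz) are the
  # 4th/6th-order carrier products listed for the four-tone design
  mb <- stimulus_complex(c(33, 39))
  expect_equal(enumerate_distortions(mb, 2)$frequencies,
               sort(c(6, 66, 72, 78)))
  # the table lists each frequency at its generating order only, so the
  # 3MB row is the exact-order-3 subset (the beats 33/39 re-enter the
  # order <= 3 cumulative set through x^3 but belong to the 2nd row)
  ds3 <- enumerate_distortions(mb, 3)
  expect_equal(sort(unique(ds3$products$frequency[ds3$products$order == 3])),
               sort(c(27, 45, 99, 105, 111, 117)))
  # and each appears among the carrier-level products at exactly that order
  st4 <- stimulus_complex(c(461, 500, 504, 537))
  ds4 <- enumerate_distortions(st4, 4, band_limit = 200)
  ds6 <- enumerate_distortions(st4, 6, band_limit = 200)
  min_order <- function(ds, f)
    min(ds$products$order[abs(ds$products$frequency - f) < 1e-9])
  for (f in c(6, 66, 72, 78)) expect_equal(min_order(ds4, f), 4)
  for (f in c(27, 45, 99, 105, 111, 117)) expect_equal(min_order(ds6, f), 6)
})

test_that("enumeration obeys count, monotonicity and validity invariants", {
  st <- stimulus_complex(c(17, 21, 27, 41, 49))
  # difference_only on I carriers yields at most I(I-1)/2 frequencies
  expect_lte(length(enumerate_distortions(st, 2, mode = "difference_only")$frequencies),
             5 * 4 / 2)
  # cumulative mode is monotone in the order
  for (R in 1:4) {
    a <- enumerate_distortions(st, R, parity = NA)$frequencies
    b <- enumerate_distortions(st, R + 1, parity = NA)$frequencies
    expect_true(all(a %in% b))
  }
  # homogeneous mode is monotone across same-parity orders
  a <- enumerate_distortions(st, 2)$frequencies
  b <- enumerate_distortions(st, 4)$frequencies
  expect_true(all(a %in% b))
  # every product's coefficients reproduce its frequency
  ds <- enumerate_distortions(st, 3)
  for (i in seq_len(nrow(ds$products)))
    expect_equal(abs(sum(ds$products$coefficients[[i]] * st$carriers)),
                 ds$products$frequency[i])
  expect_error(stimulus_complex(c(10, 10)), "distinct")
  expect_error(enumerate_distortions(st, 0), "positive integer")
})

test_that("initial-phase prediction follows the waveform rules", {
  # zero-phase cosine carriers: every product has zero phase
  st <- stimulus_complex(c(17, 21, 27))
  ds <- enumerate_distortions(st, 3, parity = NA)
  expect_true(all(ds$products$predicted_phase == 0))
  # zero-phase sine carriers: even-order pure differences sit at pi/2
  sst <- stimulus_complex(c(461, 500), waveform = "sine")
  expect_equal(predict_initial_phase(c(1, -1), sst), pi / 2)
  expect_equal(predict_initial_phase(c(2, -2), sst), pi / 2)
  expect_equal(predict_initial_phase(c(-1, 1), sst), pi / 2)
  # linearity for cosine carriers with nonzero phases
  cst <- stimulus_complex(c(100, 140), initial_phases = c(0.3, 0.5))
  expect_equal(predict_initial_phase(c(1, 1), cst), 0.8)
  # f1 - f2 < 0 here: folded to +40 Hz with the phase conjugated
  expect_equal(predict_initial_phase(c(1, -1), cst), 0.2)
  expect_equal(predict_initial_phase(c(-1, 1), cst), 0.2)
})

test_that("analytic phases agree with the numeric synthesis oracle", {
  cases <- list(
    list(w = "cosine", phi = c(0, 0), a = c(1, -1)),
    list(w = "cosine", phi = c(0.3, 0.5), a = c(1, 1)),
    list(w = "cosine", phi = c(1.1, 0.2), a = c(2, -1)),
    list(w = "sine", phi = c(0, 0), a = c(1, -1)),
    list(w = "sine", phi = c(0, 0), a = c(2, -2)),
    list(w = "sine", phi = c(0, 0), a = c(1, 1)),
    list(w = "sine", phi = c(0, 0), a = c(2, 0)),
    list(w = "sine", phi = c(0.7, 0.1), a = c(1, -2)),
    list(w = "sine", phi = c(0, 0, 0), a = c(1, -1, 1)),
    list(w = "cosine", phi = c(0.4, 2.2, 5.1), a = c(2, -1, -1)))
  for (cs in cases) {
    st <- stimulus_complex(seq(311, by = 71,
                               length.out = length(cs$a)),
                           waveform = cs$w, initial_phases = cs$phi)
    d <- abs(predict_initial_phase(cs$a, st) -
             predict_initial_phase(cs$a, st, method = "numeric"))
    expect_lt(min(d, 2 * pi - d), 1e-6)
  }
})

test_that("a synthesized polynomial spectrum matches the enumeration", {
  # full-signal oracle: peaks of x(t)^2 are exactly the enumerated set,
  # with the predicted (zero) phases
  st <- stimulus_complex(c(17, 21, 27), duration = 1)
  rec <- simulation_recipe(st, list(subsystem_spec(1:3, 2, latency_ms = 0)),
                           duration_s = 1, fs_hz = 1000)
  sim <- synthesize(rec)
  spec <- periodogram_power(sim$signal, 1000)
  peaks <- spec$frequency[spec$frequency > 0 & spec$power > 1e-6]
  expect_equal(peaks, enumerate_distortions(st, 2)$frequencies)
  ph <- extract_phases(sim$signal, 1000, peaks)$measured_phases
  expect_true(all(pmin(ph, 2 * pi - ph) < 1e-6))
})

test_that("distortion sets export to a flat table", {
  df <- as.data.frame(enumerate_distortions(stimulus_complex(c(41, 49)), 2))
  expect_named(df, c("frequency_hz", "order", "coefficients",
                     "predicted_phase_rad"))
  expect_true("1;1" %in% df$coefficients)
})
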