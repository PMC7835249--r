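# shared fixtures: all built in code at test time

# a measurement whose components are exactly consistent with given
# per-component latencies (seconds), cosine convention, zero initial phase
make_measurement <- function(freqs, tau_s, window_start = 0) {
  phase_measurement(freqs, (-2 * pi * freqs * tau_s) %% (2 * pi),
                    window_start = window_start,
                    window_length = 1)
}

# the Example-1 recipe (two pure 2nd-order subsystems, 51/21 ms)
example1_recipe <- function(snr_db = NULL, seed = NULL, duration_s = 4,
                            fs_hz = 1000, onset_skip = 0) {
  st <- stimulus_complex(c(17, 21, 27, 41, 49), onset_skip = onset_skip,
                         duration = duration_s)
  simulation_recipe(
    st,
    list(subsystem_spec(1:3, 2, latency_ms = 51),
         subsystem_spec(4:5, 2, latency_ms = 21)),
    duration_s = duration_s, fs_hz = fs_hz, snr_db = snr_db, seed = seed)
}

# frequencies of the two Example-1 subsystems
EX1_F1 <- c(4, 6, 10, 34, 38, 42, 44, 48, 54)
EX1_F2 <- c(8, 82, 90, 98)

# random homogeneous-subsystem recipe for property tests
random_recipe <- function(seed, n_sub = 2, duration_s = 4, fs_hz = 1000) {
  set.seed(seed)
  repeat {
    carriers <- sort(sample(11:60, n_sub * 2))
    st <- stimulus_complex(carriers, duration = duration_s)
    subs <- lapply(seq_len(n_sub), function(m)
      subsystem_spec((2 * m - 1):(2 * m), sample(2:3, 1),
                     latency_ms = stats::runif(1, 5, 95)))
    sets <- lapply(subs, function(s)
      enumerate_distortions(stimulus_complex(carriers[s$carrier_idx]),
                            s$orders, parity = s$orders)$frequencies)
    # demand non-overlapping outputs below Nyquist
    if (length(unlist(sets)) == length(unique(unlist(sets))) &&
        max(unlist(sets)) < fs_hz / 2 - 1)
      return(list(recipe = simulation_recipe(st, subs, duration_s, fs_hz),
                  sets = sets,
                  latencies = vapply(subs, `[[`, numeric(1), "latency_ms")))
  }
}
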