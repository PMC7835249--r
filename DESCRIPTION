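Package: alpc
Title: Multiple Latency Estimation from Auditory Steady-State Responses
Version: 0.1.0
Authors@R:
    person("ALPC", "Maintainers", email = "alpc@example.org", role = c("aut", "cre"))
Description: Estimates one or more response latencies of nonlinear subsystems
    from the steady-state phases recorded on a single channel. Implements
    apparent latency from phase coherence (ALPC) with sequential forward
    selection (SFS) over candidate distortion-product frequencies, time
    compensation for ongoing analysis windows, the parametric multi-spectral
    phase coherence (MSPC) baseline, significance statistics (latency
    consistency index, phase-locking value, neighboring SNR with F-test
    thresholds), a simulator for multi-tone stimuli passed through delayed
    homogeneous polynomial subsystems, and an EEG preprocessing protocol
    (common average reference, zero-phase Butterworth/notch filtering,
    interquartile-range trial rejection).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
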