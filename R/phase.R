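#' Bundle steady-state phase measurements at target frequencies
#'
#' @param frequencies target component frequencies in Hz.
#' @param measured_phases phases `alpha_i` in radians (folded to
#'   `[0, 2*pi)`), cosine-referenced with the time origin at the analysis
#'   window start.
#' @param initial_phases assumed initial phases `phi_i` in radians
#'   (recycled from a scalar; zero for zero-phase cosine stimuli).
#' @param amplitudes optional non-negative component amplitudes.
#' @param window_start analysis-window start in seconds after stimulus
#'   onset (the time-compensation offset `delta_t`).
#' @param window_length analysis-window length in seconds.
#' @return An object of class `"phase_measurement"`.
#' @export
phase_measurement <- function(frequencies, measured_phases,
                              initial_phases = 0, amplitudes = NULL,
                              window_start = 0, window_length = NA_real_) {
  frequencies <- as.numeric(frequencies)
  measured_phases <- as.numeric(measured_phases) %% (2 * pi)
  if (length(frequencies) != length(measured_phases))
    stop("frequencies and measured_phases must have equal length")
  initial_phases <- rep_len(as.numeric(initial_phases), length(frequencies)) %% (2 * pi)
  if (!is.null(amplitudes)) {
    amplitudes <- as.numeric(amplitudes)
    if (length(amplitudes) != length(frequencies))
      stop("amplitudes must match frequencies in length")
    if (any(amplitudes < 0)) stop("amplitudes must be >= 0")
  }
  structure(
    list(frequencies = frequencies, measured_phases = measured_phases,
         initial_phases = initial_phases, amplitudes = amplitudes,
         window_start = window_start, window_length = window_length),
    class = "phase_measurement")
}

#' @export
print.phase_measurement <- function(x, ...) {
  cat(sprintf("<phase_measurement> %d component(s), window start %.3g s\n",
              length(x$frequencies), x$window_start))
  print(data.frame(frequency_hz = x$frequencies,
                   alpha_rad = signif(x$measured_phases, 5),
                   phi_rad = signif(x$initial_phases, 5)))
  invisible(x)
}

# subset of a phase_measurement by frequency values
.pm_subset <- function(pm, freqs) {
  idx <- match(freqs, pm$frequencies)
  if (anyNA(idx)) stop("frequency not present in measurement")
  phase_measurement(pm$frequencies[idx], pm$measured_phases[idx],
                    pm$initial_phases[idx],
                    if (is.null(pm$amplitudes)) NULL else pm$amplitudes[idx],
                    pm$window_start, pm$window_length)
}

#' Extract steady-state phases by Fourier projection
#'
#' Projects a window of the sampled signal onto `cos(2*pi*f*t)` (time
#' origin at the window start) and returns the cosine-referenced phase in
#' `[0, 2*pi)` and the projection amplitude at each target frequency. The
#' window must span an integer number of cycles of every target frequency,
#' so that the projections are exact for steady-state components.
#'
#' @param signal numeric vector, the sampled series.
#' @param sampling_rate in Hz.
#' @param frequencies target frequencies in Hz, all below Nyquist.
#' @param window_start window start in seconds (>= 0; also recorded as the
#'   time-compensation offset of the measurement).
#' @param window_length window length in seconds; defaults to the rest of
#'   the signal truncated to a whole number of seconds (exact for
#'   integer-Hz targets).
#' @param initial_phases assumed initial phases passed through to the
#'   measurement (default 0).
#' @return a [phase_measurement()].
#' @examples
#' fs <- 1000; t <- seq(0, 1, by = 1/fs)[-1001]
#' m <- extract_phases(cos(2*pi*10*t), fs, 10)
#' m$measured_phases  # ~0
#' @export
extract_phases <- function(signal, sampling_rate, frequencies,
                           window_start = 0, window_length = NULL,
                           initial_phases = 0) {
  frequencies <- as.numeric(frequencies)
  if (any(frequencies >= sampling_rate / 2))
    stop("target frequency at or above Nyquist")
  n_total <- length(signal)
  i0 <- round(window_start * sampling_rate)
  if (abs(i0 - window_start * sampling_rate) > 1e-6)
    stop("window_start must align with the sampling grid")
  if (is.null(window_length))
    window_length <- floor((n_total - i0) / sampling_rate)
  n <- round(window_length * sampling_rate)
  if (abs(n - window_length * sampling_rate) > 1e-6)
    stop("window_length times sampling rate must be an integer")
  if (i0 + n > n_total) stop("window does not fit inside the signal")
  cyc <- frequencies * window_length
  if (any(abs(cyc - round(cyc)) > 1e-6))
    stop("window_length must be an integer multiple of every component period")
  x <- signal[(i0 + 1L):(i0 + n)]
  t <- (seq_len(n) - 1L) / sampling_rate
  z <- vapply(frequencies,
              function(f) sum(x * exp(-2i * pi * f * t)) * 2 / n,
              complex(1))
  phase_measurement(frequencies, Arg(z) %% (2 * pi),
                    initial_phases = initial_phases,
                    amplitudes = Mod(z),
                    window_start = window_start,
                    window_length = window_length)
}

#' Mean phase error (MPE) at a candidate latency
#'
#' The ALPC cost: the mean chord length between the latency-advanced
#' measured phasors and the assumed initial-phase phasors,
#' `mean(Mod(exp(1i*(alpha + tau*omega)) - exp(1i*phi)))`, a value in
#' `[0, 2]`. Zero means every component is exactly consistent with the
#' common latency `tau`; `4/pi` is the expectation under uniformly random
#' phase errors.
#'
#' @param measurement a [phase_measurement()].
#' @param tau candidate latency in seconds (vectorized).
#' @return numeric vector of MPE values in `[0, 2]`, one per `tau`.
#' @export
mean_phase_error <- function(measurement, tau) {
  stopifnot(inherits(measurement, "phase_measurement"))
  if (length(measurement$frequencies) == 0L) stop("empty measurement")
  omega <- 2 * pi * measurement$frequencies
  target <- exp(1i * measurement$initial_phases)
  vapply(tau, function(tt)
    mean(Mod(exp(1i * (measurement$measured_phases + tt * omega)) - target)),
    numeric(1))
}

#' Apply time compensation to a pseudo-latency
#'
#' When phases are measured from an ongoing window that starts `delta_t`
#' seconds after stimulus onset (of a zero-phase multi-cosine complex), the
#' latency recovered from those phases is the pseudo-latency
#' `tau_p = tau_e - delta_t`; the true latency is restored by adding the
#' offset back.
#'
#' @param pseudo_latency_ms pseudo-latency in ms (possibly negative).
#' @param delta_t_ms analysis-window offset in ms.
#' @return compensated latency in ms.
#' @examples
#' time_compensate(-249, 300)  # 51
#' @export
time_compensate <- function(pseudo_latency_ms, delta_t_ms) {
  pseudo_latency_ms + delta_t_ms
}

#' Estimate a common latency by minimizing the mean phase error
#'
#' Grid-searches the pseudo-latency over the prior range (shifted by the
#' analysis-window offset), refines every near-optimal grid minimum by
#' golden-section search to `1e-3` ms, and applies time compensation. The
#' MPE is periodic in `T`, the smallest common multiple of the component
#' periods, so only minima inside the prior range are reported; ties are
#' broken toward the smallest latency and flagged.
#'
#' Alongside the latency the estimator reports the integer cycle counts
#' `n_i`, the absolute phase lags `2*pi*n_i + phi_i - alpha_i`, and the
#' through-origin least-squares slope `d_phi` of lag versus frequency,
#' which satisfies the apparent-latency (group-delay) rule
#' `tau_p = d_phi / (2*pi)` up to the grid tolerance.
#'
#' @param measurement a [phase_measurement()]; its `window_start` is used
#'   as the time-compensation offset unless `delta_t_ms` is given.
#' @param prior_range_ms length-2 numeric, admissible latency range in ms
#'   (default `c(0, 100)`, a physiological prior for auditory responses).
#' @param grid_step_ms grid resolution in ms (default 0.1).
#' @param delta_t_ms analysis-window offset in ms; default
#'   `1000 * measurement$window_start`.
#' @param system_delay_ms fixed apparatus delay added to the reported
#'   latency (tube/trigger delay; default 0).
#' @return An object of class `"latency_estimate"`: latency and
#'   pseudo-latency in ms, `mpe`, the component frequencies, cycle counts,
#'   absolute phase lags, slope (rad/Hz), period `T` in ms, the prior
#'   range, per-frequency phase errors, candidate tied minima and an
#'   ambiguity flag.
#' @export
estimate_latency <- function(measurement, prior_range_ms = c(0, 100),
                             grid_step_ms = 0.1, delta_t_ms = NULL,
                             system_delay_ms = 0) {
  stopifnot(inherits(measurement, "phase_measurement"))
  if (length(measurement$frequencies) == 0L) stop("empty measurement")
  if (length(prior_range_ms) != 2L || diff(prior_range_ms) <= 0)
    stop("prior_range_ms must be an increasing length-2 range")
  if (is.null(delta_t_ms)) {
    ws <- measurement$window_start
    delta_t_ms <- if (is.null(ws) || is.na(ws)) 0 else 1000 * ws
  }
  omega <- 2 * pi * measurement$frequencies

  # search the pseudo-latency over the shifted prior
  lo <- (prior_range_ms[1] - delta_t_ms) / 1000
  hi <- (prior_range_ms[2] - delta_t_ms) / 1000
  step <- grid_step_ms / 1000
  grid <- seq(lo, hi, by = step)
  if (grid[length(grid)] < hi) grid <- c(grid, hi)
  cost <- mean_phase_error(measurement, grid)

  # all local minima on the grid (boundaries included)
  n <- length(grid)
  is_min <- if (n >= 3) {
    c(cost[1] <= cost[2],
      cost[2:(n - 1)] <= cost[1:(n - 2)] & cost[2:(n - 1)] <= cost[3:n],
      cost[n] <= cost[n - 1])
  } else rep(TRUE, n)
  cand_idx <- which(is_min)
  refine <- function(i) {
    a <- grid[max(1L, i - 1L)]; b <- grid[min(n, i + 1L)]
    if (a == b) return(c(grid[i], cost[i]))
    op <- stats::optimize(function(tt) mean_phase_error(measurement, tt),
                          c(a, b), tol = 1e-6 / 1000)
    c(op$minimum, op$objective)
  }
  ref <- vapply(cand_idx, refine, numeric(2))
  best <- min(ref[2, ])
  tied <- ref[, ref[2, ] <= best + 1e-6, drop = FALSE]
  ord <- order(tied[1, ])
  tied <- tied[, ord, drop = FALSE]
  tau_p <- tied[1, 1]                       # smallest tied latency (s)
  mpe <- tied[2, 1]

  # cycle counts and absolute phase lags at the optimum
  alpha <- measurement$measured_phases
  phi <- measurement$initial_phases
  n_i <- round((alpha + tau_p * omega - phi) / (2 * pi))
  lags <- 2 * pi * n_i + phi - alpha        # ~ tau_p * omega
  eps <- alpha + tau_p * omega - 2 * pi * n_i - phi
  f <- measurement$frequencies
  slope <- sum(lags * f) / sum(f * f)       # rad/Hz, through the origin

  period_ms <- 1000 / .gcd_frequencies(f)
  structure(
    list(latency_ms = 1000 * tau_p + delta_t_ms + system_delay_ms,
         pseudo_latency_ms = 1000 * tau_p,
         mpe = mpe,
         frequencies = f,
         cycle_counts = as.integer(n_i),
         absolute_phase_lags = lags,
         slope = slope,
         period_ms = period_ms,
         prior_range_ms = prior_range_ms,
         per_frequency_phase_error = eps,
         delta_t_ms = delta_t_ms,
         n_candidate_minima = ncol(tied),
         candidate_latencies_ms = 1000 * tied[1, ] + delta_t_ms + system_delay_ms,
         ambiguous = ncol(tied) > 1 || diff(prior_range_ms) > period_ms,
         low_confidence = length(f) < 3),
    class = "latency_estimate")
}

# greatest common divisor of the component frequencies (Hz); the MPE is
# periodic with period 1/gcd. Non-commensurate sets fall back to a pairwise
# floating gcd with 1e-6 Hz tolerance.
.gcd_frequencies <- function(f) {
  g <- function(a, b) {
    while (b > 1e-6) { r <- a %% b; a <- b; b <- r }
    a
  }
  Reduce(g, f)
}

#' @export
print.latency_estimate <- function(x, ...) {
  cat(sprintf("<latency_estimate> %.3f ms (pseudo %.3f ms, delta_t %.1f ms)\n",
              x$latency_ms, x$pseudo_latency_ms, x$delta_t_ms))
  cat(sprintf("  MPE %.4g on %d component(s); slope %.4g rad/Hz (apparent latency %.3f ms)\n",
              x$mpe, length(x$frequencies), x$slope,
              1000 * x$slope / (2 * pi) + x$delta_t_ms))
  if (x$ambiguous)
    cat(sprintf("  note: %d tied minima / prior wider than period T = %.1f ms\n",
                x$n_candidate_minima, x$period_ms))
  if (x$low_confidence)
    cat("  note: fewer than 3 components; phase-lag line underdetermined\n")
  invisible(x)
}
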