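#' Per-epoch phase table
#'
#' Holds the measured phases of each target frequency on `K` equal-length,
#' non-overlapping epochs. Epoch length must be an integer multiple of
#' every component period so the initial phases stay constant across
#' epochs.
#'
#' @param phases numeric `K x F` matrix of phases in radians (rows:
#'   epochs, columns: frequencies).
#' @param frequencies the `F` target frequencies in Hz.
#' @param epoch_length_s epoch duration in seconds.
#' @return object of class `"epoch_phase_table"`.
#' @export
epoch_phase_table <- function(phases, frequencies, epoch_length_s) {
  phases <- as.matrix(phases)
  if (ncol(phases) != length(frequencies))
    stop("phases must have one column per frequency")
  if (nrow(phases) < 2L) stop("need K >= 2 epochs")
  cyc <- frequencies * epoch_length_s
  if (any(abs(cyc - round(cyc)) > 1e-6))
    stop("epoch length must be an integer multiple of every component period")
  structure(list(phases = phases %% (2 * pi),
                 frequencies = as.numeric(frequencies),
                 epoch_length_s = epoch_length_s,
                 K = nrow(phases)),
            class = "epoch_phase_table")
}

# phase matrix (epochs x frequencies) of a signal tiled with contiguous
# epochs from `start_s`; no minimum-epoch requirement (callers assemble an
# epoch_phase_table when K >= 2)
.epoch_phase_matrix <- function(signal, fs, frequencies, start_s = 0,
                                epoch_s = 1, n_epochs = NULL) {
  avail <- floor((length(signal) / fs - start_s) / epoch_s)
  if (is.null(n_epochs)) n_epochs <- avail
  if (n_epochs > avail) stop("signal too short for requested epochs")
  t(vapply(seq_len(n_epochs), function(k) {
    m <- extract_phases(signal, fs, frequencies,
                        window_start = start_s + (k - 1) * epoch_s,
                        window_length = epoch_s)
    m$measured_phases
  }, numeric(length(frequencies))))
}

# convenience wrapper returning an epoch_phase_table
.epoch_phases <- function(signal, fs, frequencies, start_s = 0, epoch_s = 1,
                          n_epochs = NULL) {
  epoch_phase_table(.epoch_phase_matrix(signal, fs, frequencies, start_s,
                                        epoch_s, n_epochs),
                    frequencies, epoch_s)
}

#' Latency consistency index (LCI)
#'
#' The circular mean resultant length of the per-epoch phases of one
#' component, `Mod(mean(exp(1i*alpha_k)))`, in `[0, 1]`. A stable latency
#' gives 1; with no phase locking the LCI is statistically
#' indistinguishable from 0. Mathematically this equals the phase-coupling
#' strength used by the MSPC baseline.
#'
#' @param table an [epoch_phase_table()].
#' @param frequency_index column index (or vector of indices; default all
#'   columns).
#' @return LCI value(s) in `[0, 1]`.
#' @export
lci <- function(table, frequency_index = seq_along(table$frequencies)) {
  stopifnot(inherits(table, "epoch_phase_table"))
  vapply(frequency_index, function(i)
    Mod(mean(exp(1i * table$phases[, i]))), numeric(1))
}

#' Significance threshold for the LCI
#'
#' The theoretical 95% point of the resultant length of `K` uniformly
#' random phases, `sqrt(3/K)`.
#'
#' @param K number of epochs (>= 1).
#' @return threshold in `[0, sqrt(3)]`.
#' @examples
#' lci_threshold(1200)  # 0.05
#' @export
lci_threshold <- function(K) {
  if (any(K < 1)) stop("K must be >= 1")
  sqrt(3 / K)
}

# analytic signal restricted to a frequency band, via FFT: negative
# frequencies zeroed, positive doubled, out-of-band bins zeroed
.analytic_band <- function(x, fs, f_lo, f_hi) {
  n <- length(x)
  X <- stats::fft(x)
  f <- (seq_len(n) - 1L) * fs / n
  f[f > fs / 2] <- f[f > fs / 2] - fs       # signed bin frequencies
  H <- ifelse(f > 0, 2, ifelse(f == 0, 1, 0))
  H[f < f_lo | f > f_hi] <- 0
  stats::fft(X * H, inverse = TRUE) / n
}

#' Phase-locking value of an epoch to a reference frequency
#'
#' Band-limits the epoch to `frequency +/- band_halfwidth`, takes the
#' analytic (Hilbert) phase, subtracts the reference oscillator phase
#' `2*pi*f*t`, trims 10% from each edge to suppress transients, and
#' returns the resultant length of the phase difference over time, a
#' value in `[0, 1]`.
#'
#' @param epoch numeric vector, one epoch of signal.
#' @param fs sampling rate in Hz.
#' @param frequency reference frequency in Hz.
#' @param band_halfwidth half-width of the analysis band in Hz (default
#'   2).
#' @return PLV in `[0, 1]`.
#' @export
plv <- function(epoch, fs, frequency, band_halfwidth = 2) {
  if (frequency + band_halfwidth > fs / 2) stop("band exceeds Nyquist")
  if (length(epoch) < 4 * fs / frequency)
    stop("epoch must span several cycles of the reference frequency")
  z <- .analytic_band(epoch, fs, frequency - band_halfwidth,
                      frequency + band_halfwidth)
  n <- length(epoch)
  trim <- seq.int(ceiling(n * 0.1) + 1L, floor(n * 0.9))
  t <- (seq_len(n) - 1L) / fs
  dphi <- Arg(z) - 2 * pi * frequency * t
  Mod(mean(exp(1i * dphi[trim])))
}

#' Retain epochs by phase-locking value
#'
#' @param epochs numeric matrix (rows: epochs) or list of numeric vectors.
#' @param fs sampling rate in Hz.
#' @param frequencies one or more frequencies of interest.
#' @param theta PLV threshold in `[0, 1]`; 0 retains everything.
#' @param combine `"mean"` (default) thresholds the mean PLV over
#'   `frequencies`; `"any"` retains an epoch if any frequency passes.
#' @param band_halfwidth passed to [plv()].
#' @return integer vector of retained epoch indices.
#' @export
filter_epochs_by_plv <- function(epochs, fs, frequencies, theta = 0,
                                 combine = c("mean", "any"),
                                 band_halfwidth = 2) {
  combine <- match.arg(combine)
  if (is.matrix(epochs)) epochs <- asplit(epochs, 1)
  if (theta < 0 || theta > 1) stop("theta must be in [0, 1]")
  if (theta == 0) return(seq_along(epochs))
  pass <- vapply(epochs, function(e) {
    v <- vapply(frequencies, function(f) plv(e, fs, f, band_halfwidth),
                numeric(1))
    if (combine == "mean") mean(v) >= theta else any(v >= theta)
  }, logical(1))
  which(pass)
}

#' One-sided periodogram power of a sampled signal
#'
#' Raw FFT periodogram, `Mod(fft(x))^2 / n`, at bin frequencies
#' `0, 1/T, 2/T, ...` up to Nyquist; bin width is the reciprocal of the
#' signal duration (1/12 Hz for a 12-s trial).
#'
#' @param signal numeric vector.
#' @param fs sampling rate in Hz.
#' @return data frame with columns `frequency` and `power`.
#' @export
periodogram_power <- function(signal, fs) {
  n <- length(signal)
  P <- Mod(stats::fft(signal))^2 / n
  k <- seq_len(floor(n / 2) + 1L)
  data.frame(frequency = (k - 1L) * fs / n, power = P[k])
}

#' Neighboring signal-to-noise ratio at a target frequency bin
#'
#' `10*log10` of the target-bin power over the mean power of the
#' neighboring bins within `+/- neighborhood` Hz, excluding the target bin
#' itself and any bins listed in `exclude` (e.g. other known steady-state
#' components). Under a pure-noise null the power ratio follows an
#' F(2, 2N) distribution, with `N` the number of neighbors used.
#'
#' @param power numeric vector of spectral powers (one per bin).
#' @param frequency numeric vector of bin frequencies in Hz, parallel to
#'   `power`.
#' @param target target frequency in Hz (must match a bin within half a
#'   bin width).
#' @param neighborhood half-width of the neighborhood in Hz (default 0.5).
#' @param exclude frequencies (Hz) whose bins are excluded from the
#'   neighbor average.
#' @return list with `snr_db`, `n_neighbors`, and `target_power`.
#' @export
neighboring_snr <- function(power, frequency, target, neighborhood = 0.5,
                            exclude = numeric(0)) {
  if (length(power) != length(frequency))
    stop("power and frequency must be parallel vectors")
  binw <- stats::median(diff(sort(frequency)))
  it <- which.min(abs(frequency - target))
  if (abs(frequency[it] - target) > binw / 2 + 1e-9)
    stop("target frequency does not match a spectral bin")
  nb <- which(abs(frequency - target) <= neighborhood + 1e-9)
  nb <- setdiff(nb, it)
  if (length(exclude))
    nb <- nb[!vapply(frequency[nb],
                     function(f) any(abs(f - exclude) <= binw / 2 + 1e-9),
                     logical(1))]
  if (length(nb) < 1L) stop("no neighbor bins in range")
  denom <- mean(power[nb])
  if (denom <= 0) stop("zero neighbor power")
  list(snr_db = 10 * log10(power[it] / denom),
       n_neighbors = length(nb),
       target_power = power[it])
}

#' F-test significance threshold for the neighboring SNR
#'
#' Under the noise-only null the neighboring power ratio is F(2, 2N)
#' distributed; the threshold is the `(1 - alpha)` quantile in dB.
#'
#' @param alpha type-I error level in (0, 1).
#' @param N number of neighboring bins (>= 1).
#' @return threshold in dB.
#' @examples
#' snr_threshold(0.05, 12)  # 5.318 dB
#' snr_threshold(0.01, 12)  # 7.492 dB
#' @export
snr_threshold <- function(alpha, N) {
  if (any(alpha <= 0) || any(alpha >= 1)) stop("alpha must be in (0, 1)")
  if (any(N < 1)) stop("N must be >= 1")
  10 * log10(stats::qf(1 - alpha, 2, 2 * N))
}
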