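# IIR filter primitives (second-order sections, forward-backward
# application). Implemented here because no DSP package is available in
# the target environment; designs are validated against analytic
# magnitude responses in the test suite.

# Butterworth high-pass as second-order sections via pole/zero bilinear
# transform. Returns a list of sections, each c(b0, b1, b2, a1, a2) with
# a0 = 1; sections are individually normalized to unit gain at Nyquist.
.butter_highpass_sos <- function(order, cutoff_hz, fs) {
  if (order < 2 || order %% 2 != 0) stop("order must be even and >= 2")
  if (cutoff_hz <= 0 || cutoff_hz >= fs / 2) stop("cutoff must be inside (0, Nyquist)")
  wc <- 2 * fs * tan(pi * cutoff_hz / fs)     # prewarped analog cutoff
  k <- seq_len(order / 2)
  theta <- pi * (2 * k + order - 1) / (2 * order)
  p_lp <- exp(1i * theta)                     # prototype poles, upper half
  p_hp <- wc / p_lp                           # lowpass -> highpass
  z <- (2 * fs + p_hp) / (2 * fs - p_hp)      # bilinear transform
  lapply(seq_along(z), function(i) {
    a1 <- -2 * Re(z[i]); a2 <- Mod(z[i])^2
    # normalize to unity gain at Nyquist (z = -1): numerator (1 - z^-1)^2
    # evaluates to 4, denominator to 1 - a1 + a2
    g <- (1 - a1 + a2) / 4
    c(b0 = g, b1 = -2 * g, b2 = g, a1 = a1, a2 = a2)
  })
}

# RBJ-style second-order IIR notch
.notch_sos <- function(notch_hz, fs, q = 35) {
  if (notch_hz <= 0 || notch_hz >= fs / 2) stop("notch must be inside (0, Nyquist)")
  w0 <- 2 * pi * notch_hz / fs
  al <- sin(w0) / (2 * q)
  b <- c(1, -2 * cos(w0), 1) / (1 + al)
  a <- c(-2 * cos(w0) / (1 + al), (1 - al) / (1 + al))
  list(c(b0 = b[1], b1 = b[2], b2 = b[3], a1 = a[1], a2 = a[2]))
}

# single forward pass of one biquad (direct form I via stats::filter)
.biquad <- function(x, s) {
  n <- length(x)
  v <- s[1] * x +
    s[2] * c(0, x[-n]) +
    s[3] * c(0, 0, x[-c(n - 1L, n)])
  as.numeric(stats::filter(v, c(-s[4], -s[5]), method = "recursive"))
}

# forward-backward (zero-phase) application of an SOS cascade with
# odd-symmetric edge padding
.filtfilt_sos <- function(x, sos, pad = NULL) {
  n <- length(x)
  if (is.null(pad)) pad <- min(n - 1L, 3L * 2L * length(sos) + 100L)
  pad <- min(pad, n - 1L)
  ext <- c(2 * x[1] - x[(pad + 1L):2L],
           x,
           2 * x[n] - x[(n - 1L):(n - pad)])
  for (s in sos) ext <- .biquad(ext, s)
  ext <- rev(ext)
  for (s in sos) ext <- .biquad(ext, s)
  rev(ext)[(pad + 1L):(pad + n)]
}

# complex frequency response of an SOS cascade at frequencies f (Hz)
.sos_response <- function(sos, f, fs) {
  z1 <- exp(-2i * pi * f / fs)
  H <- rep(1 + 0i, length(f))
  for (s in sos)
    H <- H * (s[1] + s[2] * z1 + s[3] * z1^2) /
      (1 + s[4] * z1 + s[5] * z1^2)
  H
}
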