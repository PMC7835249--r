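#' Describe a multi-tone stimulus complex
#'
#' A stimulus complex is a superposition of pure tones (the carriers) that
#' all start at `t = 0` with known initial phases. Zero-phase cosine
#' carriers are the recommended design: every nonlinear distortion product
#' of such a complex again has zero initial phase, which is what makes time
#' compensation (see [estimate_latency()]) work without any knowledge of
#' the nonlinearity.
#'
#' @param carriers numeric vector of carrier frequencies in Hz; strictly
#'   positive and pairwise distinct.
#' @param waveform `"cosine"` (default) or `"sine"`; the waveform used for
#'   every carrier.
#' @param initial_phases numeric vector of per-carrier initial phases in
#'   radians, recycled from a scalar; folded into `[0, 2*pi)`.
#' @param levels_db optional per-carrier sound levels (dB SPL); metadata
#'   only, never used in computations.
#' @param onset_skip seconds of response discarded after stimulus onset
#'   (the time-compensation offset `delta_t`); non-negative.
#' @param duration stimulus duration in seconds; must exceed `onset_skip`.
#'
#' @return An object of class `"stimulus_complex"`.
#' @examples
#' stimulus_complex(c(461, 500, 504, 537))
#' @export
stimulus_complex <- function(carriers,
                             waveform = c("cosine", "sine"),
                             initial_phases = 0,
                             levels_db = NULL,
                             onset_skip = 0,
                             duration = Inf) {
  waveform <- match.arg(waveform)
  carriers <- as.numeric(carriers)
  if (length(carriers) < 1L || any(!is.finite(carriers)) || any(carriers <= 0))
    stop("carriers must be finite, strictly positive frequencies (Hz)")
  if (anyDuplicated(carriers))
    stop("carriers must be pairwise distinct")
  initial_phases <- rep_len(as.numeric(initial_phases), length(carriers)) %% (2 * pi)
  if (!is.null(levels_db) && length(levels_db) != length(carriers))
    stop("levels_db must have one entry per carrier")
  if (onset_skip < 0) stop("onset_skip must be >= 0")
  if (duration <= onset_skip) stop("duration must exceed onset_skip")
  structure(
    list(carriers = carriers, waveform = waveform,
         initial_phases = initial_phases, levels_db = levels_db,
         onset_skip = onset_skip, duration = duration),
    class = "stimulus_complex")
}

#' @export
print.stimulus_complex <- function(x, ...) {
  cat(sprintf("<stimulus_complex> %d %s carrier(s): %s Hz\n",
              length(x$carriers), x$waveform,
              paste(x$carriers, collapse = ", ")))
  cat(sprintf("  initial phases (rad): %s; onset skip %.3g s\n",
              paste(signif(x$initial_phases, 4), collapse = ", "),
              x$onset_skip))
  invisible(x)
}

# All signed-integer coefficient vectors a with sum(|a|) <= max_order
# (excluding the all-zero vector), as a matrix with one row per vector.
.coefficient_vectors <- function(n_carriers, max_order) {
  per <- lapply(seq_len(n_carriers), function(i) seq(-max_order, max_order))
  grid <- as.matrix(expand.grid(per, KEEP.OUT.ATTRS = FALSE))
  ord <- rowSums(abs(grid))
  grid <- grid[ord >= 1 & ord <= max_order, , drop = FALSE]
  dimnames(grid) <- NULL
  grid
}

#' Enumerate nonlinear distortion products of a stimulus complex
#'
#' A nonlinearity of order R acting on a multi-tone input produces output
#' components at every combination frequency `|sum(a_i * f_i)|` with integer
#' coefficients `a_i` and `sum(|a_i|) <= R`. This routine enumerates all
#' such products, folds negative combination frequencies onto their positive
#' mirror (conjugating the predicted phase), merges frequencies equal within
#' `1e-9` Hz, and records every generating coefficient vector per frequency.
#'
#' @param stimulus a [stimulus_complex()].
#' @param max_order positive integer; maximum combination order
#'   `sum(|a_i|)`.
#' @param mode `"all"` (harmonics, sums and differences) or
#'   `"difference_only"` (exactly one `+1` and one `-1` coefficient, i.e.
#'   the pairwise beat frequencies).
#' @param band_limit optional upper frequency bound in Hz; products above
#'   it are dropped.
#' @param parity keep only coefficient vectors whose order has the same
#'   parity as this integer. A homogeneous polynomial `x^r` produces
#'   exactly the combinations with `sum(|a_i|) <= r` of the parity of `r`,
#'   so the default (`max_order`) yields the output set of an order-R
#'   system -- the sets the worked examples quote. Pass `NA` for the
#'   cumulative set of every order up to `max_order`, which is monotone in
#'   `max_order`.
#'
#' @return An object of class `"distortion_set"`: a list with `products`
#'   (a data frame with columns `frequency`, `order`, `predicted_phase` and
#'   a list column `coefficients`), `frequencies` (sorted unique
#'   frequencies), `stimulus`, and `max_order`.
#' @examples
#' st <- stimulus_complex(c(461, 500, 504, 537))
#' enumerate_distortions(st, 2, mode = "difference_only")$frequencies
#' # 4 33 37 39 43 76
#' @seealso [predict_initial_phase()]
#' @export
enumerate_distortions <- function(stimulus, max_order,
                                  mode = c("all", "difference_only"),
                                  band_limit = NULL, parity = max_order) {
  mode <- match.arg(mode)
  stopifnot(inherits(stimulus, "stimulus_complex"))
  if (length(max_order) != 1L || max_order < 1 || max_order != round(max_order))
    stop("max_order must be a positive integer")
  f <- stimulus$carriers
  a <- .coefficient_vectors(length(f), max_order)
  ord <- rowSums(abs(a))
  if (mode == "difference_only") {
    keep <- ord == 2 & rowSums(a) == 0 & rowSums(a == 1) == 1
    a <- a[keep, , drop = FALSE]; ord <- ord[keep]
  } else if (!is.na(parity)) {
    keep <- (ord %% 2) == (parity %% 2)
    a <- a[keep, , drop = FALSE]; ord <- ord[keep]
  }
  freq_signed <- drop(a %*% f)
  # canonical representative: positive combination frequency (its mirror -a
  # is the complex conjugate and carries no extra information)
  keep <- freq_signed > 1e-9
  a <- a[keep, , drop = FALSE]; ord <- ord[keep]
  freq <- freq_signed[keep]
  if (!is.null(band_limit)) {
    keep <- freq <= band_limit + 1e-9
    a <- a[keep, , drop = FALSE]; ord <- ord[keep]; freq <- freq[keep]
  }
  o <- order(freq, ord)
  a <- a[o, , drop = FALSE]; ord <- ord[o]; freq <- freq[o]
  phase <- vapply(seq_along(freq), function(i)
    predict_initial_phase(a[i, ], stimulus), numeric(1))
  products <- data.frame(frequency = freq, order = ord,
                         predicted_phase = phase)
  products$coefficients <- lapply(seq_len(nrow(a)), function(i) as.integer(a[i, ]))
  # merge keys equal within 1e-9 Hz (exact for integer-Hz designs)
  key <- cumsum(c(TRUE, diff(freq) > 1e-9))
  ufreq <- as.numeric(tapply(freq, key, function(z) z[1]))
  structure(
    list(products = products, frequencies = ufreq,
         frequency_key = key, stimulus = stimulus, max_order = max_order,
         mode = mode, band_limit = band_limit),
    class = "distortion_set")
}

#' @export
print.distortion_set <- function(x, ...) {
  cat(sprintf("<distortion_set> %d product(s) at %d distinct frequencies (order <= %d)\n",
              nrow(x$products), length(x$frequencies), x$max_order))
  cat("  frequencies (Hz):", paste(signif(x$frequencies, 6), collapse = ", "), "\n")
  invisible(x)
}

#' Coerce a distortion set to a data frame
#'
#' @param x a `distortion_set`.
#' @param ... unused.
#' @return data frame with columns `frequency_hz`, `order`, `coefficients`
#'   (semicolon-joined) and `predicted_phase_rad`, one row per generating
#'   coefficient vector.
#' @export
as.data.frame.distortion_set <- function(x, ...) {
  data.frame(
    frequency_hz = x$products$frequency,
    order = x$products$order,
    coefficients = vapply(x$products$coefficients,
                          function(a) paste(a, collapse = ";"), character(1)),
    predicted_phase_rad = x$products$predicted_phase)
}

#' Predict the initial phase of a distortion product
#'
#' For carriers `w(2*pi*f_i*t + phi_i)` (with `w` either cosine or sine) the
#' combination product with coefficients `a` appears at frequency
#' `sum(a_i*f_i)` with phase `sum(a_i*phi_i)` *in the carrier waveform's own
#' reference*. The returned phase is referenced to the carrier waveform, so
#' the product component reads `w(2*pi*f*t + phase)`:
#' * cosine carriers, all `phi_i = 0`: every product has phase 0;
#' * sine carriers, all `phi_i = 0`: a product picks up an extra offset of
#'   `-(pi/2)*sum(a_i) + pi/2` (a multiple of `pi/2`); in particular every
#'   even-order pure-difference product (`sum(a_i) = 0`) has phase `pi/2`.
#'
#' If the signed combination frequency is negative the product is folded to
#' its positive mirror, which conjugates (negates) the phase.
#'
#' @param coefficients signed integer coefficient vector, one entry per
#'   carrier (a `DistortionProduct`'s `coefficients`).
#' @param stimulus the [stimulus_complex()] the product derives from.
#' @param method `"analytic"` (closed form above, default) or `"numeric"`
#'   (synthesize the isolated polynomial product on surrogate carriers and
#'   read the phase off a discrete Fourier projection; slow, used as an
#'   independent cross-check).
#' @return phase in radians in `[0, 2*pi)`.
#' @examples
#' st <- stimulus_complex(c(461, 500), waveform = "sine")
#' predict_initial_phase(c(1, -1), st)  # pi/2
#' @export
predict_initial_phase <- function(coefficients, stimulus,
                                  method = c("analytic", "numeric")) {
  method <- match.arg(method)
  stopifnot(inherits(stimulus, "stimulus_complex"))
  a <- as.numeric(coefficients)
  if (length(a) != length(stimulus$carriers))
    stop("coefficients must have one entry per carrier")
  if (method == "numeric")
    return(.numeric_product_phase(a, stimulus))
  fold <- sum(a * stimulus$carriers) < 0
  if (stimulus$waveform == "cosine") {
    ph <- sum(a * stimulus$initial_phases)
    if (fold) ph <- -ph
  } else {
    # sine = cosine shifted by -pi/2; fold in cosine reference, then
    # re-express the folded product in the sine reference (+pi/2)
    ph_cos <- sum(a * (stimulus$initial_phases - pi / 2))
    if (fold) ph_cos <- -ph_cos
    ph <- ph_cos + pi / 2
  }
  ph %% (2 * pi)
}

# Independent numeric oracle: re-express the combination on surrogate
# integer-Hz carriers chosen so that, inside the monomial
# prod_i x_i^(|a_i|), the target combination frequency is produced by the
# target coefficient vector alone, then read its phase by Fourier
# projection over an exactly commensurate 1-s window.
.numeric_product_phase <- function(a, stimulus) {
  n <- length(a)
  absa <- abs(a)
  active <- which(absa > 0)
  # surrogate frequencies: spread primes keep combination frequencies unique
  primes <- c(101, 137, 173, 211, 251, 293, 331, 373, 419, 457)
  if (n > length(primes)) stop("numeric oracle supports at most 10 carriers")
  fs_sur <- primes[seq_len(n)]
  target <- sum(a * fs_sur)
  # all combinations b with |b_i| <= |a_i| and b_i == |a_i| (mod 2) occur in
  # the monomial; verify the target is unique among them
  combos <- expand.grid(lapply(absa, function(m) seq(-m, m, by = 2)),
                        KEEP.OUT.ATTRS = FALSE)
  cf <- as.matrix(combos) %*% fs_sur
  if (sum(abs(abs(cf) - abs(target)) < 1e-9) != if (target == 0) 1 else 2)
    stop("surrogate frequencies produce an overlapping product; oracle invalid")
  fs <- 4L * (sum(absa * fs_sur) + 1L)   # beyond Nyquist of every product
  t <- seq(0, 1, length.out = fs + 1L)[-(fs + 1L)]
  wav <- if (stimulus$waveform == "cosine") cos else sin
  x <- rep(1, fs)
  for (i in active)
    x <- x * wav(2 * pi * fs_sur[i] * t + stimulus$initial_phases[i])^absa[i]
  z <- sum(x * exp(-2i * pi * abs(target) * t)) * 2 / fs
  if (Mod(z) < 1e-6) stop("target product has vanishing amplitude")
  # Arg(z) is the cosine-referenced phase of the folded surrogate product;
  # unfold to the signed combination, then fold by the *original* carriers
  ph <- sign(target) * Arg(z)
  if (sum(a * stimulus$carriers) < 0) ph <- -ph
  if (stimulus$waveform == "sine") ph <- ph + pi / 2
  ph %% (2 * pi)
}
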