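# run `expr` under a temporary RNG seed, restoring the caller's RNG state
.with_seed <- function(seed, expr) {
  if (is.null(seed)) return(eval.parent(substitute(expr)))
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else suppressWarnings(rm(".Random.seed", envir = genv))
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}

#' Specify one nonlinear subsystem of the hybrid model
#'
#' A subsystem selects a subset of the stimulus carriers (its band-pass
#' input), delays them by a common latency, and applies a polynomial
#' nonlinearity `sum_r psi_r * x^r`.
#'
#' @param carrier_idx integer indices into the stimulus carriers that
#'   drive this subsystem.
#' @param orders integer polynomial orders (>= 1).
#' @param gains per-order gains `psi_r` (recycled from a scalar; default
#'   1).
#' @param latency_ms subsystem latency `tau_m` in ms (>= 0).
#' @param output_gain scalar gain `xi` applied to the subsystem output in
#'   the mixture (default 1).
#' @return object of class `"subsystem_spec"`.
#' @export
subsystem_spec <- function(carrier_idx, orders, gains = 1, latency_ms,
                           output_gain = 1) {
  orders <- as.integer(orders)
  if (any(orders < 1)) stop("orders must be >= 1")
  if (latency_ms < 0) stop("latency_ms must be >= 0")
  gains <- rep_len(as.numeric(gains), length(orders))
  structure(list(carrier_idx = as.integer(carrier_idx), orders = orders,
                 gains = gains, latency_ms = latency_ms,
                 output_gain = output_gain),
            class = "subsystem_spec")
}

#' Assemble a simulation recipe
#'
#' @param stimulus a [stimulus_complex()].
#' @param subsystems list of [subsystem_spec()] objects.
#' @param duration_s signal duration in seconds.
#' @param fs_hz sampling rate in Hz; must exceed twice the highest
#'   distortion frequency any subsystem can produce.
#' @param snr_db signal-to-noise ratio of the additive white Gaussian
#'   noise in dB, relative to the measured power of the noise-free
#'   mixture; `NULL` for a noise-free signal.
#' @param seed RNG seed for the noise (recorded in all outputs).
#' @return object of class `"simulation_recipe"`.
#' @export
simulation_recipe <- function(stimulus, subsystems, duration_s = 100,
                              fs_hz = 1000, snr_db = NULL, seed = NULL) {
  stopifnot(inherits(stimulus, "stimulus_complex"))
  if (!all(vapply(subsystems, inherits, logical(1), "subsystem_spec")))
    stop("subsystems must be subsystem_spec objects")
  fmax <- max(vapply(subsystems, function(s)
    max(s$orders) * max(stimulus$carriers[s$carrier_idx]), numeric(1)))
  if (fs_hz <= 2 * fmax)
    stop(sprintf("aliasing: product frequency %.0f Hz at or above Nyquist (fs = %.0f Hz)",
                 fmax, fs_hz))
  structure(list(stimulus = stimulus, subsystems = subsystems,
                 duration_s = duration_s, fs_hz = fs_hz,
                 snr_db = snr_db, seed = seed),
            class = "simulation_recipe")
}

#' Synthesize the hybrid nonlinear model
#'
#' Evaluates `Y(t) = sum_m xi_m * sum_r psi_mr * x_m(t - tau_m)^r` on the
#' sampling grid (delays applied analytically, so there is no start-up
#' transient) and, if requested, adds white Gaussian noise calibrated so
#' that `10*log10(P_signal / P_noise)` equals `snr_db` with respect to the
#' measured mean-square power of the noise-free mixture.
#'
#' @param recipe a [simulation_recipe()].
#' @return list with `signal` (numeric vector), `t` (seconds),
#'   `noise_free` (the mixture before noise), `noise_sd`,
#'   `ground_truth` (per-subsystem [enumerate_distortions()] sets),
#'   and `recipe`.
#' @export
synthesize <- function(recipe) {
  stopifnot(inherits(recipe, "simulation_recipe"))
  st <- recipe$stimulus
  fs <- recipe$fs_hz
  n <- round(recipe$duration_s * fs)
  t <- (seq_len(n) - 1L) / fs
  wav <- if (st$waveform == "cosine") cos else sin
  clean <- numeric(n)
  for (sub in recipe$subsystems) {
    td <- t - sub$latency_ms / 1000
    x <- numeric(n)
    for (i in sub$carrier_idx)
      x <- x + wav(2 * pi * st$carriers[i] * td + st$initial_phases[i])
    y <- numeric(n)
    for (k in seq_along(sub$orders))
      y <- y + sub$gains[k] * x^sub$orders[k]
    clean <- clean + sub$output_gain * y
  }
  noise_sd <- 0
  signal <- clean
  if (!is.null(recipe$snr_db)) {
    p_sig <- mean(clean^2)
    noise_sd <- sqrt(p_sig / 10^(recipe$snr_db / 10))
    signal <- clean + .with_seed(recipe$seed, stats::rnorm(n, sd = noise_sd))
  }
  gt <- lapply(recipe$subsystems, function(sub) {
    sub_st <- stimulus_complex(st$carriers[sub$carrier_idx], st$waveform,
                               st$initial_phases[sub$carrier_idx],
                               onset_skip = st$onset_skip,
                               duration = st$duration)
    sets <- lapply(sub$orders, function(r)
      enumerate_distortions(sub_st, r, parity = r))
    list(spec = sub, frequencies = sort(unique(unlist(
      lapply(sets, `[[`, "frequencies")))), sets = sets)
  })
  list(signal = signal, t = t, noise_free = clean, noise_sd = noise_sd,
       ground_truth = gt, recipe = recipe)
}

#' Detect candidate steady-state components in a simulated response
#'
#' Nonparametric candidate screen used before forward selection: every
#' integer frequency bin in `band` whose neighboring SNR exceeds the
#' F-test threshold at `alpha` *and* whose latency consistency index over
#' 1-s epochs exceeds `sqrt(3/K)` is retained.
#'
#' @param signal sampled response.
#' @param fs sampling rate in Hz.
#' @param window_start analysis-window start in seconds.
#' @param band length-2 integer frequency range to scan (default
#'   `c(2, 150)`).
#' @param alpha type-I level of the SNR screen (default 0.01).
#' @param epoch_s epoch length for the LCI screen (default 1 s).
#' @return list with `frequencies`, `snr_db`, `lci`, `epoch_table`
#'   (phases of the retained frequencies), and `K`.
#' @export
detect_candidates <- function(signal, fs, window_start = 0,
                              band = c(2, 150), alpha = 0.01, epoch_s = 1) {
  win_len <- floor(length(signal) / fs - window_start)
  i0 <- round(window_start * fs)
  spec <- periodogram_power(signal[(i0 + 1L):(i0 + win_len * fs)], fs)
  freqs <- seq(ceiling(band[1]), floor(min(band[2], fs / 2 - 1)))
  sn <- lapply(freqs, function(f)
    neighboring_snr(spec$power, spec$frequency, f))
  snr <- vapply(sn, `[[`, numeric(1), "snr_db")
  thr <- vapply(sn, function(s) snr_threshold(alpha, s$n_neighbors),
                numeric(1))
  keep <- snr > thr
  freqs <- freqs[keep]; snr <- snr[keep]
  if (!length(freqs))
    return(list(frequencies = numeric(0), snr_db = numeric(0),
                lci = numeric(0), epoch_table = NULL, K = 0L))
  tab <- .epoch_phases(signal, fs, freqs, start_s = window_start,
                       epoch_s = epoch_s)
  ci <- lci(tab)
  keep <- ci > lci_threshold(tab$K)
  list(frequencies = freqs[keep], snr_db = snr[keep], lci = ci[keep],
       epoch_table = epoch_phase_table(tab$phases[, keep, drop = FALSE],
                                       freqs[keep], epoch_s),
       K = tab$K)
}

# published worked-example recipes
.example_recipe <- function(which, snr_db, seed, fs_hz, duration_s,
                            delta_t_s) {
  if (which == 1) {
    st <- stimulus_complex(c(17, 21, 27, 41, 49), onset_skip = delta_t_s,
                           duration = duration_s)
    subs <- list(subsystem_spec(1:3, 2, latency_ms = 51),
                 subsystem_spec(4:5, 2, latency_ms = 21))
    list(recipe = simulation_recipe(st, subs, duration_s, fs_hz, snr_db, seed),
         sfs_start = 38, mspc_orders = 2)
  } else if (which == 2) {
    st <- stimulus_complex(c(37, 43, 38, 46), onset_skip = delta_t_s,
                           duration = duration_s)
    subs <- list(subsystem_spec(1:2, c(2, 3), latency_ms = 51),
                 subsystem_spec(3:4, c(2, 3), latency_ms = 21))
    list(recipe = simulation_recipe(st, subs, duration_s, fs_hz, snr_db, seed),
         sfs_start = 6, mspc_orders = c(2, 3))
  } else if (which == 3) {
    st <- stimulus_complex(c(17, 21, 27), onset_skip = delta_t_s,
                           duration = duration_s)
    subs <- list(subsystem_spec(1:3, 2, latency_ms = 15, output_gain = 1),
                 subsystem_spec(1:3, 2, latency_ms = 20))
    list(recipe = simulation_recipe(st, subs, duration_s, fs_hz, snr_db, seed),
         sfs_start = 10, mspc_orders = 2)
  } else stop("which must be 1, 2 or 3")
}

#' Run one of the published worked examples end to end
#'
#' Builds the stated two-subsystem recipe, synthesizes the mixture,
#' screens candidate components ([detect_candidates()]), runs ALPC-SFS
#' ([extract_all_latencies()]) starting from the stated frequency, and
#' runs the MSPC baseline at the stated assumed orders.
#'
#' * Example 1: pure 2nd-order subsystems on carriers (17, 21, 27) and
#'   (41, 49) Hz with latencies 51 and 21 ms.
#' * Example 2: mixed 2nd+3rd-order subsystems on (37, 43) and (38, 46)
#'   Hz with latencies 51 and 21 ms.
#' * Example 3: two 2nd-order subsystems sharing carriers (17, 21, 27) Hz
#'   with latencies 15 and 20 ms and relative gain `xi` on the first.
#'
#' @param which 1, 2 or 3.
#' @param snr_db SNR of the additive noise in dB (`NULL` = noise-free;
#'   default 5).
#' @param seed RNG seed.
#' @param fs_hz sampling rate (default 1000 Hz).
#' @param duration_s duration (default 100 s; long windows sharpen the
#'   phase estimates at low SNR).
#' @param delta_t_s onset-skip/time-compensation offset (default 0.3 s).
#' @param xi relative gain of the first subsystem (example 3 only).
#' @return object of class `"alpc_report"`: the recipe, candidate screen,
#'   `alpc` (list of `sfs_result`), `mspc` (list of per-order results)
#'   and ground truth.
#' @export
run_example <- function(which, snr_db = 5, seed = NULL, fs_hz = 1000,
                        duration_s = 100, delta_t_s = 0.3, xi = 1) {
  ex <- .example_recipe(which, snr_db, seed, fs_hz, duration_s, delta_t_s)
  if (which == 3) ex$recipe$subsystems[[1]]$output_gain <- xi
  sim <- synthesize(ex$recipe)
  win_len <- floor(duration_s - delta_t_s)
  cand <- detect_candidates(sim$signal, fs_hz, window_start = delta_t_s)
  pm <- extract_phases(sim$signal, fs_hz, cand$frequencies,
                       window_start = delta_t_s, window_length = win_len)
  cfg <- sfs_config(start = ex$sfs_start)
  alpc <- extract_all_latencies(pm, cfg, lci_values = cand$lci)
  mspc <- lapply(ex$mspc_orders, function(r)
    mspc_estimate(ex$recipe$stimulus, r, sim$signal, fs_hz,
                  window_start = delta_t_s, snr_alpha = 0.01))
  names(mspc) <- paste0("order", ex$mspc_orders)
  structure(list(which = which, recipe = ex$recipe, candidates = cand,
                 measurement = pm, alpc = alpc, mspc = mspc,
                 ground_truth = sim$ground_truth, seed = seed,
                 sfs_start = ex$sfs_start),
            class = "alpc_report")
}

#' @export
print.alpc_report <- function(x, ...) {
  cat(sprintf("<alpc_report> worked example %d (seed %s)\n", x$which,
              if (is.null(x$seed)) "none" else x$seed))
  cat(sprintf("  %d candidate component(s): %s Hz\n",
              length(x$candidates$frequencies),
              paste(x$candidates$frequencies, collapse = ", ")))
  for (i in seq_along(x$alpc))
    cat(sprintf("  ALPC-SFS subsystem %d: %.2f ms (MPE %.4g) on {%s} Hz\n",
                i, x$alpc[[i]]$estimate$latency_ms, x$alpc[[i]]$estimate$mpe,
                paste(x$alpc[[i]]$selected, collapse = ", ")))
  for (nm in names(x$mspc)) {
    m <- x$mspc[[nm]]
    if (isTRUE(m$no_estimate)) cat(sprintf("  MSPC %s: no estimate\n", nm))
    else cat(sprintf("  MSPC %s: %.2f ms (MPE %.4g, %d components)\n", nm,
                     m$estimate$latency_ms, m$estimate$mpe,
                     length(m$frequencies)))
  }
  invisible(x)
}

#' Overlapping-output mixing experiment
#'
#' Two 2nd-order subsystems share all carriers (17, 21, 27 Hz), so their
#' nine output components coincide and only the mixed phases are
#' observable. For each relative gain `xi` (applied to the
#' shorter-latency subsystem) the single mixed latency is estimated; the
#' estimates, normalized to `[0, 1]` over the grid, are fitted with the
#' logistic `f(x) = a / (1 + exp(-b*x))` in `x = log(xi)` by nonlinear
#' least squares. Numerically, `xi -> Inf` drives the mixed latency to
#' `tau1` (the gained subsystem), so the fitted `b` is negative for
#' `tau1 < tau2`; the magnitude `|b|` is the shape constant of the
#' phasor-averaging law.
#'
#' @param tau1_ms,tau2_ms the two latencies in ms (`tau1_ms <= tau2_ms`);
#'   defaults 15 and 20.
#' @param xi_grid positive relative gains; defaults to the published
#'   15-point grid from 1/100 to 100.
#' @param snr_db noise level (`NULL` = noise-free, the default).
#' @param seed RNG seed (noise only).
#' @param fs_hz sampling rate (default 1000).
#' @param duration_s duration; default 2 s noise-free (delays are exact,
#'   so short commensurate windows lose nothing), 100 s with noise.
#' @return list with `table` (data frame: xi, log_xi, latency_ms, mpe,
#'   normalized), `fit` (list: a, b, se, ci95, converged), and the inputs.
#' @export
mixing_experiment <- function(tau1_ms = 15, tau2_ms = 20,
                              xi_grid = c(1/100, 1/10, 1/6, 1/4, 1/3, 1/2,
                                          1/sqrt(2), 1, sqrt(2), 2, 3, 4, 6,
                                          10, 100),
                              snr_db = NULL, seed = NULL, fs_hz = 1000,
                              duration_s = NULL) {
  if (tau1_ms > tau2_ms) stop("tau1_ms must be <= tau2_ms")
  if (any(xi_grid <= 0)) stop("xi values must be > 0")
  if (is.null(duration_s)) duration_s <- if (is.null(snr_db)) 2 else 100
  st <- stimulus_complex(c(17, 21, 27), duration = duration_s)
  freqs <- enumerate_distortions(st, 2, parity = 2)$frequencies
  lat <- mpe <- numeric(length(xi_grid))
  for (k in seq_along(xi_grid)) {
    rec <- simulation_recipe(
      st,
      list(subsystem_spec(1:3, 2, latency_ms = tau1_ms,
                          output_gain = xi_grid[k]),
           subsystem_spec(1:3, 2, latency_ms = tau2_ms)),
      duration_s, fs_hz, snr_db,
      seed = if (is.null(seed)) NULL else seed + k)
    sim <- synthesize(rec)
    pm <- extract_phases(sim$signal, fs_hz, freqs,
                         window_length = floor(duration_s))
    res <- sfs_select(pm, sfs_config(start = 10))
    lat[k] <- res$estimate$latency_ms
    mpe[k] <- res$estimate$mpe
  }
  normalized <- (lat - min(lat)) / (max(lat) - min(lat))
  tab <- data.frame(xi = xi_grid, log_xi = log(xi_grid),
                    latency_ms = lat, mpe = mpe, normalized = normalized)
  fit <- list(converged = FALSE, a = NA_real_, b = NA_real_,
              se = c(a = NA_real_, b = NA_real_),
              ci95 = matrix(NA_real_, 2, 2,
                            dimnames = list(c("a", "b"), c("lo", "hi"))))
  b0 <- if (stats::cor(tab$log_xi, normalized) < 0) -1 else 1
  fit_try <- try(stats::nls(normalized ~ a / (1 + exp(-b * log_xi)),
                            data = tab, start = list(a = 1, b = b0)),
                 silent = TRUE)
  if (!inherits(fit_try, "try-error")) {
    cf <- stats::coef(fit_try)
    se <- sqrt(diag(stats::vcov(fit_try)))
    fit <- list(converged = TRUE, a = unname(cf["a"]), b = unname(cf["b"]),
                se = se,
                ci95 = cbind(lo = cf - 1.96 * se, hi = cf + 1.96 * se),
                model = fit_try)
  }
  list(table = tab, fit = fit, tau1_ms = tau1_ms, tau2_ms = tau2_ms,
       snr_db = snr_db, seed = seed)
}
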