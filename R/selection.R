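#' Configure sequential forward selection
#'
#' @param start a single frequency, a length-2 frequency pair, or `"auto"`
#'   (pick the pair with the two largest LCI values, falling back to
#'   amplitude, ties toward the lower frequency).
#' @param max_mpe selection stops when the MPE would exceed this (default
#'   0.5).
#' @param max_mpe_step selection stops when one step would increase the
#'   summed phase-error length (the added component's residual chord) by
#'   at least this much (default 0.1); see [sfs_select()].
#' @param max_latency_jump_ms pair-start only: stop when one step would
#'   move the latency estimate by at least this much (default 5 ms).
#' @param prior_range_ms latency prior passed to [estimate_latency()].
#' @param grid_step_ms grid resolution passed to [estimate_latency()].
#' @return An object of class `"sfs_config"`.
#' @export
sfs_config <- function(start = "auto", max_mpe = 0.5, max_mpe_step = 0.1,
                       max_latency_jump_ms = 5, prior_range_ms = c(0, 100),
                       grid_step_ms = 0.1) {
  if (!identical(start, "auto")) {
    start <- as.numeric(start)
    if (!length(start) %in% 1:2) stop("start must be one frequency, a pair, or \"auto\"")
  }
  if (max_mpe <= 0 || max_mpe > 2) stop("max_mpe must be in (0, 2]")
  if (max_mpe_step <= 0) stop("max_mpe_step must be positive")
  if (max_latency_jump_ms <= 0) stop("max_latency_jump_ms must be positive")
  structure(list(start = start, max_mpe = max_mpe,
                 max_mpe_step = max_mpe_step,
                 max_latency_jump_ms = max_latency_jump_ms,
                 prior_range_ms = prior_range_ms,
                 grid_step_ms = grid_step_ms),
            class = "sfs_config")
}

.sfs_auto_start <- function(candidates, lci_values = NULL) {
  score <- lci_values
  if (is.null(score)) score <- candidates$amplitudes
  if (is.null(score)) score <- rep(0, length(candidates$frequencies))
  # two largest scores; ties resolved toward the lower frequency
  o <- order(-score, candidates$frequencies)
  candidates$frequencies[o[seq_len(min(2L, length(o)))]]
}

#' Grow a latency-consistent frequency subset by forward selection
#'
#' Starting from one frequency (or a pair), repeatedly adds the remaining
#' candidate that yields the smallest new MPE after re-estimating the
#' common latency. A candidate is committed only if (i) the step increase
#' of the summed phase-error length, `n_new * MPE_new - n_old * MPE_old`
#' (which is the residual phase-error chord contributed by the added
#' component), stays below `max_mpe_step`, (ii) the MPE stays below
#' `max_mpe`, and (iii) for a pair start the latency change stays below
#' `max_latency_jump_ms`; the first violation terminates the search
#' without adding the offending frequency. Criterion (i) is deliberately
#' a *total*-error increase, not a mean increase: with `n` components
#' already selected, an inconsistent component contributing a chord `c`
#' raises the mean by only `c/(n+1)`, which for moderate `n` can never
#' reach a fixed mean threshold, so a mean-based rule would absorb
#' near-commensurate components of a foreign subsystem into large
#' subsets.
#'
#' @param candidates a [phase_measurement()] of all significant candidate
#'   components.
#' @param config an [sfs_config()].
#' @param lci_values optional per-candidate LCI values used by
#'   `start = "auto"`.
#' @return a list of class `"sfs_result"`: `selected` frequencies,
#'   `estimate` (the [estimate_latency()] result on the selected subset),
#'   and `trace` (data frame of step, added frequency, MPE, latency).
#' @export
sfs_select <- function(candidates, config = sfs_config(), lci_values = NULL) {
  stopifnot(inherits(candidates, "phase_measurement"),
            inherits(config, "sfs_config"))
  start <- config$start
  if (identical(start, "auto")) start <- .sfs_auto_start(candidates, lci_values)
  pair_start <- length(start) == 2L
  if (!all(start %in% candidates$frequencies))
    stop("start frequency absent from candidates")
  if (length(candidates$frequencies) < 2L)
    stop("need at least 2 candidate frequencies")

  est <- function(freqs)
    estimate_latency(.pm_subset(candidates, freqs),
                     prior_range_ms = config$prior_range_ms,
                     grid_step_ms = config$grid_step_ms)
  selected <- start
  current <- est(selected)
  trace <- data.frame(step = seq_along(start),
                      added_freq = start,
                      mpe = current$mpe,
                      latency_ms = current$latency_ms)
  remaining <- setdiff(candidates$frequencies, selected)
  while (length(remaining) > 0L) {
    trials <- lapply(remaining, function(f) est(c(selected, f)))
    mpes <- vapply(trials, function(e) e$mpe, numeric(1))
    k <- which.min(mpes)
    nxt <- trials[[k]]
    step_inc <- (length(selected) + 1L) * nxt$mpe -
      length(selected) * current$mpe
    if (step_inc >= config$max_mpe_step) break
    if (nxt$mpe >= config$max_mpe) break
    if (pair_start &&
        abs(nxt$latency_ms - current$latency_ms) >= config$max_latency_jump_ms) break
    selected <- c(selected, remaining[k])
    remaining <- remaining[-k]
    current <- nxt
    trace <- rbind(trace, data.frame(step = nrow(trace) + 1L,
                                     added_freq = selected[length(selected)],
                                     mpe = current$mpe,
                                     latency_ms = current$latency_ms))
  }
  structure(list(selected = selected, estimate = current, trace = trace,
                 start = start),
            class = "sfs_result")
}

#' @export
print.sfs_result <- function(x, ...) {
  cat(sprintf("<sfs_result> %d selected: %s Hz\n", length(x$selected),
              paste(x$selected, collapse = ", ")))
  cat(sprintf("  latency %.3f ms, MPE %.4g\n",
              x$estimate$latency_ms, x$estimate$mpe))
  invisible(x)
}

#' Extract multiple latencies by repeated forward selection
#'
#' Runs [sfs_select()], removes the selected subset from the candidate
#' pool, and repeats on the remainder until fewer than two candidates are
#' left, no subset meets the MPE bound, or `max_subsystems` subsets were
#' extracted. The configured start applies to the first pass; subsequent
#' passes use `"auto"` on the remaining candidates.
#'
#' @inheritParams sfs_select
#' @param max_subsystems maximum number of subsets to extract (default 5).
#' @return list of `"sfs_result"` objects (possibly empty); the selected
#'   subsets are pairwise disjoint.
#' @export
extract_all_latencies <- function(candidates, config = sfs_config(),
                                  max_subsystems = 5, lci_values = NULL) {
  stopifnot(inherits(candidates, "phase_measurement"))
  out <- list()
  pool <- candidates
  pool_lci <- lci_values
  cfg <- config
  while (length(out) < max_subsystems && length(pool$frequencies) >= 2L) {
    res <- sfs_select(pool, cfg, lci_values = pool_lci)
    if (res$estimate$mpe >= config$max_mpe) break
    out[[length(out) + 1L]] <- res
    keep <- !(pool$frequencies %in% res$selected)
    if (!any(keep)) break
    pool_lci <- if (is.null(pool_lci)) NULL else pool_lci[keep]
    pool <- .pm_subset(pool, pool$frequencies[keep])
    cfg$start <- "auto"
  }
  out
}
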