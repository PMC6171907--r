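#' Decision-consistency curve of the reservoir simulator
#'
#' For each of `n_runs` independent simulations, a reference decision is
#' read at cycle `t0` and a lag-t decision at cycle `t0 + t`; the
#' consistency indicator is 1 when the two agree, and the curve reports
#' its mean over runs for every lag. With the default
#' `readout = "exact"`, a run contributes to a lag only when both cycles
#' actually carry a decision (stalled cycles are excluded and tallied in
#' `n_excluded`). With `readout = "next-decision"`, each decision is read
#' from the first decision-bearing cycle at or after the nominal cycle,
#' and a run is excluded only when no such cycle exists in range.
#'
#' Decision consistency above 0.5 is the signature of choice-based
#' learning: small reservoirs and long lifetimes give high consistency at
#' short lags, while consistency decays to 0.5 (no correlation) at long
#' lags or for large reservoirs.
#'
#' @param config A [reservoir_config()].
#' @param t0 Reference cycle (default 2000, a burn-in long enough for the
#'   state to forget the fully-stocked initial condition).
#' @param max_lag Largest lag t to evaluate (default 100).
#' @param n_runs Number of independent runs (default 10000).
#' @param n_cycles Cycles per run; defaults to `t0 + max_lag + lookahead`.
#' @param lookahead Extra cycles beyond `t0 + max_lag` kept so that, under
#'   `readout = "next-decision"`, a stalled cycle near the end can still
#'   resolve to its next decision (default `2 * lifetime`).
#' @param readout `"exact"` (decisions read at the nominal cycles, stalled
#'   cycles excluded) or `"next-decision"` (read from the first
#'   decision-bearing cycle at or after the nominal cycle).
#' @return A tibble of class `consistency_curve` with columns `lag`,
#'   `mean_consistency`, `n_runs_used`, `n_excluded`.
#' @examples
#' cc <- decision_consistency_curve(reservoir_config(4, 10, seed = 7),
#'                                  t0 = 200, max_lag = 20, n_runs = 200)
#' head(cc)
#' @export
decision_consistency_curve <- function(config, t0 = 2000L, max_lag = 100L,
                                       n_runs = 10000L, n_cycles = NULL,
                                       lookahead = NULL,
                                       readout = c("exact", "next-decision")) {
  stopifnot(inherits(config, "reservoir_config"))
  t0 <- check_count(t0, "t0", min = 1L)
  max_lag <- check_count(max_lag, "max_lag", min = 1L)
  n_runs <- check_count(n_runs, "n_runs", min = 1L)
  readout <- match.arg(readout)
  if (is.null(lookahead))
    lookahead <- if (readout == "exact") 1L else 2L * config$lifetime
  if (is.null(n_cycles)) n_cycles <- t0 + max_lag + lookahead
  n_cycles <- check_count(n_cycles, "n_cycles", min = t0 + max_lag + 1L)
  res <- with_seed(config$seed,
                   cpp_consistency_mc(config$n_levels, config$lifetime,
                                      t0, max_lag, n_runs, n_cycles,
                                      readout == "exact"))
  out <- tibble::tibble(
    lag = seq_len(max_lag),
    mean_consistency = ifelse(res$valid > 0, res$match / res$valid, NA_real_),
    n_runs_used = as.integer(res$valid),
    n_excluded = n_runs - as.integer(res$valid)
  )
  attr(out, "config") <- config
  attr(out, "t0") <- t0
  attr(out, "readout") <- readout
  attr(out, "mean_active_portion") <- res$mean_active_portion
  class(out) <- c("consistency_curve", class(out))
  out
}

#' Maximum decision consistency over lags
#'
#' The maximum of the consistency curve over lags `1..max_lag`; used to
#' summarize how strongly a reservoir of a given size and lifetime repeats
#' its decisions. With `lifetime = 1` this is 0.5 (plus sampling noise)
#' regardless of reservoir size.
#'
#' @inheritParams decision_consistency_curve
#' @param ... Passed on to [decision_consistency_curve()].
#' @return A single number.
#' @export
max_decision_consistency <- function(config, t0 = 2000L, max_lag = 100L,
                                     n_runs = 10000L, ...) {
  cc <- decision_consistency_curve(config, t0 = t0, max_lag = max_lag,
                                   n_runs = n_runs, ...)
  max(cc$mean_consistency, na.rm = TRUE)
}

#' Mean active portion at the reference cycle
#'
#' Monte Carlo mean of the fraction of disabled arrows at cycle `t0`
#' (measured after recovery, before the cycle's arrow draw). It decreases
#' with reservoir size and increases with lifetime, mirroring the
#' consistency trends.
#'
#' @inheritParams decision_consistency_curve
#' @return A single number in \\[0, 1\\].
#' @export
mean_active_portion <- function(config, t0 = 2000L, n_runs = 10000L) {
  stopifnot(inherits(config, "reservoir_config"))
  t0 <- check_count(t0, "t0", min = 1L)
  n_runs <- check_count(n_runs, "n_runs", min = 1L)
  res <- with_seed(config$seed,
                   cpp_consistency_mc(config$n_levels, config$lifetime,
                                      t0, 1L, n_runs, t0 + 2L, TRUE))
  res$mean_active_portion
}

#' @export
print.consistency_curve <- function(x, ...) {
  cfg <- attr(x, "config")
  cat(sprintf("<consistency_curve> N = %d, lifetime = %d, t0 = %d\n",
              cfg$n_levels, cfg$lifetime, attr(x, "t0")))
  NextMethod()
}

#' @rdname decision_consistency_curve
#' @param object,x A `consistency_curve`.
#' @export
autoplot.consistency_curve <- function(object, ...) {
  cfg <- attr(object, "config")
  ggplot2::ggplot(object, ggplot2::aes(.data$lag, .data$mean_consistency)) +
    ggplot2::geom_hline(yintercept = 0.5, linetype = 2, colour = "grey50") +
    ggplot2::geom_line() +
    ggplot2::labs(
      x = "cycles after reference decision",
      y = "mean decision consistency",
      title = sprintf("Local reservoir N = %d, lifetime = %d",
                      cfg$n_levels, cfg$lifetime)
    )
}
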