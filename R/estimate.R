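#' Model consistency curve over reservoir sizes
#'
#' Runs the reservoir simulator on a grid of sizes N at a fixed lifetime
#' and reports the mean consistency between the decision at the reference
#' cycle and the decision a fixed number of cycles later (default lag 8,
#' matching an 8-repetition behavioral session). With lifetime 10 the
#' curve decreases from about 0.7 at N = 2 to 0.5 at N = 50, and is the
#' calibration used to translate an observed behavioral consistency into
#' a reservoir size.
#'
#' @param n_grid Integer vector of reservoir sizes (default
#'   `c(2, 5, 10, 20, 50)`).
#' @param lifetime Recovery lifetime in cycles (default 10).
#' @param lag Cycle separation between the compared decisions (default 8).
#' @param t0 Reference cycle (default 2000).
#' @param n_runs Monte Carlo runs per grid point (default 10000).
#' @param seed Optional integer seed.
#' @return A tibble of class `model_curve` with columns `n_levels`,
#'   `consistency`, `n_runs_used`.
#' @examples
#' mc <- model_curve(n_grid = c(2, 10), t0 = 200, n_runs = 500, seed = 1)
#' @export
model_curve <- function(n_grid = c(2L, 5L, 10L, 20L, 50L), lifetime = 10L,
                        lag = 8L, t0 = 2000L, n_runs = 10000L, seed = NULL) {
  lag <- check_count(lag, "lag", min = 1L)
  run <- function() {
    purrr::map_dfr(n_grid, function(n) {
      cc <- decision_consistency_curve(
        reservoir_config(n, lifetime), t0 = t0, max_lag = lag,
        n_runs = n_runs)
      tibble::tibble(n_levels = as.integer(n),
                     consistency = cc$mean_consistency[lag],
                     n_runs_used = cc$n_runs_used[lag])
    })
  }
  out <- with_seed(seed, run())
  attr(out, "lifetime") <- lifetime
  attr(out, "lag") <- lag
  class(out) <- c("model_curve", class(out))
  out
}

#' Estimate the reservoir size from an observed consistency
#'
#' Inverts a monotone non-increasing model curve (see [model_curve()]) by
#' piecewise-linear interpolation. Observations at or below the curve's
#' right endpoint are flagged `at-boundary` (the reservoir is at least as
#' large as the largest grid size); observations above the curve's maximum
#' are flagged `above-curve` — the model can accommodate them, but only
#' with a longer lifetime, so refitting the curve at a larger lifetime is
#' suggested.
#'
#' @param observed Observed decision consistency (a single number).
#' @param curve A `model_curve` tibble (columns `n_levels`,
#'   `consistency`).
#' @return An object of class `reservoir_estimate` with fields `n_hat`,
#'   `status` (`"in-range"`, `"at-boundary"`, `"above-curve"`),
#'   `observed`, and the curve.
#' @examples
#' curve <- tibble::tibble(n_levels = c(2, 5, 10, 20, 50),
#'                         consistency = c(0.70, 0.62, 0.56, 0.52, 0.50))
#' estimate_reservoir_size(0.6, curve)
#' @export
estimate_reservoir_size <- function(observed, curve) {
  if (!is.numeric(observed) || length(observed) != 1L || is.na(observed))
    abort("`observed` must be a single number.",
          class = "resdec_config_error")
  stopifnot(all(c("n_levels", "consistency") %in% names(curve)))
  if (nrow(curve) == 0L)
    abort("`curve` is empty.", class = "resdec_config_error")
  cv <- dplyr::arrange(curve, .data$n_levels)
  # regularize tiny Monte Carlo non-monotonicities before inversion
  y <- cummin(cv$consistency)
  n <- cv$n_levels
  if (observed > max(y)) {
    status <- "above-curve"; n_hat <- NA_real_
  } else if (observed <= min(y)) {
    status <- "at-boundary"; n_hat <- max(n)
  } else {
    status <- "in-range"
    n_hat <- approx(x = rev(y), y = rev(n), xout = observed,
                    ties = "ordered")$y
  }
  structure(list(n_hat = n_hat, status = status, observed = observed,
                 curve = cv),
            class = "reservoir_estimate")
}

#' @export
print.reservoir_estimate <- function(x, ...) {
  msg <- switch(x$status,
    "in-range" = sprintf("estimated reservoir size n_hat = %.2f", x$n_hat),
    "at-boundary" = sprintf(
      "consistency at chance level: reservoir size >= %g", x$n_hat),
    "above-curve" = paste0(
      "observed consistency exceeds the curve maximum; ",
      "refit with a longer lifetime"))
  cat(sprintf("<reservoir_estimate> observed = %.3f: %s\n", x$observed, msg))
  invisible(x)
}

#' @rdname estimate_reservoir_size
#' @param x A `reservoir_estimate`.
#' @param ... Unused.
#' @export
tidy.reservoir_estimate <- function(x, ...) {
  dplyr::mutate(x$curve, observed = x$observed)
}

#' @rdname estimate_reservoir_size
#' @export
glance.reservoir_estimate <- function(x, ...) {
  tibble::tibble(observed = x$observed, n_hat = x$n_hat, status = x$status)
}

#' @rdname model_curve
#' @param object,x A `model_curve`.
#' @param ... Unused.
#' @export
autoplot.model_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$n_levels, .data$consistency)) +
    ggplot2::geom_hline(yintercept = 0.5, linetype = 2, colour = "grey50") +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "reservoir size N",
                  y = sprintf("consistency at lag %d", attr(object, "lag")))
}
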