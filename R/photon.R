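#' Configure the single-photon decision maker
#'
#' A linearly polarized single photon meets a polarizing beam splitter;
#' detection at the horizontal port is Decision 1, at the vertical port
#' Decision 2 (Malus law: P(Decision 1) = cos^2 theta). After each
#' decision a waveplate rotates the polarization by `delta = pi /
#' resolution` toward the pole of the decision just made, so decisions
#' feed back on themselves. When the angle leaves \\[0, pi/2\\] the run
#' terminates. The resolution plays the role of the reservoir size: small
#' R means a big, quickly saturating feedback (strong CBL), large R a
#' nearly fair coin.
#'
#' @param resolution Angular resolution R >= 4; the per-decision rotation
#'   is `pi / R`.
#' @param n_decisions Maximum number of decisions per run (default 500).
#' @param seed Optional integer seed.
#' @return An object of class `photon_config`.
#' @examples
#' photon_config(resolution = 10, seed = 3)
#' @export
photon_config <- function(resolution, n_decisions = 500L, seed = NULL) {
  resolution <- check_count(resolution, "resolution", min = 4L)
  n_decisions <- check_count(n_decisions, "n_decisions", min = 1L)
  if (!is.null(seed)) seed <- check_count(seed, "seed", min = 0L)
  structure(list(resolution = resolution, n_decisions = n_decisions,
                 seed = seed, delta = pi / resolution),
            class = "photon_config")
}

#' Probability of Decision 1 at a polarization angle
#'
#' Malus law for the horizontal detector port: `cos^2(theta)`. At
#' `theta = pi/4` the two detectors fire at a 50:50 ratio.
#'
#' @param theta Polarization angle(s) in radians, within \\[0, pi/2\\].
#' @return Probability of Decision 1, same length as `theta`.
#' @examples
#' detection_probability(pi / 4)  # 0.5
#' @export
detection_probability <- function(theta) {
  if (any(theta < 0 | theta > pi / 2))
    abort("`theta` must lie in [0, pi/2]; outside, the run has terminated.",
          class = "resdec_config_error")
  cos(theta)^2
}

#' Initial photon state
#'
#' @param config A [photon_config()].
#' @return An object of class `photon_state` with `theta = pi/4`,
#'   `active = TRUE`, and an empty decision history.
#' @export
photon_init <- function(config) {
  stopifnot(inherits(config, "photon_config"))
  structure(list(config = config, theta = pi / 4, active = TRUE,
                 decisions = integer(0)),
            class = "photon_state")
}

#' @export
print.photon_state <- function(x, ...) {
  cat(sprintf("<photon_state> theta = %.4f rad, %s, %d decisions made\n",
              x$theta, if (x$active) "active" else "terminated",
              length(x$decisions)))
  invisible(x)
}

#' One decision of the photon system
#'
#' Draws Decision 1 with probability `cos^2(theta)`; Decision 1 rotates the
#' polarization toward horizontal (`theta - delta`), Decision 2 toward
#' vertical (`theta + delta`). If the updated angle leaves \\[0, pi/2\\]
#' the state becomes inactive and no further decisions occur.
#'
#' @param state An active `photon_state`.
#' @return The updated `photon_state`.
#' @export
step_photon <- function(state) {
  stopifnot(inherits(state, "photon_state"))
  if (!state$active)
    abort("cannot step a terminated photon state",
          class = "resdec_state_error")
  d <- if (runif(1) < detection_probability(state$theta)) 1L else 2L
  state$decisions <- c(state$decisions, d)
  state$theta <- state$theta + if (d == 1L) -state$config$delta else
    state$config$delta
  if (state$theta < 0 || state$theta > pi / 2) state$active <- FALSE
  state
}

#' Simulate one photon decision sequence
#'
#' Repeats [step_photon()] from `theta = pi/4` until `n_decisions`
#' decisions have been made or the run terminates at a polarization
#' boundary.
#'
#' @param config A [photon_config()].
#' @return A tibble with columns `cycle` (1-based), `decision` (1 or 2),
#'   and `theta` (angle after the decision's update); the configuration is
#'   attached as attribute `"config"`.
#' @examples
#' run_photon_trace(photon_config(5, seed = 1))
#' @export
run_photon_trace <- function(config) {
  stopifnot(inherits(config, "photon_config"))
  run <- function() {
    st <- photon_init(config)
    theta <- numeric(0)
    while (st$active && length(st$decisions) < config$n_decisions) {
      st <- step_photon(st)
      theta <- c(theta, st$theta)
    }
    tibble::tibble(cycle = seq_along(st$decisions),
                   decision = st$decisions, theta = theta)
  }
  out <- with_seed(config$seed, run())
  attr(out, "config") <- config
  out
}

#' Normalized waveplate rotation away from the neutral angle
#'
#' The photon analogue of the reservoir's active portion: how far the
#' polarization has rotated from pi/4, as a fraction of the rotation to a
#' pole. 0 at theta = pi/4; 1 at theta = 0 or pi/2.
#'
#' @param theta Polarization angle(s) in radians.
#' @return Values in \\[0, 1\\] (larger if theta is outside the band).
#' @export
photon_active_portion <- function(theta) {
  abs(theta - pi / 4) / (pi / 4)
}

#' Consistency curves of the photon decision maker
#'
#' For each resolution, simulates `n_runs` decision sequences (vectorized
#' across runs) and reports, per cycle, the fraction of still-active runs
#' whose decision equals their own first decision, the number of surviving
#' runs, and the mean normalized waveplate rotation. Terminated runs are
#' excluded from later cycles and tracked via `surviving_runs`.
#'
#' @param resolutions Integer vector of resolutions R (each >= 4).
#' @param n_decisions Decisions per run (default 500).
#' @param n_runs Runs per resolution (default 10000).
#' @param seed Optional integer seed.
#' @return A tibble of class `photon_curve` with columns `resolution`,
#'   `cycle`, `mean_consistency`, `surviving_runs`, `mean_active_portion`.
#' @examples
#' pc <- photon_consistency_curve(c(5, 100), n_decisions = 50,
#'                                n_runs = 500, seed = 2)
#' @export
photon_consistency_curve <- function(resolutions, n_decisions = 500L,
                                     n_runs = 10000L, seed = NULL) {
  n_decisions <- check_count(n_decisions, "n_decisions", min = 1L)
  n_runs <- check_count(n_runs, "n_runs", min = 1L)
  one_resolution <- function(r) {
    r <- check_count(r, "resolution", min = 4L)
    delta <- pi / r
    theta <- rep(pi / 4, n_runs)
    active <- rep(TRUE, n_runs)
    first <- integer(n_runs)
    out <- vector("list", n_decisions)
    for (t in seq_len(n_decisions)) {
      idx <- which(active)
      if (length(idx) == 0L) {
        out[[t]] <- tibble::tibble(resolution = r, cycle = t,
                                   mean_consistency = NA_real_,
                                   surviving_runs = 0L,
                                   mean_active_portion = NA_real_)
        next
      }
      d <- ifelse(runif(length(idx)) < cos(theta[idx])^2, 1L, 2L)
      if (t == 1L) first[idx] <- d
      theta[idx] <- theta[idx] + ifelse(d == 1L, -delta, delta)
      out[[t]] <- tibble::tibble(
        resolution = r, cycle = t,
        mean_consistency = mean(d == first[idx]),
        surviving_runs = length(idx),
        mean_active_portion = mean(photon_active_portion(
          pmin(pmax(theta[idx], 0), pi / 2)))
      )
      active[idx] <- theta[idx] >= 0 & theta[idx] <= pi / 2
    }
    dplyr::bind_rows(out)
  }
  out <- with_seed(seed, dplyr::bind_rows(lapply(resolutions, one_resolution)))
  class(out) <- c("photon_curve", class(out))
  out
}

#' @rdname photon_consistency_curve
#' @param object,x A `photon_curve`.
#' @param ... Unused.
#' @export
autoplot.photon_curve <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(.data$cycle, .data$mean_consistency,
                               colour = factor(.data$resolution))) +
    ggplot2::geom_hline(yintercept = 0.5, linetype = 2, colour = "grey50") +
    ggplot2::geom_line() +
    ggplot2::labs(x = "cycle", y = "mean decision consistency",
                  colour = "resolution R")
}
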