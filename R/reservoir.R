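#' Configure a local reservoir
#'
#' A local reservoir is the finite hidden environment that absorbs the
#' energy dissipated by each decision. It consists of `n_levels` lower
#' energy levels and `n_levels + 1` upper levels, each holding at most one
#' excitation (fermionic single occupancy). A Decision L excites lower
#' level *i* to upper level *i + 1*; a Decision R excites lower level *i*
#' to upper level *i*. A used lower level refills, and a used upper level
#' empties, `lifetime` cycles after the excitation.
#'
#' @param n_levels Number of lower energy levels (reservoir size N >= 1).
#' @param lifetime Recovery delay in cycles (tau >= 1). `lifetime = 1`
#'   means resources recover before the next cycle, so every cycle sees the
#'   full arrow set and decisions are an unbiased coin.
#' @param seed Optional integer seed; used by [run_trace()] and the
#'   consistency routines for reproducibility.
#' @return An object of class `reservoir_config`.
#' @examples
#' reservoir_config(n_levels = 4, lifetime = 10, seed = 1)
#' @export
reservoir_config <- function(n_levels, lifetime, seed = NULL) {
  n_levels <- check_count(n_levels, "n_levels", min = 1L)
  lifetime <- check_count(lifetime, "lifetime", min = 1L)
  if (!is.null(seed)) seed <- check_count(seed, "seed", min = 0L)
  structure(list(n_levels = n_levels, lifetime = lifetime, seed = seed),
            class = "reservoir_config")
}

#' @export
print.reservoir_config <- function(x, ...) {
  cat(sprintf("<reservoir_config> N = %d, lifetime = %d, seed = %s\n",
              x$n_levels, x$lifetime,
              if (is.null(x$seed)) "none" else x$seed))
  invisible(x)
}

#' Initial reservoir state
#'
#' The fresh reservoir has every lower level occupied and every upper level
#' vacant, so all `2 * n_levels` excitation arrows are available.
#'
#' @param config A [reservoir_config()].
#' @return An object of class `reservoir_state`: occupancy flags for the
#'   lower and upper levels, recovery timers (`NA` when no recovery is
#'   pending), and the cycle counter.
#' @examples
#' st <- reservoir_init(reservoir_config(4, 10))
#' nrow(available_arrows(st))  # 8 arrows
#' @export
reservoir_init <- function(config) {
  stopifnot(inherits(config, "reservoir_config"))
  n <- config$n_levels
  structure(
    list(
      config = config,
      cycle = 0L,
      lower_occupied = rep(TRUE, n),
      upper_occupied = rep(FALSE, n + 1L),
      lower_refill_cycle = rep(NA_integer_, n),
      upper_clear_cycle = rep(NA_integer_, n + 1L)
    ),
    class = "reservoir_state"
  )
}

#' @export
print.reservoir_state <- function(x, ...) {
  cat(sprintf("<reservoir_state> cycle %d | lower: %s | upper: %s\n",
              x$cycle,
              paste(ifelse(x$lower_occupied, "x", "."), collapse = ""),
              paste(ifelse(x$upper_occupied, "x", "."), collapse = "")))
  invisible(x)
}

#' Arrows currently available in the reservoir
#'
#' An arrow is available iff its source lower level is occupied and its
#' target upper level is vacant. L-arrow *i* targets upper level *i + 1*
#' (Decision L); R-arrow *i* targets upper level *i* (Decision R).
#'
#' @param state A `reservoir_state`.
#' @return A tibble with columns `kind` ("L"/"R"), `index` (source lower
#'   level), and `target_upper`.
#' @export
available_arrows <- function(state) {
  stopifnot(inherits(state, "reservoir_state"))
  n <- state$config$n_levels
  i <- seq_len(n)
  ok_l <- state$lower_occupied & !state$upper_occupied[i + 1L]
  ok_r <- state$lower_occupied & !state$upper_occupied[i]
  tibble::tibble(
    kind = c(rep("L", sum(ok_l)), rep("R", sum(ok_r))),
    index = c(i[ok_l], i[ok_r]),
    target_upper = c(i[ok_l] + 1L, i[ok_r])
  )
}

#' Fraction of arrows in use at the current cycle
#'
#' The active portion is the fraction of the `2 * n_levels` excitation
#' arrows that are currently disabled (their resources are in use or not
#' yet recovered). A fresh reservoir has active portion 0.
#'
#' @param state A `reservoir_state`.
#' @return A number in \\[0, 1\\].
#' @export
active_portion <- function(state) {
  n <- state$config$n_levels
  (2 * n - nrow(available_arrows(state))) / (2 * n)
}

# recovery: fire every timer equal to the current cycle
fire_recovery <- function(state) {
  c0 <- state$cycle
  due_l <- which(!is.na(state$lower_refill_cycle) &
                   state$lower_refill_cycle == c0)
  due_u <- which(!is.na(state$upper_clear_cycle) &
                   state$upper_clear_cycle == c0)
  state$lower_occupied[due_l] <- TRUE
  state$lower_refill_cycle[due_l] <- NA_integer_
  state$upper_occupied[due_u] <- FALSE
  state$upper_clear_cycle[due_u] <- NA_integer_
  state
}

#' Advance the reservoir by one cycle
#'
#' Pure-R reference stepper. Each cycle: recovery timers equal to the
#' current cycle fire first; then one of the `2 * n_levels` arrow slots is
#' drawn uniformly at random. If that arrow is currently available it is
#' executed (its lower level is vacated and its target upper level
#' occupied, both recovering `lifetime` cycles later) and its kind is the
#' cycle's decision; a draw of a disabled arrow — in particular, any draw
#' when no arrow is available — yields no decision. Sampling arrow slots
#' rather than the available set keeps the decision timing stochastic;
#' conditioning the draw on the available set phase-locks the recovery
#' clocks into near-periodic decision patterns for small reservoirs.
#' Uses the ambient R RNG; draws are bit-identical to the compiled fast
#' path in [run_trace()].
#'
#' @param state A `reservoir_state`.
#' @return A list with elements `state` (the advanced state) and
#'   `decision` ("L", "R", or "none").
#' @export
step_cycle <- function(state) {
  stopifnot(inherits(state, "reservoir_state"))
  state <- fire_recovery(state)
  n <- state$config$n_levels
  a <- min(floor(runif(1) * 2 * n) + 1L, 2L * n)
  kind <- if (a <= n) "L" else "R"
  index <- if (a <= n) a else a - n
  target <- if (a <= n) index + 1L else index
  decision <- "none"
  if (state$lower_occupied[index] && !state$upper_occupied[target]) {
    decision <- kind
    tau <- state$config$lifetime
    state$lower_occupied[index] <- FALSE
    state$lower_refill_cycle[index] <- state$cycle + tau
    state$upper_occupied[target] <- TRUE
    state$upper_clear_cycle[target] <- state$cycle + tau
  }
  state$cycle <- state$cycle + 1L
  list(state = state, decision = decision)
}

decision_levels <- c("none", "L", "R")

#' Simulate a decision trace
#'
#' Runs the reservoir for `n_cycles` consecutive cycles (compiled fast
#' path) and records the decision made at each cycle.
#'
#' @param config A [reservoir_config()]. Its `seed`, when set, makes the
#'   trace reproducible.
#' @param n_cycles Number of cycles to simulate (default 3000).
#' @return A tibble of class `decision_trace` with columns `cycle`
#'   (0-based) and `decision` ("L", "R", or "none"), carrying the
#'   configuration as an attribute.
#' @examples
#' tr <- run_trace(reservoir_config(4, 10, seed = 42), n_cycles = 100)
#' table(tr$decision)
#' @export
run_trace <- function(config, n_cycles = 3000L) {
  stopifnot(inherits(config, "reservoir_config"))
  n_cycles <- check_count(n_cycles, "n_cycles", min = 1L)
  d <- with_seed(config$seed,
                 cpp_run_trace(config$n_levels, config$lifetime, n_cycles))
  out <- tibble::tibble(
    cycle = seq_len(n_cycles) - 1L,
    decision = decision_levels[d + 1L]
  )
  attr(out, "config") <- config
  class(out) <- c("decision_trace", class(out))
  out
}

#' Random-walk view of a decision trace
#'
#' Maps a decision trace to a cumulative walk: Decision L is a unit step
#' up, Decision R a unit step down, and a no-decision cycle holds the
#' position. Under CBL, walks that start with Decision L drift upward.
#'
#' @param trace A tibble with columns `cycle` and `decision`
#'   (as produced by [run_trace()]).
#' @return A tibble with columns `cycle` and `position`.
#' @examples
#' random_walk_path(run_trace(reservoir_config(4, 10, seed = 1), 50))
#' @export
random_walk_path <- function(trace) {
  stopifnot(all(c("cycle", "decision") %in% names(trace)))
  step <- dplyr::case_match(trace$decision, "L" ~ 1L, "R" ~ -1L,
                            .default = 0L)
  tibble::tibble(cycle = trace$cycle, position = cumsum(step))
}
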