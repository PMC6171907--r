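#' Decision-transition probabilities of the reservoir chain
#'
#' A decision is an UP transition of the chain (UP_L = Decision L, UP_R =
#' Decision R). `P(L -> L)` is the probability that a Decision L is
#' followed — after any number of refill (IN) and emptying (OUT) events —
#' by another Decision L. It is computed exactly by a first-passage
#' argument on the embedded jump chain: let `h_L(s)` be the probability
#' that the next UP event starting from state `s` is UP_L; `h_L` solves a
#' dense linear system in which IN/OUT jumps are pass-through and UP jumps
#' absorb. Conditioning on a steady-state Decision L event (flux-weighted
#' over all UP_L transitions) and averaging `h_L` over the post-decision
#' states gives `P(L -> L)`.
#'
#' The imbalance `P(L -> L) - P(L -> R)` quantifies choice-based learning:
#' positive values mean a decision makes its own repetition more likely.
#'
#' @inheritParams reservoir_transitions
#' @return An object of class `decision_probs` with fields `p_LL`, `p_LR`,
#'   `p_RL`, `p_RR`, `imbalance`, the steady-state vector `pi` (binary
#'   state order), and the inputs.
#' @examples
#' dp <- decision_transition_probs(2, rate_params(1, 1, 10))
#' dp$imbalance   # > 0: consecutive identical decisions favored
#' @export
decision_transition_probs <- function(n_levels, params) {
  n_levels <- check_count(n_levels, "n_levels", min = 1L)
  stopifnot(inherits(params, "rate_params"))
  tr <- reservoir_transitions(n_levels, params)
  s <- 2L^(2L * n_levels + 1L)
  out_rate <- vapply(seq_len(s), function(i) sum(tr$rate[tr$source == i]),
                     numeric(1))
  # embedded jump chain, split into pass-through (IN/OUT) and absorbing (UP)
  pass <- tr$label %in% c("IN", "OUT")
  p_nd <- matrix(0, s, s)
  idx <- which(pass)
  for (k in idx) {
    p_nd[tr$source[k], tr$target[k]] <-
      p_nd[tr$source[k], tr$target[k]] + tr$rate[k] / out_rate[tr$source[k]]
  }
  b_for <- function(lab) {
    b <- numeric(s)
    for (k in which(tr$label == lab))
      b[tr$source[k]] <- b[tr$source[k]] + tr$rate[k] / out_rate[tr$source[k]]
    b
  }
  a <- diag(s) - p_nd
  h_l <- solve(a, b_for("UP_L"))
  h_r <- solve(a, b_for("UP_R"))
  pi <- steady_state(build_generator(n_levels, params))
  cond_prob <- function(dec_lab, h) {
    k <- which(tr$label == dec_lab)
    flux <- pi[tr$source[k]] * tr$rate[k]
    sum(flux * h[tr$target[k]]) / sum(flux)
  }
  res <- list(
    p_LL = cond_prob("UP_L", h_l), p_LR = cond_prob("UP_L", h_r),
    p_RL = cond_prob("UP_R", h_l), p_RR = cond_prob("UP_R", h_r),
    pi = pi, h_L = h_l, h_R = h_r,
    n_levels = n_levels, params = params
  )
  res$imbalance <- res$p_LL - res$p_LR
  structure(res, class = "decision_probs")
}

#' @export
print.decision_probs <- function(x, ...) {
  cat(sprintf(paste0(
    "<decision_probs> N = %d, rates (in, up, out) = (%g, %g, %g)\n",
    "  P(L->L) = %.6f  P(L->R) = %.6f  imbalance = %+.6f\n"),
    x$n_levels, x$params$gamma_in, x$params$gamma_up, x$params$gamma_out,
    x$p_LL, x$p_LR, x$imbalance))
  invisible(x)
}

#' @rdname decision_transition_probs
#' @param x A `decision_probs` object.
#' @param ... Unused.
#' @export
tidy.decision_probs <- function(x, ...) {
  tibble::tibble(
    from = c("L", "L", "R", "R"),
    to = c("L", "R", "L", "R"),
    probability = c(x$p_LL, x$p_LR, x$p_RL, x$p_RR)
  )
}

#' @rdname decision_transition_probs
#' @export
glance.decision_probs <- function(x, ...) {
  tibble::tibble(
    n_levels = x$n_levels,
    gamma_in = x$params$gamma_in,
    gamma_up = x$params$gamma_up,
    gamma_out = x$params$gamma_out,
    p_LL = x$p_LL, p_LR = x$p_LR, imbalance = x$imbalance
  )
}

#' Imbalance of decision-transition probabilities
#'
#' Shorthand for `P(L -> L) - P(L -> R)` from
#' [decision_transition_probs()]. Positive values indicate choice-based
#' learning. A single-lower-level reservoir (N = 1) never shows CBL:
#' occupying one of its upper levels blocks the very path just used.
#'
#' @inheritParams reservoir_transitions
#' @return A single number in \\[-1, 1\\].
#' @export
imbalance <- function(n_levels, params) {
  decision_transition_probs(n_levels, params)$imbalance
}

#' Closed-form N = 1 imbalance expression
#'
#' Evaluates, verbatim, the closed-form expression for the N = 1
#' decision-transition imbalance in terms of the three rates and the eight
#' steady-state probabilities (diagram state order). It is reported
#' side-by-side with the first-passage [imbalance()] for reconciliation;
#' equality between the two is deliberately not assumed, because the
#' expression evaluates positive for positive rates while an N = 1
#' reservoir provably cannot favor repeating a decision.
#'
#' @param params A [rate_params()].
#' @param p Length-8 probability vector in the diagram state order
#'   (see [enumerate_states()] with `order = "diagram"`).
#' @return A single number.
#' @examples
#' pr <- rate_params(1, 1, 1)
#' p <- steady_state(build_generator(1, pr, order = "diagram"))
#' closed_form_imbalance_n1(pr, p)
#' @export
closed_form_imbalance_n1 <- function(params, p) {
  stopifnot(inherits(params, "rate_params"))
  if (length(p) != 8L || abs(sum(p) - 1) > 1e-8)
    abort("`p` must be a normalized length-8 probability vector.",
          class = "resdec_config_error")
  gi <- params$gamma_in; gu <- params$gamma_up; go <- params$gamma_out
  pref <- gi * gu / ((gi + go) * (gu + go))
  term12 <- (p[1] + p[2]) / 2
  term34 <- (gi * go + go * (gu + go)) / (2 * (gi + go) * (gu + go)) *
    (p[3] + p[4])
  term7 <- (2 * (2 * gi + go) * (gu + go) * go^2 + gi * go * (gi + go)^2) /
    (2 * (gi + 2 * go) * (gi + go)^2 * (gu + go)) * p[7]
  term568 <- go / (2 * (gu + go)) * (p[5] + p[6] + p[8])
  pref * (term12 + term34 + term7 + term568)
}
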