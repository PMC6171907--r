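#' Rate parameters of the reservoir's continuous-time dynamics
#'
#' The continuous-time counterpart of the cycle simulator is a Markov
#' chain over occupation micro-states, driven by three rates: `gamma_in`
#' (a vacant lower level refills), `gamma_up` (an available arrow fires,
#' i.e. a decision), and `gamma_out` (an occupied upper level empties).
#'
#' @param gamma_in,gamma_up,gamma_out Strictly positive rates.
#' @return An object of class `rate_params`.
#' @examples
#' rate_params(1, 1, 10)
#' @export
rate_params <- function(gamma_in, gamma_up, gamma_out) {
  structure(list(gamma_in = check_positive(gamma_in, "gamma_in"),
                 gamma_up = check_positive(gamma_up, "gamma_up"),
                 gamma_out = check_positive(gamma_out, "gamma_out")),
            class = "rate_params")
}

#' @export
print.rate_params <- function(x, ...) {
  cat(sprintf("<rate_params> in = %g, up = %g, out = %g\n",
              x$gamma_in, x$gamma_up, x$gamma_out))
  invisible(x)
}

# ---- state encoding -------------------------------------------------------
# Micro-state: occupancy bits over 2N+1 levels. Canonical ("binary") order:
# bit 0..N-1 = lower 1..N, bit N..2N = upper 1..N+1; index = 1 + binary value.

state_matrix <- function(n_levels) {
  nb <- 2L * n_levels + 1L
  s <- 2L^nb
  idx <- 0:(s - 1L)
  bits <- vapply(seq_len(nb) - 1L, function(b) bitwAnd(idx, 2L^b) > 0L,
                 logical(s))
  if (s == 1L) bits <- matrix(bits, nrow = 1L)
  bits  # s x (2N+1) logical: cols 1..N lowers, N+1..2N+1 uppers
}

# Permutation mapping the 8-state diagram order used for the N = 1 ladder
# (1 = empty; 2 = {lower}; 3 = {upper-left}; 4 = {upper-right};
#  5 = {lower, UL}; 6 = {lower, UR}; 7 = {UL, UR}; 8 = all occupied)
# to the canonical binary order.
diagram_perm_n1 <- c(1L, 2L, 3L, 5L, 4L, 6L, 7L, 8L)

#' Enumerate reservoir occupation micro-states
#'
#' A reservoir with N lower levels has `2N + 1` single-occupancy levels and
#' hence `2^(2N+1)` occupation micro-states: 8 for N = 1, 32 for N = 2.
#'
#' @param n_levels Reservoir size N >= 1.
#' @param order `"binary"` (canonical: lower-level bits first, least
#'   significant first, then upper levels left to right) or `"diagram"`
#'   (the conventional indexing of the 8-state transition diagram;
#'   N = 1 only).
#' @return A tibble with columns `state` (1-based index in the requested
#'   order), `lower` and `upper` (occupancy strings, "x" occupied,
#'   "." vacant), and `n_excitations`.
#' @examples
#' enumerate_states(1, order = "diagram")
#' nrow(enumerate_states(2))  # 32
#' @export
enumerate_states <- function(n_levels, order = c("binary", "diagram")) {
  n_levels <- check_count(n_levels, "n_levels", min = 1L)
  order <- match.arg(order)
  bits <- state_matrix(n_levels)
  if (order == "diagram") {
    if (n_levels != 1L)
      abort("`order = \"diagram\"` is defined for n_levels = 1 only.",
            class = "resdec_config_error")
    bits <- bits[diagram_perm_n1, , drop = FALSE]
  }
  n <- n_levels
  occ <- function(m) apply(m, 1L, function(r)
    paste(ifelse(r, "x", "."), collapse = ""))
  tibble::tibble(
    state = seq_len(nrow(bits)),
    lower = occ(bits[, seq_len(n), drop = FALSE]),
    upper = occ(bits[, n + seq_len(n + 1L), drop = FALSE]),
    n_excitations = rowSums(bits)
  )
}

#' Labeled transitions of the reservoir Markov chain
#'
#' Enumerates every allowed transition between occupation micro-states:
#' `IN(i)` refills vacant lower level i (rate `gamma_in`); `OUT(j)` empties
#' occupied upper level j (rate `gamma_out`); `UP_L(i)` excites lower i to
#' upper i + 1 and `UP_R(i)` excites lower i to upper i (rate `gamma_up`
#' each). UP transitions are the decisions: UP_L is Decision L, UP_R is
#' Decision R.
#'
#' @inheritParams enumerate_states
#' @param params A [rate_params()].
#' @return A tibble with columns `source`, `target` (state indices in the
#'   binary order), `label` ("IN", "OUT", "UP_L", "UP_R"), `level`, `rate`.
#' @export
reservoir_transitions <- function(n_levels, params) {
  n_levels <- check_count(n_levels, "n_levels", min = 1L)
  stopifnot(inherits(params, "rate_params"))
  n <- n_levels
  bits <- state_matrix(n)
  s <- nrow(bits)
  lower_bit <- function(i) 2L^(i - 1L)
  upper_bit <- function(j) 2L^(n + j - 1L)
  rows <- vector("list", s)
  for (st in seq_len(s)) {
    low <- bits[st, seq_len(n)]
    up <- bits[st, n + seq_len(n + 1L)]
    code <- st - 1L
    out <- list()
    for (i in seq_len(n)) {
      if (!low[i])
        out[[length(out) + 1L]] <- c(code + lower_bit(i), 1L, i,
                                     params$gamma_in)
      if (low[i] && !up[i + 1L])
        out[[length(out) + 1L]] <- c(code - lower_bit(i) + upper_bit(i + 1L),
                                     3L, i, params$gamma_up)
      if (low[i] && !up[i])
        out[[length(out) + 1L]] <- c(code - lower_bit(i) + upper_bit(i),
                                     4L, i, params$gamma_up)
    }
    for (j in seq_len(n + 1L)) {
      if (up[j])
        out[[length(out) + 1L]] <- c(code - upper_bit(j), 2L, j,
                                     params$gamma_out)
    }
    m <- do.call(rbind, out)
    rows[[st]] <- cbind(source = st, target = m[, 1L] + 1L,
                        label = m[, 2L], level = m[, 3L], rate = m[, 4L])
  }
  m <- do.call(rbind, rows)
  tibble::tibble(
    source = as.integer(m[, "source"]),
    target = as.integer(m[, "target"]),
    label = c("IN", "OUT", "UP_L", "UP_R")[m[, "label"]],
    level = as.integer(m[, "level"]),
    rate = m[, "rate"]
  )
}

#' Generator matrix of the reservoir rate equation
#'
#' Assembles the rate-equation generator G with the convention
#' `dp/dt = G p`: entry (i, j), i != j, is the total rate from state j to
#' state i, and each diagonal entry is minus its column's outflow, so every
#' column sums to zero.
#'
#' @inheritParams reservoir_transitions
#' @param order State ordering; see [enumerate_states()].
#' @return A square numeric matrix of size `2^(2N+1)` with the transition
#'   table attached as attribute `"transitions"` (binary order).
#' @examples
#' G <- build_generator(1, rate_params(1, 1, 1), order = "diagram")
#' round(colSums(G), 12)  # all zero
#' @export
build_generator <- function(n_levels, params, order = c("binary", "diagram")) {
  order <- match.arg(order)
  tr <- reservoir_transitions(n_levels, params)
  s <- 2L^(2L * n_levels + 1L)
  g <- matrix(0, s, s)
  for (k in seq_len(nrow(tr))) {
    g[tr$target[k], tr$source[k]] <- g[tr$target[k], tr$source[k]] + tr$rate[k]
  }
  diag(g) <- diag(g) - colSums(g)
  if (order == "diagram") {
    if (n_levels != 1L)
      abort("`order = \"diagram\"` is defined for n_levels = 1 only.",
            class = "resdec_config_error")
    g <- g[diagram_perm_n1, diagram_perm_n1]
  }
  attr(g, "transitions") <- tr
  g
}

#' Steady state of a generator
#'
#' Solves `G p = 0` with `sum(p) = 1` by least squares on the normalized
#' system. For strictly positive rates the chain is irreducible, so the
#' null space is one-dimensional and the steady state unique.
#'
#' @param gen A generator matrix from [build_generator()].
#' @param tol Residual tolerance for declaring the solve degenerate.
#' @return A probability vector in the same state order as `gen`.
#' @export
steady_state <- function(gen, tol = 1e-8) {
  s <- nrow(gen)
  a <- rbind(gen, rep(1, s))
  b <- c(rep(0, s), 1)
  p <- qr.solve(a, b)
  if (max(abs(gen %*% p)) > tol * max(abs(gen)) || abs(sum(p) - 1) > tol)
    abort("steady-state solve did not converge (degenerate generator?)",
          class = "resdec_numeric_error")
  p[p < 0 & p > -tol] <- 0
  p / sum(p)
}
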