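#' Exact stochastic simulation of the reservoir Markov chain
#'
#' Gillespie-style simulation of the labeled continuous-time chain:
#' exponential waiting times with the state's total outflow rate, next
#' transition drawn proportionally to its rate. Records time-weighted
#' state occupation and the sequence of UP (decision) events. Serves as an
#' independent Monte Carlo cross-check of [steady_state()] and
#' [decision_transition_probs()].
#'
#' @inheritParams reservoir_transitions
#' @param n_events Number of jump events to simulate.
#' @param seed Optional integer seed.
#' @param n_batches Number of equal-event batches used for the occupation
#'   standard errors.
#' @return An object of class `gillespie_sim`: `occupation` (tibble with
#'   `state`, `time_fraction`, `se`, binary state order), `decisions`
#'   (character vector of "L"/"R" in event order), and the empirical
#'   decision-transition estimates `p_LL_hat`, `p_RR_hat` with standard
#'   errors and pair counts.
#' @examples
#' sim <- gillespie_reservoir(1, rate_params(1, 1, 1),
#'                            n_events = 5000, seed = 1)
#' sim$p_LL_hat
#' @export
gillespie_reservoir <- function(n_levels, params, n_events = 100000L,
                                seed = NULL, n_batches = 20L) {
  n_levels <- check_count(n_levels, "n_levels", min = 1L)
  n_events <- check_count(n_events, "n_events", min = 10L)
  stopifnot(inherits(params, "rate_params"))
  tr <- reservoir_transitions(n_levels, params)
  s <- 2L^(2L * n_levels + 1L)
  by_state <- lapply(seq_len(s), function(i) {
    k <- which(tr$source == i)
    list(target = tr$target[k],
         decision = dplyr::case_match(tr$label[k], "UP_L" ~ 1L, "UP_R" ~ 2L,
                                      .default = 0L),
         total = sum(tr$rate[k]),
         cum = cumsum(tr$rate[k]) / sum(tr$rate[k]))
  })
  batch_size <- ceiling(n_events / n_batches)
  run <- function() {
    occ_time <- matrix(0, n_batches, s)
    decisions <- integer(n_events)
    st <- 1L  # empty reservoir; burn-in is implicit in the long horizon
    for (ev in seq_len(n_events)) {
      info <- by_state[[st]]
      dt <- stats::rexp(1L, info$total)
      occ_time[(ev - 1L) %/% batch_size + 1L, st] <-
        occ_time[(ev - 1L) %/% batch_size + 1L, st] + dt
      j <- findInterval(runif(1L), info$cum) + 1L
      decisions[ev] <- info$decision[j]
      st <- info$target[j]
    }
    list(occ_time = occ_time, decisions = decisions)
  }
  res <- with_seed(seed, run())
  batch_frac <- res$occ_time / rowSums(res$occ_time)
  frac <- colSums(res$occ_time) / sum(res$occ_time)
  se <- apply(batch_frac, 2L, stats::sd) / sqrt(n_batches)
  dec <- res$decisions[res$decisions > 0L]
  pair_stat <- function(kind) {
    first <- head(dec, -1L); second <- tail(dec, -1L)
    sel <- first == kind
    n <- sum(sel)
    p <- mean(second[sel] == kind)
    list(p = p, se = sqrt(p * (1 - p) / n), n = n)
  }
  ll <- pair_stat(1L); rr <- pair_stat(2L)
  structure(list(
    occupation = tibble::tibble(state = seq_len(s), time_fraction = frac,
                                se = se),
    decisions = c("L", "R")[dec],
    p_LL_hat = ll$p, p_LL_se = ll$se, n_L_pairs = ll$n,
    p_RR_hat = rr$p, p_RR_se = rr$se, n_R_pairs = rr$n,
    n_levels = n_levels, params = params, n_events = n_events
  ), class = "gillespie_sim")
}

#' @export
print.gillespie_sim <- function(x, ...) {
  cat(sprintf(paste0(
    "<gillespie_sim> N = %d, %d events, %d decisions\n",
    "  p_LL_hat = %.4f (se %.4f)  p_RR_hat = %.4f (se %.4f)\n"),
    x$n_levels, x$n_events, length(x$decisions),
    x$p_LL_hat, x$p_LL_se, x$p_RR_hat, x$p_RR_se))
  invisible(x)
}
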