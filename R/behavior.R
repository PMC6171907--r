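#' Build a paired-preference trial schedule
#'
#' Random pairing schedule for a two-alternative forced-choice preference
#' experiment: `n_items` items, each appearing exactly `reps` times, paired
#' at random with no self-pairs, giving `n_items * reps / 2` trials. The
#' reference protocol pairs 28 occupations 8 times each over 112 trials.
#'
#' @param n_items Number of items (>= 2).
#' @param reps Appearances per item; `n_items * reps` must be even.
#' @param seed Optional integer seed.
#' @param max_tries Rejection-sampling attempts before giving up.
#' @return A tibble of class `choice_schedule` with columns `trial`,
#'   `item_a`, `item_b`.
#' @examples
#' sched <- build_schedule(28, 8, seed = 1)
#' nrow(sched)  # 112
#' @export
build_schedule <- function(n_items, reps, seed = NULL, max_tries = 1000L) {
  n_items <- check_count(n_items, "n_items", min = 2L)
  reps <- check_count(reps, "reps", min = 1L)
  if ((n_items * reps) %% 2L != 0L)
    abort("`n_items * reps` must be even to pair all appearances.",
          class = "resdec_config_error")
  slots <- rep(seq_len(n_items), reps)
  draw <- function() {
    for (try in seq_len(max_tries)) {
      s <- sample(slots)
      a <- s[c(TRUE, FALSE)]
      b <- s[c(FALSE, TRUE)]
      if (all(a != b)) return(list(a = a, b = b))
    }
    abort("could not build a self-pair-free schedule; try another seed.",
          class = "resdec_config_error")
  }
  m <- with_seed(seed, draw())
  out <- tibble::tibble(trial = seq_along(m$a), item_a = m$a, item_b = m$b)
  class(out) <- c("choice_schedule", class(out))
  out
}

# per-item appearance table: one row per (item, appearance k), with the
# chosen/not-chosen indicator
item_appearances <- function(record) {
  stopifnot(all(c("trial", "item_a", "item_b", "chosen") %in% names(record)))
  bad <- record$chosen != record$item_a & record$chosen != record$item_b
  if (any(bad))
    abort(sprintf("`chosen` must be one of the paired items (trial %d).",
                  record$trial[which(bad)[1]]),
          class = "resdec_config_error")
  dplyr::bind_rows(
    tibble::tibble(trial = record$trial, item = record$item_a,
                   picked = record$chosen == record$item_a),
    tibble::tibble(trial = record$trial, item = record$item_b,
                   picked = record$chosen == record$item_b)
  ) |>
    dplyr::arrange(.data$item, .data$trial) |>
    dplyr::group_by(.data$item) |>
    dplyr::mutate(appearance = dplyr::row_number()) |>
    dplyr::ungroup()
}

#' Repetition consistency of a choice record
#'
#' For every item, compares its chosen/not-chosen indicator at its k-th
#' appearance with the (k + 1)-th; the consistency `c_k` is the fraction
#' of items whose indicator is unchanged between adjacent appearances
#' (first vs second, second vs third, ...). The partner item of each pair
#' is ignored: with random pairings, item-level repetition is the stable
#' unit of comparison.
#'
#' @param record A tibble with columns `trial`, `item_a`, `item_b`,
#'   `chosen` (the chosen item, one of the pair).
#' @return A tibble of class `repetition_consistency` with columns `pair`
#'   (k, comparing appearance k with k + 1) and `consistency`.
#' @export
repetition_consistency <- function(record) {
  app <- item_appearances(record)
  counts <- dplyr::count(app, .data$item)
  k_all <- unique(counts$n)
  if (length(k_all) != 1L)
    abort("every item must appear the same number of times.",
          class = "resdec_config_error")
  if (k_all < 2L)
    abort("items must appear at least twice to score consistency.",
          class = "resdec_config_error")
  out <- app |>
    dplyr::arrange(.data$item, .data$appearance) |>
    dplyr::group_by(.data$item) |>
    dplyr::reframe(same = .data$picked[-1] == .data$picked[-dplyr::n()],
                   pair = seq_len(dplyr::n() - 1L)) |>
    dplyr::group_by(.data$pair) |>
    dplyr::summarise(consistency = mean(.data$same), .groups = "drop")
  class(out) <- c("repetition_consistency", class(out))
  out
}

#' Learning score of a consistency profile
#'
#' Summarizes a repetition-consistency profile as
#' `max(c_2, ..., c_{K-1}) - c_1 + 0.5`: the gain of the best later
#' consistency over the initial one, re-centered so that 0.5 means "no
#' learning" (the chance level of the reservoir model). Values above 0.5
#' indicate that consistency grew over the session.
#'
#' @param rc A `repetition_consistency` tibble (or any tibble with `pair`
#'   and `consistency` columns), needing at least two consistency values.
#' @return A list of class `learning_score` with fields `initial`
#'   (`c_1`), `max_rest`, and `reported`.
#' @examples
#' rc <- tibble::tibble(pair = 1:7,
#'                      consistency = c(.6, .7, .8, .65, .7, .7, .75))
#' learning_score(rc)$reported  # 0.7
#' @export
learning_score <- function(rc) {
  stopifnot(all(c("pair", "consistency") %in% names(rc)))
  cs <- rc$consistency[order(rc$pair)]
  if (length(cs) < 2L)
    abort("need at least two consistency values (reps >= 3).",
          class = "resdec_config_error")
  initial <- cs[1]
  max_rest <- max(cs[-1])
  structure(list(initial = initial, max_rest = max_rest,
                 reported = max_rest - initial + 0.5),
            class = "learning_score")
}

#' @export
print.learning_score <- function(x, ...) {
  cat(sprintf(
    "<learning_score> initial c1 = %.3f, max rest = %.3f, reported = %.3f\n",
    x$initial, x$max_rest, x$reported))
  invisible(x)
}

#' @rdname learning_score
#' @param x A `learning_score`.
#' @param ... Unused.
#' @export
glance.learning_score <- function(x, ...) {
  tibble::tibble(initial = x$initial, max_rest = x$max_rest,
                 reported = x$reported)
}

#' Simulate a synthetic participant
#'
#' Generates a choice record on a random schedule. Each item has a latent
#' preference value; at each trial, with probability `stickiness` the
#' participant re-chooses an item that was chosen at its own most recent
#' appearance (if both qualify, one is picked at random; if neither, the
#' value rule applies), and otherwise picks the item with the larger
#' latent value plus fresh Gaussian noise. `stickiness = 0` with dominant
#' noise gives an inconsistent chooser (c_k near 0.5); high stickiness
#' with small noise yields strongly repeated choices.
#'
#' @inheritParams build_schedule
#' @param stickiness Probability in \\[0, 1\\] of repeating a previous
#'   choice when available.
#' @param value_sd Spread of the latent item values (default 1).
#' @param noise_sd Trial-level noise on the value comparison (default 1).
#' @return A tibble choice record (`trial`, `item_a`, `item_b`, `chosen`)
#'   with the schedule parameters as attributes.
#' @examples
#' rec <- simulate_participant(8, 4, stickiness = 0.9, seed = 5)
#' repetition_consistency(rec)
#' @export
simulate_participant <- function(n_items, reps, stickiness, seed = NULL,
                                 value_sd = 1, noise_sd = 1) {
  if (!is.numeric(stickiness) || stickiness < 0 || stickiness > 1)
    abort("`stickiness` must be in [0, 1].", class = "resdec_config_error")
  run <- function() {
    sched <- build_schedule(n_items, reps)
    values <- rnorm(n_items, sd = value_sd)
    last_chosen <- rep(NA, n_items)  # indicator at the item's last appearance
    chosen <- integer(nrow(sched))
    for (t in seq_len(nrow(sched))) {
      a <- sched$item_a[t]; b <- sched$item_b[t]
      cand <- c(a, b)[c(isTRUE(last_chosen[a]), isTRUE(last_chosen[b]))]
      pick <- if (length(cand) > 0L && runif(1) < stickiness) {
        if (length(cand) == 1L) cand else sample(cand, 1L)
      } else {
        va <- values[a] + rnorm(1, sd = noise_sd)
        vb <- values[b] + rnorm(1, sd = noise_sd)
        if (va >= vb) a else b
      }
      chosen[t] <- pick
      last_chosen[a] <- pick == a
      last_chosen[b] <- pick == b
    }
    dplyr::mutate(sched, chosen = chosen)
  }
  out <- with_seed(seed, run())
  attr(out, "stickiness") <- stickiness
  out
}
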