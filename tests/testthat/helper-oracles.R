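# Independent oracles and small fixtures used across the suite.

# The printed 8x8 rate-equation matrix for the single-lower-level (N = 1)
# reservoir, hand-coded in the diagram state order (1 = empty, 2 = {lower},
# 3 = {upper-left}, 4 = {upper-right}, 5 = {lower, UL}, 6 = {lower, UR},
# 7 = {UL, UR}, 8 = all). Used as the frozen reference for the generator
# builder; every entry is a linear form in the three rates.
printed_rate_matrix_n1 <- function(gi, gu, go) {
  matrix(c(
    -gi,      0,        go,        go,        0,        0,        0,       0,
     gi,     -2 * gu,   0,         0,         go,       go,       0,       0,
     0,       gu,      -gi - go,   0,         0,        0,        go,      0,
     0,       gu,       0,        -gi - go,   0,        0,        go,      0,
     0,       0,        gi,        0,        -go - gu,  0,        0,       go,
     0,       0,        0,         gi,        0,       -go - gu,  0,       go,
     0,       0,        0,         0,         gu,       gu,      -gi - 2 * go, 0,
     0,       0,        0,         0,         0,        0,        gi,     -2 * go
  ), nrow = 8, byrow = TRUE)
}

# Brute-force arrow enumeration straight from the occupancy definition,
# written against raw logical vectors rather than the package state object.
brute_arrows <- function(lower, upper) {
  n <- length(lower)
  out <- list()
  for (i in seq_len(n)) {
    if (lower[i] && !upper[i + 1]) out[[length(out) + 1]] <- c("L", i)
    if (lower[i] && !upper[i]) out[[length(out) + 1]] <- c("R", i)
  }
  if (length(out) == 0) return(data.frame(kind = character(), index = integer()))
  m <- do.call(rbind, out)
  data.frame(kind = m[, 1], index = as.integer(m[, 2]))
}

# run a pure-R trace through step_cycle (reference path)
r_trace <- function(config, n_cycles) {
  st <- reservoir_init(config)
  dec <- character(n_cycles)
  for (i in seq_len(n_cycles)) {
    r <- step_cycle(st)
    st <- r$state
    dec[i] <- r$decision
  }
  list(decisions = dec, state = st)
}

# choice record for a chooser with a liked/disliked item partition and
# schedules that always pair a liked with a disliked item: the chosen
# indicator of every item is constant, so all c_k = 1
liked_disliked_record <- function(n_pairs = 4, reps = 3) {
  liked <- seq_len(n_pairs)
  disliked <- n_pairs + seq_len(n_pairs)
  rows <- list()
  t <- 0
  for (k in seq_len(reps)) {
    shift <- (seq_len(n_pairs) + k - 2) %% n_pairs + 1
    for (j in seq_len(n_pairs)) {
      t <- t + 1
      rows[[t]] <- data.frame(trial = t, item_a = liked[j],
                              item_b = disliked[shift[j]],
                              chosen = liked[j])
    }
  }
  tibble::as_tibble(do.call(rbind, rows))
}
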