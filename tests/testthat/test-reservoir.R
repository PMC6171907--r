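test_that("initial state has all lowers occupied, uppers vacant, full arrow set", {
  st <- reservoir_init(reservoir_config(4, 10))
  expect_true(all(st$lower_occupied))
  expect_false(any(st$upper_occupied))
  expect_true(all(is.na(st$lower_refill_cycle)))
  expect_true(all(is.na(st$upper_clear_cycle)))
  expect_equal(st$cycle, 0L)
  expect_equal(nrow(available_arrows(st)), 8L)
  expect_equal(active_portion(st), 0)

  st1 <- reservoir_init(reservoir_config(1, 1))
  a1 <- available_arrows(st1)
  expect_equal(nrow(a1), 2L)
  expect_setequal(a1$kind, c("L", "R"))

  expect_error(reservoir_config(0, 10), class = "resdec_config_error")
  expect_error(reservoir_config(4, 0), class = "resdec_config_error")
})

test_that("executing an arrow disables its own kind once and the other kind twice", {
  # worked example: N = 5, L-arrow 2 occupies upper 3 and vacates lower 2,
  # disabling L2 plus R2 and R3
  st <- reservoir_init(reservoir_config(5, 10))
  exec <- function(st, kind, i) {
    tgt <- if (kind == "L") i + 1L else i
    st$lower_occupied[i] <- FALSE
    st$lower_refill_cycle[i] <- st$cycle + st$config$lifetime
    st$upper_occupied[tgt] <- TRUE
    st$upper_clear_cycle[tgt] <- st$cycle + st$config$lifetime
    st
  }
  st <- exec(st, "L", 2L)
  a <- available_arrows(st)
  expect_equal(nrow(a), 7L)
  expect_setequal(a$index[a$kind == "L"], c(1L, 3L, 4L, 5L))
  expect_setequal(a$index[a$kind == "R"], c(1L, 4L, 5L))
  expect_equal(active_portion(st), 0.3)

  # after L2 then L4: three L-arrows and a single R-arrow remain
  st <- exec(st, "L", 4L)
  a <- available_arrows(st)
  expect_setequal(a$index[a$kind == "L"], c(1L, 3L, 5L))
  expect_equal(a$index[a$kind == "R"], 1L)
})

test_that("available_arrows matches brute-force enumeration on random states", {
  set.seed(42)
  for (rep in 1:50) {
    n <- sample(1:6, 1)
    st <- reservoir_init(reservoir_config(n, 5))
    st$lower_occupied <- runif(n) < 0.5
    st$upper_occupied <- runif(n + 1) < 0.5
    got <- available_arrows(st)
    want <- brute_arrows(st$lower_occupied, st$upper_occupied)
    expect_equal(nrow(got), nrow(want))
    expect_setequal(paste(got$kind, got$index), paste(want$kind, want$index))
  }
})

test_that("N = 1, lifetime 3: a decision is followed by stalled cycles until recovery", {
  # after the single lower level is used at cycle t it refills at t + 3,
  # so at most one decision can occur in any 3-cycle window
  tr <- run_trace(reservoir_config(1, 3, seed = 7), 300)
  dec_cycles <- tr$cycle[tr$decision != "none"]
  expect_true(length(dec_cycles) > 0)
  expect_true(all(diff(dec_cycles) >= 3))
  expect_true(any(tr$decision == "none"))
})

test_that("lifetime 1 keeps the full arrow set: no stalls, fair i.i.d. decisions", {
  tr <- run_trace(reservoir_config(1, 1, seed = 3), 2000)
  expect_false(any(tr$decision == "none"))
  frac_l <- mean(tr$decision == "L")
  expect_lt(abs(frac_l - 0.5), 3 * sqrt(0.25 / 2000))
  # no serial correlation: consecutive-pair agreement at chance
  d <- tr$decision
  agree <- mean(d[-1] == d[-length(d)])
  expect_lt(abs(agree - 0.5), 3 * sqrt(0.25 / (length(d) - 1)))
})

test_that("step_cycle timers obey the lifetime and occupancy conservation holds", {
  set.seed(11)
  st <- reservoir_init(reservoir_config(3, 4))
  for (k in 1:60) {
    r <- step_cycle(st)
    st <- r$state
    # timer exists iff resource in use
    expect_equal(is.na(st$lower_refill_cycle), st$lower_occupied)
    expect_equal(!is.na(st$upper_clear_cycle), st$upper_occupied)
    # timers within (cycle - lifetime, cycle + lifetime]
    tv <- c(st$lower_refill_cycle, st$upper_clear_cycle)
    tv <- tv[!is.na(tv)]
    expect_true(all(tv > st$cycle - st$config$lifetime))
    expect_true(all(tv <= st$cycle - 1L + st$config$lifetime))
    # vacant lowers equal pending refills; occupied uppers equal pending clears
    expect_equal(sum(!st$lower_occupied), sum(!is.na(st$lower_refill_cycle)))
    expect_equal(sum(st$upper_occupied), sum(!is.na(st$upper_clear_cycle)))
    expect_lte(nrow(available_arrows(st)), 2L * st$config$n_levels)
  }
})

test_that("compiled trace and pure-R stepper are bit-identical under one seed", {
  for (cfg in list(reservoir_config(1, 3, seed = 5),
                   reservoir_config(4, 10, seed = 6),
                   reservoir_config(2, 7, seed = 8))) {
    tr <- run_trace(cfg, 80)
    set.seed(cfg$seed)
    ref <- r_trace(cfg, 80)
    expect_identical(tr$decision, ref$decisions)
  }
})

test_that("traces are reproducible under a fixed seed and symmetric in L/R", {
  cfg <- reservoir_config(100, 10, seed = 123)
  t1 <- run_trace(cfg, 3000)
  t2 <- run_trace(cfg, 3000)
  expect_identical(t1, t2)
  dec <- t1$decision[t1$decision != "none"]
  expect_lt(abs(mean(dec == "L") - 0.5), 3 * sqrt(0.25 / length(dec)))
})

test_that("random_walk_path accumulates L up, R down, and holds on stalls", {
  tr <- tibble::tibble(cycle = 0:2, decision = c("L", "L", "R"))
  expect_equal(random_walk_path(tr)$position, c(1, 2, 1))
  tr2 <- tibble::tibble(cycle = 0:2, decision = c("L", "none", "R"))
  expect_equal(random_walk_path(tr2)$position, c(1, 1, 0))
})

test_that("walkers starting with Decision L drift upward under CBL", {
  # small reservoir, long lifetime: positive mean displacement after an
  # initial L over the following decisions
  set.seed(21)
  disp <- replicate(300, {
    tr <- run_trace(reservoir_config(4, 10), 120)
    d <- tr$decision[tr$decision != "none"]
    if (length(d) < 12 || d[1] != "L") return(NA_real_)
    sum(ifelse(d[2:11] == "L", 1, -1))
  })
  disp <- disp[!is.na(disp)]
  expect_gt(mean(disp), 0)
})
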