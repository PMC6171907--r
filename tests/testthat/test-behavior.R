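test_that("schedules give every item exactly `reps` appearances with no self-pairs", {
  sched <- build_schedule(28, 8, seed = 1)
  expect_equal(nrow(sched), 112L)
  counts <- table(c(sched$item_a, sched$item_b))
  expect_equal(length(counts), 28L)
  expect_true(all(counts == 8L))
  expect_true(all(sched$item_a != sched$item_b))

  expect_equal(nrow(build_schedule(4, 2, seed = 2)), 4L)
  expect_error(build_schedule(3, 3), class = "resdec_config_error")
})

test_that("schedule validity holds across many seeds", {
  for (seed in 1:200) {
    sched <- build_schedule(7, 4, seed = seed)
    counts <- table(factor(c(sched$item_a, sched$item_b), levels = 1:7))
    expect_true(all(counts == 4L))
    expect_true(all(sched$item_a != sched$item_b))
  }
})

test_that("the toy record scores a first-pair consistency of 0.75", {
  rec <- resdec:::toy_choice_record()
  rc <- repetition_consistency(rec)
  expect_equal(nrow(rc), 1L)
  expect_equal(rc$consistency, 0.75)
})

test_that("a liked/disliked partition chooser is perfectly consistent", {
  rec <- liked_disliked_record(n_pairs = 4, reps = 4)
  rc <- repetition_consistency(rec)
  expect_equal(rc$consistency, rep(1, 3))
})

test_that("a uniformly random chooser scores near 0.5 at every pair", {
  set.seed(61)
  sched <- build_schedule(30, 6)
  rec <- dplyr::mutate(sched,
                       chosen = ifelse(runif(dplyr::n()) < 0.5,
                                       item_a, item_b))
  rc <- repetition_consistency(rec)
  expect_equal(nrow(rc), 5L)
  expect_true(all(abs(rc$consistency - 0.5) < 3 * sqrt(0.25 / 30) + 0.05))
})

test_that("consistency scoring validates its input", {
  rec <- resdec:::toy_choice_record()
  bad <- rec
  bad$chosen[2] <- 99L
  expect_error(repetition_consistency(bad), class = "resdec_config_error")
  uneven <- rec[-8, ]
  expect_error(repetition_consistency(uneven),
               class = "resdec_config_error")
})

test_that("the learning score applies max-rest minus initial plus a 0.5 bias", {
  rc <- tibble::tibble(pair = 1:7,
                       consistency = c(0.6, 0.7, 0.8, 0.65, 0.7, 0.7, 0.75))
  ls <- learning_score(rc)
  expect_equal(ls$reported, 0.8 - 0.6 + 0.5)
  # flat profile: no learning, reference value 0.5
  flat <- tibble::tibble(pair = 1:7, consistency = rep(0.62, 7))
  expect_equal(learning_score(flat)$reported, 0.5)
  # maximal learning
  ext <- tibble::tibble(pair = 1:3, consistency = c(0.5, 1, 0.7))
  expect_equal(learning_score(ext)$reported, 1)
  expect_error(learning_score(tibble::tibble(pair = 1, consistency = 0.5)),
               class = "resdec_config_error")
  expect_equal(unname(unlist(glance(ls))), c(0.6, 0.8, 0.7))
})

test_that("synthetic participants span chance to strong repetition", {
  set.seed(62)
  mean_c <- function(stickiness, ...) {
    mean(replicate(25, mean(repetition_consistency(
      simulate_participant(20, 6, stickiness = stickiness, ...)
    )$consistency)))
  }
  c0 <- mean_c(0, value_sd = 0, noise_sd = 1)   # pure-noise chooser
  expect_lt(abs(c0 - 0.5), 0.05)
  # full stickiness with noiseless values: strong but not perfect
  # repetition (an item that lost its last appearance can still win a
  # later pairing on value, flipping its indicator)
  c1 <- mean_c(1, noise_sd = 0)
  expect_gt(c1, 0.7)
  expect_gt(c1, c0 + 0.15)
})

test_that("reported learning-type scores rise monotonically with stickiness", {
  set.seed(64)
  levels <- c(0, 0.25, 0.5, 0.75, 1)
  mean_c <- vapply(levels, function(s) {
    mean(replicate(60, {
      rec <- simulate_participant(12, 4, stickiness = s, noise_sd = 2)
      mean(repetition_consistency(rec)$consistency)
    }))
  }, numeric(1))
  expect_true(all(diff(mean_c) > 0))
  expect_gt(stats::cor(levels, mean_c, method = "spearman"), 0.95)
})

test_that("curve inversion recovers sizes and flags boundary and overshoot", {
  curve <- tibble::tibble(n_levels = c(2, 5, 10, 20, 50),
                          consistency = c(0.70, 0.62, 0.56, 0.52, 0.50))
  est <- estimate_reservoir_size(0.70, curve)
  expect_equal(est$status, "in-range")
  expect_equal(est$n_hat, 2)
  mid <- estimate_reservoir_size(0.59, curve)
  expect_equal(mid$status, "in-range")
  expect_true(mid$n_hat > 5 && mid$n_hat < 10)
  low <- estimate_reservoir_size(0.5, curve)
  expect_equal(low$status, "at-boundary")
  expect_gte(low$n_hat, 50)
  high <- estimate_reservoir_size(0.75, curve)
  expect_equal(high$status, "above-curve")
  expect_true(is.na(high$n_hat))
  expect_error(estimate_reservoir_size(0.6, curve[0, ]),
               class = "resdec_config_error")
  gl <- glance(high)
  expect_equal(gl$status, "above-curve")
})

test_that("estimated size decreases as synthetic participants get stickier", {
  curve <- tibble::tibble(n_levels = c(2, 5, 10, 20, 50),
                          consistency = c(0.70, 0.62, 0.56, 0.52, 0.50))
  set.seed(65)
  est_for <- function(s) {
    cs <- mean(replicate(40, {
      rec <- simulate_participant(12, 4, stickiness = s, noise_sd = 2)
      mean(repetition_consistency(rec)$consistency)
    }))
    est <- estimate_reservoir_size(cs, curve)
    if (est$status == "above-curve") 0 else est$n_hat
  }
  n_lo <- est_for(0.2)
  n_hi <- est_for(0.8)
  expect_gt(n_lo, n_hi)
})
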