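test_that("parse_config fills protocol defaults and validates keys", {
  cfg <- parse_config("simulate-reservoir", list(n_levels = 4, seed = 1))
  expect_equal(cfg$options$t0, 2000L)
  expect_equal(cfg$options$cycles, 3000L)
  expect_equal(cfg$options$lifetime, 10L)

  expect_error(parse_config("simulate-reservoir",
                            list(n_levels = 4, bogus = 1)),
               class = "resdec_config_error")
  expect_error(parse_config("simulate-reservoir", list(lifetime = 5)),
               class = "resdec_config_error")
  expect_error(parse_config("simulate-reservoir",
                            list(n_levels = 4, lifetime = 0)),
               class = "resdec_config_error")
  expect_error(parse_config("frobnicate", list()),
               class = "resdec_config_error")
  # identical input gives an identical parsed config
  expect_identical(parse_config("analytic",
                                list(n_levels = 1, gamma_in = 1,
                                     gamma_up = 1, gamma_out = 1)),
                   parse_config("analytic",
                                list(n_levels = 1, gamma_in = 1,
                                     gamma_up = 1, gamma_out = 1)))
})

test_that("parse_config reads options from a YAML file", {
  yml <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("n_levels: 2", "gamma_in: 1", "gamma_up: 1",
               "gamma_out: 10"), yml)
  cfg <- parse_config("analytic", yml)
  expect_equal(cfg$options$n_levels, 2)
  expect_equal(cfg$options$gamma_out, 10)
})

test_that("the analytic subcommand returns eight state probabilities for N = 1", {
  cfg <- parse_config("analytic", list(n_levels = 1, gamma_in = 1,
                                       gamma_up = 1, gamma_out = 1))
  res <- run_subcommand(cfg)
  expect_length(res$p, 8L)
  expect_equal(sum(res$p), 1, tolerance = 1e-9)
  expect_equal(res$p_LL + res$p_LR, 1, tolerance = 1e-9)
  expect_true(is.finite(res$closed_form_imbalance))
})

test_that("subcommands write round-trippable outputs with a metadata sidecar", {
  dir <- withr::local_tempdir()
  out <- file.path(dir, "curve.csv")
  cfg <- parse_config("simulate-reservoir",
                      list(n_levels = 4, lifetime = 5, cycles = 300,
                           runs = 200, t0 = 200, max_lag = 5, seed = 9,
                           out = out))
  run_subcommand(cfg)
  expect_true(file.exists(out))
  got <- read.csv(out)
  expect_equal(names(got), c("lag", "mean_consistency", "n_runs",
                             "n_excluded"))
  expect_equal(nrow(got), 5L)
  meta <- jsonlite::read_json(paste0(out, ".meta.json"))
  expect_equal(meta$subcommand, "simulate-reservoir")
  expect_equal(meta$options$seed, 9)
  # deterministic re-run from the sidecar reproduces the file
  out2 <- file.path(dir, "curve2.csv")
  opts <- meta$options
  opts$out <- out2
  run_subcommand(parse_config(meta$subcommand, opts))
  expect_identical(read.csv(out2), got)
})

test_that("behavior-score pipes a CSV record through scoring and estimation", {
  dir <- withr::local_tempdir()
  rec_path <- file.path(dir, "choices.csv")
  write.csv(resdec:::toy_choice_record(), rec_path, row.names = FALSE)
  curve_path <- file.path(dir, "curve.json")
  jsonlite::write_json(list(n_levels = c(2, 5, 10, 20, 50),
                            consistency = c(0.70, 0.62, 0.56, 0.52, 0.50)),
                       curve_path)
  # the toy record has a single consistency pair, so scoring alone works
  res <- run_subcommand(parse_config("behavior-score",
                                     list(`in` = rec_path)))
  expect_equal(unname(res$consistency["c1"]), 0.75)
})

test_that("fixture generation writes the documented deterministic files", {
  dir <- withr::local_tempdir()
  p1 <- generate_fixtures("choice-record", dir = dir)
  rec <- tibble::as_tibble(read.csv(p1))
  expect_equal(repetition_consistency(rec)$consistency, 0.75)
  p2 <- generate_fixtures("reservoir-trace", dir = dir, seed = 1)
  tr <- read.csv(p2)
  expect_equal(nrow(tr), 10L)
  expect_true("none" %in% tr$decision)
  p3 <- generate_fixtures("photon-trace", dir = dir, seed = 1)
  expect_lt(nrow(read.csv(p3)), 10L)
})
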