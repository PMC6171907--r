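# Front-end plumbing: config parsing, subcommand dispatch, fixtures.
# The `resdec` CLI script (inst/scripts/resdec) is a thin wrapper over
# parse_config() + run_subcommand().

subcommand_defaults <- list(
  `simulate-reservoir` = list(n_levels = NULL, lifetime = 10L,
                              cycles = 3000L, runs = 10000L, t0 = 2000L,
                              max_lag = 100L, seed = NULL, out = NULL),
  analytic = list(n_levels = NULL, gamma_in = NULL, gamma_up = NULL,
                  gamma_out = NULL, out = NULL),
  `simulate-photon` = list(resolution = NULL, decisions = 500L,
                           runs = 10000L, seed = NULL, out = NULL),
  `behavior-score` = list(`in` = NULL, curve = NULL, out = NULL),
  `estimate-n` = list(consistency = NULL, lifetime = 10L, runs = 10000L,
                      t0 = 2000L, seed = NULL, out = NULL),
  fixtures = list(kind = NULL, dir = ".", seed = 1L)
)

required_keys <- list(
  `simulate-reservoir` = "n_levels",
  analytic = c("n_levels", "gamma_in", "gamma_up", "gamma_out"),
  `simulate-photon` = "resolution",
  `behavior-score` = "in",
  `estimate-n` = "consistency",
  fixtures = "kind"
)

#' Parse a run configuration
#'
#' Validates a subcommand plus key-value options (e.g. from CLI flags or a
#' YAML file) against that subcommand's schema: unknown keys are rejected,
#' missing required keys raise an error, and defaults matching the
#' reference protocols are filled in (3000 cycles, reference cycle 2000,
#' 500 photon decisions, lifetime 10).
#'
#' @param subcommand One of `"simulate-reservoir"`, `"analytic"`,
#'   `"simulate-photon"`, `"behavior-score"`, `"estimate-n"`,
#'   `"fixtures"`.
#' @param options Named list of option values, or a path to a YAML file
#'   holding one.
#' @return A list of class `run_config` with fields `subcommand` and the
#'   resolved options.
#' @examples
#' parse_config("simulate-reservoir", list(n_levels = 4, seed = 1))
#' @export
parse_config <- function(subcommand, options = list()) {
  if (!subcommand %in% names(subcommand_defaults))
    abort(sprintf("unknown subcommand '%s' (available: %s)", subcommand,
                  paste(names(subcommand_defaults), collapse = ", ")),
          class = "resdec_config_error")
  if (is.character(options) && length(options) == 1L)
    options <- yaml::read_yaml(options)
  defaults <- subcommand_defaults[[subcommand]]
  unknown <- setdiff(names(options), names(defaults))
  if (length(unknown) > 0L)
    abort(sprintf("unknown option(s) for %s: %s", subcommand,
                  paste(unknown, collapse = ", ")),
          class = "resdec_config_error")
  opts <- utils::modifyList(defaults, options)
  missing <- required_keys[[subcommand]]
  missing <- missing[vapply(opts[missing], is.null, logical(1))]
  if (length(missing) > 0L)
    abort(sprintf("missing required option(s) for %s: %s", subcommand,
                  paste(missing, collapse = ", ")),
          class = "resdec_config_error")
  # validate the numbers the schemas share
  if (!is.null(opts$lifetime)) check_count(opts$lifetime, "lifetime", 1L)
  if (!is.null(opts$n_levels)) check_count(opts$n_levels, "n_levels", 1L)
  structure(list(subcommand = subcommand, options = opts),
            class = "run_config")
}

write_sidecar <- function(path, config) {
  meta <- list(subcommand = config$subcommand, options = config$options,
               package_version =
                 as.character(utils::packageVersion("resdec")))
  jsonlite::write_json(meta, paste0(path, ".meta.json"), auto_unbox = TRUE,
                       pretty = TRUE, null = "null")
}

#' Run a parsed configuration
#'
#' Dispatches a [parse_config()] result to the owning module, writes the
#' requested outputs (CSV for curves and traces, JSON for probabilities
#' and estimates) plus a `.meta.json` sidecar holding the full
#' configuration, and returns the result invisibly.
#'
#' @param config A `run_config` from [parse_config()].
#' @return The computed result (tibble or list), invisibly when written to
#'   a file.
#' @export
run_subcommand <- function(config) {
  stopifnot(inherits(config, "run_config"))
  o <- config$options
  result <- switch(config$subcommand,
    `simulate-reservoir` = {
      cc <- decision_consistency_curve(
        reservoir_config(o$n_levels, o$lifetime, seed = o$seed),
        t0 = o$t0, max_lag = o$max_lag, n_runs = o$runs,
        n_cycles = max(o$cycles, o$t0 + o$max_lag))
      dplyr::select(tibble::as_tibble(cc), "lag", "mean_consistency",
                    n_runs = "n_runs_used", "n_excluded")
    },
    analytic = {
      dp <- decision_transition_probs(
        o$n_levels, rate_params(o$gamma_in, o$gamma_up, o$gamma_out))
      res <- list(p = dp$pi, p_LL = dp$p_LL, p_LR = dp$p_LR,
                  p_RL = dp$p_RL, p_RR = dp$p_RR, imbalance = dp$imbalance)
      if (o$n_levels == 1L) {
        p_diag <- dp$pi[diagram_perm_n1]
        res$closed_form_imbalance <- closed_form_imbalance_n1(
          rate_params(o$gamma_in, o$gamma_up, o$gamma_out), p_diag)
      }
      res
    },
    `simulate-photon` = photon_consistency_curve(
      o$resolution, n_decisions = o$decisions, n_runs = o$runs,
      seed = o$seed),
    `behavior-score` = {
      record <- tibble::as_tibble(read.csv(o$`in`))
      rc <- repetition_consistency(record)
      score <- if (nrow(rc) >= 2L) learning_score(rc)$reported else NA_real_
      res <- list(consistency = setNames(rc$consistency,
                                         paste0("c", rc$pair)),
                  learning_score = score)
      if (!is.null(o$curve) && !is.na(score)) {
        cv <- tibble::as_tibble(as.data.frame(jsonlite::read_json(
          o$curve, simplifyVector = TRUE)))
        est <- estimate_reservoir_size(score, cv)
        res$n_hat <- est$n_hat
        res$status <- est$status
      }
      res
    },
    `estimate-n` = {
      cv <- model_curve(lifetime = o$lifetime, t0 = o$t0, n_runs = o$runs,
                        seed = o$seed)
      est <- estimate_reservoir_size(o$consistency, cv)
      list(observed = est$observed, n_hat = est$n_hat, status = est$status,
           curve = list(n_levels = cv$n_levels,
                        consistency = cv$consistency))
    },
    fixtures = generate_fixtures(o$kind, dir = o$dir, seed = o$seed)
  )
  if (!is.null(o$out)) {
    if (inherits(result, "data.frame")) {
      write.csv(result, o$out, row.names = FALSE)
    } else {
      jsonlite::write_json(result, o$out, auto_unbox = TRUE, digits = NA,
                           pretty = TRUE)
    }
    write_sidecar(o$out, config)
    return(invisible(result))
  }
  result
}

#' Generate small deterministic fixtures
#'
#' Writes the plain-text fixtures used in examples and tests: a reservoir
#' decision trace with a stalled (no-decision) cycle, a quickly
#' terminating coarse-resolution photon trace, or a 4-item toy choice
#' record with a hand-checkable first-pair consistency of 0.75.
#'
#' @param kind `"reservoir-trace"`, `"photon-trace"`, or
#'   `"choice-record"`.
#' @param dir Output directory.
#' @param seed Integer seed.
#' @return The path of the written CSV, invisibly.
#' @export
generate_fixtures <- function(kind = c("reservoir-trace", "photon-trace",
                                       "choice-record"),
                              dir = ".", seed = 1L) {
  kind <- match.arg(kind)
  path <- file.path(dir, paste0(kind, ".csv"))
  data <- switch(kind,
    "reservoir-trace" = run_trace(reservoir_config(1, 3, seed = seed), 10L),
    "photon-trace" = run_photon_trace(photon_config(4, seed = seed)),
    "choice-record" = toy_choice_record()
  )
  write.csv(data, path, row.names = FALSE)
  invisible(path)
}

# 8 items x 2 appearances; items 2 and 3 flip their chosen indicator
# between appearances, the rest keep it: c_1 = 6/8 = 0.75. (With an even
# trial count the number of flipped items is always even, so 0.75 needs
# at least 8 items.)
toy_choice_record <- function() {
  tibble::tibble(
    trial = 1:8,
    item_a = c(1L, 3L, 5L, 7L, 1L, 2L, 5L, 7L),
    item_b = c(2L, 4L, 6L, 8L, 3L, 4L, 6L, 8L),
    chosen = c(1L, 3L, 5L, 7L, 1L, 2L, 5L, 7L)
  )
}
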