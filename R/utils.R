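# internal helpers shared across modules

# run `code` under a temporary RNG seed, restoring the caller's RNG state;
# seed = NULL leaves the ambient RNG untouched
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  force(code)
}

check_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x != round(x) || x < min) {
    abort(sprintf("`%s` must be a single integer >= %d, got %s.",
                  name, min, deparse(substitute(x))),
          class = "resdec_config_error")
  }
  as.integer(x)
}

check_positive <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x <= 0) {
    abort(sprintf("`%s` must be a single positive number.", name),
          class = "resdec_config_error")
  }
  as.numeric(x)
}
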