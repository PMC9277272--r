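# Classed conditions so the CLI can map failures to exit codes:
# domain errors (bad arguments) -> 1, format errors (bad files) -> 2.

abort_domain <- function(msg) {
  stop(errorCondition(msg, class = c("chainscaling_domain_error", "chainscaling_error")))
}

abort_format <- function(msg) {
  stop(errorCondition(msg, class = c("chainscaling_format_error", "chainscaling_error")))
}

abort_usage <- function(msg) {
  stop(errorCondition(msg, class = c("chainscaling_usage_error", "chainscaling_error")))
}

abort_numeric <- function(msg) {
  stop(errorCondition(msg, class = c("chainscaling_numeric_error", "chainscaling_error")))
}

check_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < min || x != round(x))
    abort_domain(sprintf("`%s` must be a single integer >= %d", name, min))
  as.integer(x)
}

check_positive <- function(x, name, allow_zero = FALSE) {
  ok <- is.numeric(x) && length(x) == 1L && is.finite(x) &&
    (x > 0 || (allow_zero && x >= 0))
  if (!ok)
    abort_domain(sprintf("`%s` must be a single %s number",
                         name, if (allow_zero) "non-negative" else "positive"))
  as.numeric(x)
}

# Evaluate `code` under a fixed RNG seed without disturbing the caller's
# RNG state.
with_seed <- function(seed, code) {
  env <- globalenv()
  old <- if (exists(".Random.seed", envir = env, inherits = FALSE))
    get(".Random.seed", envir = env) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = env, inherits = FALSE))
        rm(".Random.seed", envir = env)
    } else assign(".Random.seed", old, envir = env)
  })
  set.seed(as.integer(seed %% 2147483647))
  force(code)
}
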