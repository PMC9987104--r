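# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

clamp01 <- function(x) pmin(1, pmax(0, x))

# All exported simulators take one explicit integer seed; RNG state is
# restored afterwards so no global state leaks between calls.
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  withr::with_seed(as.integer(seed), code)
}

stop_if_not_scalar_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    stop(sprintf("'%s' must be a single finite number", name), call. = FALSE)
  }
  if (x < lower || x > upper) {
    stop(sprintf("'%s' must be in [%s, %s], got %s", name,
                 format(lower), format(upper), format(x)), call. = FALSE)
  }
  invisible(x)
}
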