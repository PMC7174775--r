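# internal helpers

stop_param <- function(msg, ...) {
  abort(sprintf(msg, ...), class = "hdemg_parameter_error")
}

stop_format <- function(msg, ...) {
  abort(sprintf(msg, ...), class = "hdemg_format_error")
}

check_number <- function(x, name, lower = -Inf, upper = Inf,
                         allow_equal_lower = TRUE, allow_equal_upper = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop_param("`%s` must be a single finite number", name)
  }
  lo_ok <- if (allow_equal_lower) x >= lower else x > lower
  hi_ok <- if (allow_equal_upper) x <= upper else x < upper
  if (!lo_ok || !hi_ok) {
    stop_param("`%s` = %g is outside the allowed range %s%g, %g%s", name, x,
               if (allow_equal_lower) "[" else "(", lower, upper,
               if (allow_equal_upper) "]" else ")")
  }
  invisible(x)
}

# Draw sub-seeds below 2^31 deterministically from a parent seed (or from the
# current RNG stream when seed is NULL).
draw_seeds <- function(n, seed = NULL) {
  draw <- function() sample.int(.Machine$integer.max, n)
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

with_seed_maybe <- function(seed, code) {
  if (is.null(seed)) code else withr::with_seed(seed, code)
}

as_signal_matrix <- function(x, name = "signals") {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
  if (!is.matrix(x) || !is.numeric(x)) {
    stop_param("`%s` must be a numeric channels x samples matrix", name)
  }
  x
}
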