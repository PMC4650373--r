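# Internal helpers shared across modules.

`%||%` <- function(x, y) if (is.null(x)) y else x

# Geometric mean of strictly positive values.
gm_mean <- function(x) exp(mean(log(x)))

abort_arg <- function(msg) rlang::abort(msg, class = "trnmapr_argument_error")
abort_data <- function(msg) rlang::abort(msg, class = "trnmapr_data_error")

assert_scalar_number <- function(x, name, min = -Inf, strict_min = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    abort_arg(sprintf("`%s` must be a single number", name))
  }
  if (strict_min && x <= min) {
    abort_arg(sprintf("`%s` must be > %s", name, format(min)))
  }
  if (!strict_min && x < min) {
    abort_arg(sprintf("`%s` must be >= %s", name, format(min)))
  }
  invisible(x)
}

assert_count <- function(x, name, min = 1L) {
  assert_scalar_number(x, name, min = min)
  if (x != as.integer(x)) abort_arg(sprintf("`%s` must be an integer", name))
  invisible(as.integer(x))
}
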