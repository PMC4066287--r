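`%||%` <- function(a, b) if (is.null(a)) b else a

# Validation helper: all checks name the offending field.
stop_field <- function(field, msg) {
  stop(sprintf("invalid field '%s': %s", field, msg), call. = FALSE)
}

check_fraction <- function(x, field, open_left = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x))
    stop_field(field, "must be a single number")
  lo_ok <- if (open_left) x > 0 else x >= 0
  if (!lo_ok || x > 1)
    stop_field(field, sprintf("must lie in %s0,1]", if (open_left) "(" else "["))
  x
}

check_count <- function(x, field, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x != round(x))
    stop_field(field, sprintf("must be an integer >= %d", min))
  as.integer(x)
}

# Derive a stream-specific seed from a master seed, staying inside 32-bit
# integer range.
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) + 104729 * offset) %% 2147483629)
}
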