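# internal helpers shared across modules

# round-half-up (R's round() is banker's rounding; mm -> px conversion
# must map 5/0.7 = 7.14 -> 7 and 7.5 -> 8 deterministically)
round_half_up <- function(x) floor(x + 0.5)

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x > 0 && x == as.integer(x)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a
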