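# internal assertion helpers

abort_if <- function(cond, ...) {
  if (isTRUE(cond)) stop(..., call. = FALSE)
}

is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

is_count <- function(x) is_number(x) && x >= 0 && x == floor(x)

is_prob <- function(x) is_number(x) && x >= 0 && x <= 1

`%||%` <- function(a, b) if (is.null(a)) b else a
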