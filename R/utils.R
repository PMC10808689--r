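DAYS_PER_MONTH <- 365.25 / 12
DAYS_PER_YEAR <- 365.25

`%||%` <- function(x, y) if (is.null(x)) y else x

stop_input <- function(...) stop(sprintf(...), call. = FALSE)

assert_that <- function(cond, ...) {
  if (!isTRUE(cond)) stop_input(...)
  invisible(TRUE)
}

is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

days_to_months <- function(days) days / DAYS_PER_MONTH
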