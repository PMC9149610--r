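#' @importFrom rlang abort %||% .data
#' @importFrom stats rnorm runif setNames
#' @importFrom utils modifyList write.table
NULL

clamp <- function(x, lo, hi) min(max(x, lo), hi)

is_count1 <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x)

abort_input <- function(msg, ...) {
  abort(msg, class = c("nivflow_input_error", "nivflow_error"), ...)
}

abort_protocol <- function(msg, ...) {
  abort(msg, class = c("nivflow_protocol_error", "nivflow_error"), ...)
}

abort_config <- function(msg, ...) {
  abort(msg, class = c("nivflow_configuration_error", "nivflow_error"), ...)
}

# integer-valued check (pressures are whole mbar)
check_integerish <- function(x, what) {
  if (!is_count1(x) || x != round(x)) {
    abort_input(sprintf("%s must be a whole number, got %s", what,
                        paste(format(x), collapse = ", ")))
  }
  as.integer(round(x))
}
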