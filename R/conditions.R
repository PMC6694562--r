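# Classed conditions so callers can distinguish bad input from thin data.

tc_error <- function(class, message, ..., call. = FALSE) {
  cond <- structure(
    class = c(class, "tumorclock_error", "error", "condition"),
    list(message = message, call = if (isTRUE(call.)) sys.call(-1) else NULL, ...)
  )
  stop(cond)
}

stop_invalid <- function(message, ...) tc_error("tc_invalid_input", message, ...)

#' @details Insufficient-data conditions carry the observed count in `$n_obs`
#'   and the required minimum in `$n_required`.
#' @noRd
stop_insufficient <- function(message, n_obs, n_required) {
  tc_error("tc_insufficient_data", message, n_obs = n_obs, n_required = n_required)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
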