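# Classed conditions so callers (and the pipeline's partial-failure contract)
# can distinguish bad input from degenerate data from fit failure.

wb_abort <- function(message, class, ...) {
  stop(structure(
    class = c(class, "wb_error", "error", "condition"),
    list(message = message, call = sys.call(-1), ...)
  ))
}

wb_format_error     <- function(msg, ...) wb_abort(msg, "wb_format_error", ...)
wb_validation_error <- function(msg, ...) wb_abort(msg, "wb_validation_error", ...)
wb_unit_error       <- function(msg, ...) wb_abort(msg, "wb_unit_error", ...)
wb_parameter_error  <- function(msg, ...) wb_abort(msg, "wb_parameter_error", ...)
wb_degenerate_error <- function(msg, ...) wb_abort(msg, "wb_degenerate_error", ...)
wb_insufficient_data <- function(msg, ...) wb_abort(msg, "wb_insufficient_data", ...)
wb_fit_failure      <- function(msg, ...) wb_abort(msg, "wb_fit_failure", ...)
wb_generator_error  <- function(msg, ...) wb_abort(msg, "wb_generator_error", ...)

`%||%` <- function(a, b) if (is.null(a)) b else a
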