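# Classed conditions so callers (and tests) can branch on failure mode
# rather than on message text.
abort_lamotion <- function(message, class, ...) {
  rlang::abort(message, class = c(paste0("lamotion_", class), "lamotion_error"), ...)
}

stop_invalid_geometry <- function(msg, ...) abort_lamotion(msg, "invalid_geometry", ...)
stop_invalid_input <- function(msg, ...) abort_lamotion(msg, "invalid_input", ...)
stop_invalid_params <- function(msg, ...) abort_lamotion(msg, "invalid_params", ...)
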