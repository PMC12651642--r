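# Classed conditions so callers can distinguish failure modes programmatically.

thal_error <- function(class, message, ...) {
  stop(structure(
    class = c(class, "thal_error", "error", "condition"),
    list(message = message, call = sys.call(-1), ...)
  ))
}

thal_warn <- function(class, message, ...) {
  warning(structure(
    class = c(class, "thal_warning", "warning", "condition"),
    list(message = message, call = sys.call(-1), ...)
  ))
}
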