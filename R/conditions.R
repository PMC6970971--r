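# Classed conditions so callers (and the CLI) can distinguish schema errors
# from undefined-result conditions.

schema_error <- function(msg, ...) {
  stop(structure(
    class = c("caloscope_schema_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

undefined_result_error <- function(msg, ...) {
  stop(structure(
    class = c("caloscope_undefined_result", "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}
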