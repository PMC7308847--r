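# Classed conditions so callers (and the CLI) can distinguish data problems
# from usage errors without parsing messages.

abort_shadecor <- function(message, class, call = sys.call(-1)) {
  stop(structure(
    class = c(class, "shadecor_error", "error", "condition"),
    list(message = message, call = call)
  ))
}

abort_dimension <- function(message) {
  abort_shadecor(message, "shadecor_dimension_error")
}

abort_insufficient_stack <- function(message) {
  abort_shadecor(message, "shadecor_insufficient_stack_error")
}

abort_degenerate_field <- function(message) {
  abort_shadecor(message, "shadecor_degenerate_field_error")
}

abort_undefined_score <- function(message) {
  abort_shadecor(message, "shadecor_undefined_score_error")
}

abort_parameter <- function(message) {
  abort_shadecor(message, "shadecor_parameter_error")
}

abort_io <- function(message) {
  abort_shadecor(message, "shadecor_io_error")
}
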