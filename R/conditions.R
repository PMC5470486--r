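# Classed conditions so callers can distinguish bad input from a degenerate
# result (e.g. an empty image mask) without string-matching messages.

rs_abort <- function(message, class) {
  stop(structure(
    class = c(class, "rowsense_error", "error", "condition"),
    list(message = message, call = sys.call(-1))
  ))
}

rs_invalid <- function(message) rs_abort(message, "rowsense_invalid_input")
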