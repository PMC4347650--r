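# Classed conditions used across the package.  Every error raised by
# metabosearch carries the "metabosearch_error" class plus a specific
# subclass so callers (and the CLI) can react by kind.

ms_error <- function(message, class, call = sys.call(-1)) {
  stop(structure(
    class = c(class, "metabosearch_error", "error", "condition"),
    list(message = message, call = call)
  ))
}

ms_element_error    <- function(msg) ms_error(msg, "ms_element_error")
ms_parse_error      <- function(msg) ms_error(msg, "ms_parse_error")
ms_hypothesis_error <- function(msg) ms_error(msg, "ms_hypothesis_error")
ms_schema_error     <- function(msg) ms_error(msg, "ms_schema_error")
ms_dialect_error    <- function(msg) ms_error(msg, "ms_dialect_error")
ms_input_error      <- function(msg) ms_error(msg, "ms_input_error")
ms_empty_error      <- function(msg) ms_error(msg, "ms_empty_error")
ms_capability_error <- function(msg) ms_error(msg, "ms_capability_error")
ms_usage_error      <- function(msg) ms_error(msg, "ms_usage_error")
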