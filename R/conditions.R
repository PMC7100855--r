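# Classed conditions so callers (and the CLI) can map failures to exit codes.

ldassoc_error <- function(class, msg, ...) {
  stop(structure(
    class = c(class, "ldassoc_error", "error", "condition"),
    list(message = msg, call = sys.call(-1), ...)
  ))
}

usage_error  <- function(msg, ...) ldassoc_error("ldassoc_usage_error", msg, ...)
format_error <- function(msg, ...) ldassoc_error("ldassoc_format_error", msg, ...)
scope_error  <- function(msg, ...) ldassoc_error("ldassoc_scope_error", msg, ...)
io_error     <- function(msg, ...) ldassoc_error("ldassoc_io_error", msg, ...)
lookup_error <- function(msg, ...) ldassoc_error("ldassoc_lookup_error", msg, ...)
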