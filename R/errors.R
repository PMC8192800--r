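# Typed condition helpers: every validation failure raises a classed error so
# callers (and tests) can distinguish schema, parse, range and numeric faults.

vpp_error <- function(msg, class, ...) {
  stop(structure(
    class = c(class, "vpp_error", "error", "condition"),
    list(message = msg, call = sys.call(-1), ...)
  ))
}

vpp_schema_error     <- function(msg, ...) vpp_error(msg, "vpp_schema_error", ...)
vpp_parse_error      <- function(msg, ...) vpp_error(msg, "vpp_parse_error", ...)
vpp_validation_error <- function(msg, ...) vpp_error(msg, "vpp_validation_error", ...)
vpp_range_error      <- function(msg, ...) vpp_error(msg, "vpp_range_error", ...)
vpp_domain_error     <- function(msg, ...) vpp_error(msg, "vpp_domain_error", ...)
vpp_degenerate_error <- function(msg, ...) vpp_error(msg, "vpp_degenerate_error", ...)
vpp_io_error         <- function(msg, ...) vpp_error(msg, "vpp_io_error", ...)
vpp_precondition_error <- function(msg, ...) vpp_error(msg, "vpp_precondition_error", ...)
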