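# Typed conditions: every malformed input raises a classed error so callers
# (and the CLI) can distinguish schema problems from value problems.

tilStop <- function(msg, class, call = sys.call(-1)) {
  stop(errorCondition(msg, class = c(class, "til_error"), call = call))
}

tilSchemaStop     <- function(msg) tilStop(msg, "til_schema_error")
tilValidationStop <- function(msg) tilStop(msg, "til_validation_error")
tilParseStop      <- function(msg) tilStop(msg, "til_parse_error")
tilContractStop   <- function(msg) tilStop(msg, "til_contract_error")
tilIOStop         <- function(msg) tilStop(msg, "til_io_error")

assertScalarNumber <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    tilContractStop(sprintf("'%s' must be a single finite number", name))
  if (positive && x <= 0)
    tilContractStop(sprintf("'%s' must be > 0", name))
  invisible(x)
}
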