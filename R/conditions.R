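# Error taxonomy shared across the package: validation errors (bad inputs,
# broken invariants) vs parse errors (malformed files) vs I/O errors.
# The CLI maps these classes to exit codes.

stop_validation <- function(...) {
  stop(errorCondition(paste0(...), class = c("inc_validation_error", "error")))
}

stop_parse <- function(...) {
  stop(errorCondition(paste0(...),
                      class = c("inc_parse_error", "inc_validation_error", "error")))
}

stop_io <- function(...) {
  stop(errorCondition(paste0(...), class = c("inc_io_error", "error")))
}
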