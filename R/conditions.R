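# Condition helpers: validation errors (bad input, exit code 1 at the CLI)
# vs numerical failures (non-convergence etc., exit code 2).

stop_validation <- function(...) {
  stop(errorCondition(paste0(...),
                      class = c("alphadose_validation_error", "error")))
}

stop_numerical <- function(..., data = NULL) {
  stop(errorCondition(paste0(...), data = data,
                      class = c("alphadose_numerical_error", "error")))
}
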