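# Classed conditions so the CLI can map failures onto exit codes:
# frlf_usage_error -> 2 (bad parameters / flags), frlf_data_error -> 3 (bad data).

stop_usage <- function(...) {
  stop(errorCondition(paste0(...), class = c("frlf_usage_error", "frlf_error")))
}

stop_data <- function(...) {
  stop(errorCondition(paste0(...), class = c("frlf_data_error", "frlf_error")))
}
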