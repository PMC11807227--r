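# Structured conditions. Every domain failure signals a condition of class
# c("revent_<type>", "revent_error", ...) so callers (and the CLI) can react to
# the specific violation rather than matching message strings.

.reventStop <- function(type, msg, call. = FALSE) {
  stop(errorCondition(msg, class = c(paste0("revent_", type), "revent_error")))
}

.reventWarn <- function(type, msg) {
  warning(warningCondition(msg, class = c(paste0("revent_", type), "revent_warning")))
}
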