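# Classed conditions so callers can distinguish design errors from data errors.

stop_tdm <- function(class, message, call = sys.call(-1)) {
  stop(errorCondition(message, class = c(class, "tdm_error"), call = call))
}

warn_tdm <- function(class, message) {
  warning(warningCondition(message, class = c(class, "tdm_warning")))
}
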