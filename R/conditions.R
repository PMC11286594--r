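# Classed error conditions so callers (and tests) can dispatch on failure mode.

ga_stop <- function(class, msg, ...) {
  stop(errorCondition(sprintf(msg, ...), class = c(class, "graftaxis_error")))
}

ga_warn <- function(class, msg, ...) {
  warning(warningCondition(sprintf(msg, ...), class = c(class, "graftaxis_warning")))
}
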