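# Structured conditions: every error carries class kuscape_<what> so callers
# and tests can dispatch on the failure kind rather than on message text.

ks_abort <- function(class, msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c(paste0("kuscape_", class), "kuscape_error")))
}

ks_warn <- function(class, msg, ...) {
  warning(warningCondition(sprintf(msg, ...),
                           class = c(paste0("kuscape_", class), "kuscape_warning")))
}
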