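# Classed conditions so callers (and tests) can discriminate failure modes
# without matching message text.

pf_stop <- function(class, msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c(paste0("pitchfatigue_", class),
                                "pitchfatigue_error")))
}

pf_assert <- function(ok, class, msg, ...) {
  if (!isTRUE(ok)) pf_stop(class, msg, ...)
  invisible(TRUE)
}
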