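# Condition helpers. All user-input problems signal a condition inheriting
# "edl_error" so the CLI can map them to exit status 2; anything else is an
# internal error (exit 1).

edl_stop <- function(msg, class) {
  stop(structure(
    class = c(class, "edl_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

stop_validation <- function(msg) edl_stop(msg, "edl_validation_error")
stop_format     <- function(msg) edl_stop(msg, "edl_format_error")
stop_domain     <- function(msg) edl_stop(msg, "edl_domain_error")
stop_lookup     <- function(msg) edl_stop(msg, "edl_lookup_error")
stop_usage      <- function(msg) edl_stop(msg, "edl_usage_error")
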