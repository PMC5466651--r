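# Condition constructors. Every error raised by the package carries the class
# "knetdist_error" plus a specific subclass so callers (and the CLI) can map
# failures to exit codes without string matching.

pkd_error <- function(subclass, message, call = sys.call(-1), data = list()) {
  structure(
    class = c(subclass, "knetdist_error", "error", "condition"),
    c(list(message = message, call = call), data)
  )
}

stop_cycle <- function(msg) stop(pkd_error("pkd_cycle_error", msg))
stop_multiroot <- function(msg) stop(pkd_error("pkd_multiroot_error", msg))
stop_label <- function(msg) stop(pkd_error("pkd_label_error", msg))
stop_disconnected <- function(msg) stop(pkd_error("pkd_disconnected_error", msg))
stop_parse <- function(msg, pos = NA_integer_) {
  stop(pkd_error("pkd_parse_error",
                 if (is.na(pos)) msg else sprintf("%s (at position %d)", msg, pos),
                 data = list(position = pos)))
}
stop_size <- function(msg) stop(pkd_error("pkd_size_error", msg))
stop_generation <- function(msg) stop(pkd_error("pkd_generation_error", msg))
stop_fixture <- function(msg) stop(pkd_error("pkd_fixture_error", msg))
stop_usage <- function(msg) stop(pkd_error("pkd_usage_error", msg))
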