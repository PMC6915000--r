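# Structured conditions so callers (and the CLI) can map failures to exit codes.

stop_gaitsf <- function(class, msg, ...) {
  stop(structure(
    class = c(class, "gaitsf_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
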