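# Classed conditions so callers (and tests) can distinguish failure modes
# without parsing messages.

abort_isofv <- function(message, class, call = sys.call(-1)) {
  cond <- structure(
    class = c(class, "isofv_error", "error", "condition"),
    list(message = message, call = call)
  )
  stop(cond)
}

warn_isofv <- function(message, class) {
  cond <- structure(
    class = c(class, "isofv_warning", "warning", "condition"),
    list(message = message, call = NULL)
  )
  warning(cond)
}

`%||%` <- function(x, y) if (is.null(x)) y else x
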