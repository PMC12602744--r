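# Classed error conditions shared across the package. Every user-facing
# precondition failure signals one of these so callers (and the pipeline's
# missing-value policy) can branch on class rather than on message text.

vm_stop <- function(class, msg, call = sys.call(-1)) {
  stop(structure(
    class = c(class, "vm_error", "error", "condition"),
    list(message = msg, call = call)
  ))
}

vm_check <- function(ok, class, msg) {
  if (!isTRUE(ok)) vm_stop(class, msg, call = sys.call(-1))
  invisible(TRUE)
}
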