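# Structured error conditions used across the package. Every user-facing
# failure mode carries a condition class so callers (and the CLI) can react
# programmatically instead of matching message text.

cp_abort <- function(message, class, ...) {
  rlang::abort(message, class = c(paste0("chemprobe_", class), "chemprobe_error"), ...)
}

cp_warn <- function(message, class = "warning") {
  rlang::warn(message, class = c(paste0("chemprobe_", class), "chemprobe_warning"))
}

`%||%` <- rlang::`%||%`
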