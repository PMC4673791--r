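# Classed conditions so callers (and the CLI) can map failures to causes.
abort_param <- function(msg, ...) {
  abort(msg, class = "kmerules_param_error", ...)
}

abort_format <- function(msg, ...) {
  abort(msg, class = "kmerules_format_error", ...)
}

abort_validation <- function(msg, ...) {
  abort(msg, class = "kmerules_validation_error", ...)
}

abort_filter <- function(msg, ...) {
  abort(msg, class = "kmerules_filter_error", ...)
}
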