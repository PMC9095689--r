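# Internal condition helpers. Every user-facing failure carries a subclass of
# "soleusshape_error" so callers (and tests) can dispatch on the failure kind.

abort_io <- function(msg, ...) {
  rlang::abort(msg, class = c("soleusshape_error_io", "soleusshape_error"), ...)
}

abort_format <- function(msg, ...) {
  rlang::abort(msg, class = c("soleusshape_error_format", "soleusshape_error"), ...)
}

abort_dimension <- function(msg, ...) {
  rlang::abort(msg, class = c("soleusshape_error_dimension", "soleusshape_error"), ...)
}

abort_parameter <- function(msg, ...) {
  rlang::abort(msg, class = c("soleusshape_error_parameter", "soleusshape_error"), ...)
}

abort_degenerate <- function(msg, ...) {
  rlang::abort(msg, class = c("soleusshape_error_degenerate", "soleusshape_error"), ...)
}

abort_unsupported <- function(msg, ...) {
  rlang::abort(msg, class = c("soleusshape_error_unsupported", "soleusshape_error"), ...)
}

# Cross product of two 3-vectors.
cross3 <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}
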