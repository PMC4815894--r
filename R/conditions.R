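#' @keywords internal
"_PACKAGE"

# Structured error conditions. Every user-facing failure carries a condition
# class so callers (and the CLI) can map validation vs configuration vs
# degenerate-statistics failures to distinct exit codes.

fs_stop <- function(msg, class, call = sys.call(-1)) {
  stop(errorCondition(msg, class = c(class, "fusionstrat_error"),
                      call = call))
}

stop_validation <- function(msg, call = sys.call(-1)) {
  fs_stop(msg, "fusionstrat_validation_error", call)
}

stop_config <- function(msg, call = sys.call(-1)) {
  fs_stop(msg, "fusionstrat_config_error", call)
}

stop_degenerate <- function(msg, call = sys.call(-1)) {
  fs_stop(msg, "fusionstrat_degenerate_error", call)
}

assert_finite <- function(x, what) {
  if (!is.numeric(x) || anyNA(x) || any(!is.finite(x))) {
    stop_validation(sprintf("%s must be finite numeric values", what))
  }
  invisible(x)
}
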