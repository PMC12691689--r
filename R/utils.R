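# condition classes used across the package; every error carries a subclass of
# "alarmkin_error" so callers can trap pipeline failures selectively
abort_invalid <- function(msg) {
  abort(msg, class = c("alarmkin_invalid_parameter", "alarmkin_error"))
}

abort_missing_param <- function(msg) {
  abort(msg, class = c("alarmkin_missing_parameter", "alarmkin_error"))
}

abort_insufficient <- function(msg) {
  abort(msg, class = c("alarmkin_insufficient_data", "alarmkin_error"))
}

abort_fit <- function(msg) {
  abort(msg, class = c("alarmkin_fit_failure", "alarmkin_error"))
}

abort_design <- function(msg) {
  abort(msg, class = c("alarmkin_design_error", "alarmkin_error"))
}

abort_deconvolution <- function(msg, thetas = NULL) {
  abort(msg, class = c("alarmkin_deconvolution_error", "alarmkin_error"),
        thetas = thetas)
}

abort_undefined_ratio <- function(msg) {
  abort(msg, class = c("alarmkin_undefined_ratio", "alarmkin_error"))
}

# evaluate expr under a fixed RNG state when seed is given, untouched otherwise
with_seed_maybe <- function(seed, expr) {
  if (is.null(seed)) force(expr) else withr::with_seed(seed, expr)
}
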