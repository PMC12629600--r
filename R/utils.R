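#' Round half away from zero
#'
#' Plain commercial rounding: 62.5 rounds to 63, matching how cohort
#' percentages are conventionally reported. `base::round()` rounds half to
#' even (62.5 -> 62), which is not what demographic tables print.
#'
#' @param x numeric vector.
#' @param digits integer number of decimal places.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 0) {
  f <- 10^digits
  sign(x) * floor(abs(x) * f + 0.5) / f
}

# internal: stop with a classed condition so callers can distinguish
# configuration errors from input errors
cs_stop <- function(msg, class) {
  stop(structure(class = c(class, "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

cs_config_error <- function(msg) cs_stop(msg, "clonoscan_config_error")
cs_input_error  <- function(msg) cs_stop(msg, "clonoscan_input_error")

# internal: check a probability vector sums to one
check_prob <- function(p, what) {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1) ||
      abs(sum(p) - 1) > 1e-8) {
    cs_config_error(sprintf("'%s' must be probabilities in [0,1] summing to 1", what))
  }
  invisible(p)
}
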