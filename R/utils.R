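#' Round half away from zero
#'
#' Fixed-point rounding where ties go up (97.95 -> 98.0), as used for the
#' displayed degree-of-agreement percentages. Base \code{round()} rounds
#' half to even, which is unsuitable for reproducing reported percentages.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return numeric vector rounded to \code{digits} places.
#' @export
#' @examples
#' round_half_up(143 / 146 * 100, 1)  # 97.9
round_half_up <- function(x, digits = 1) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

# classed conditions so the CLI can map error types to exit codes
usage_error <- function(msg) {
  stop(structure(class = c("cosegscan_usage_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

data_error <- function(msg) {
  stop(structure(class = c("cosegscan_data_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
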