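#' Round half away from zero
#'
#' Commercial ("half-up") rounding, as used for all reported quantities:
#' nutrients to 1 decimal, absorbed iron to 2, footprints to 1, vehicle
#' kilometres to integers. Base `round()` rounds half to even, which would
#' disagree with published tables on exact .5 boundaries.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places (default 0).
#' @return `x` rounded half away from zero to `digits` decimals.
#' @examples
#' round_half_up(0.165, 2) # 0.17, where round() gives 0.16
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  # nudge by a few ulp so values that are conceptually exact halves but sit
  # just below .5 in binary (e.g. 1026.25 stored as ...249999) still round up
  sign(x) * floor(abs(x) * p + 0.5 + sqrt(.Machine$double.eps)) / p
}

stop_input <- function(msg, class) {
  abort(msg, class = c(class, "sustainaswap_error"))
}
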