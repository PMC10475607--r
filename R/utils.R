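#' Round half-up
#'
#' Commercial ("half-up") rounding: 0.5 always rounds away from zero, unlike
#' [base::round()]'s round-half-to-even. All reported rupee figures in this
#' package use half-up rounding at the report boundary; internal arithmetic is
#' never rounded.
#'
#' @param x numeric vector.
#' @param digits integer, number of decimal places (default 0).
#' @return numeric vector rounded half-up to `digits` places.
#' @examples
#' round_half_up(176.81)   # 177
#' round_half_up(190.43)   # 190
#' round_half_up(3.676, 2) # 3.68
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  # nudge by a few ulps so values that are exactly .5 in decimal but stored
  # fractionally below it in binary (e.g. 0.15-based sums) still round up
  z <- abs(x) * p
  z <- floor(z + 0.5 + sqrt(.Machine$double.eps))
  sign(x) * z / p
}

# money display rounding: 2 dp
round2 <- function(x) round_half_up(x, 2)

# parse money that may carry Indian digit grouping ("4,91,040") or plain commas
parse_money <- function(x) {
  out <- suppressWarnings(as.numeric(gsub(",", "", trimws(as.character(x)))))
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# scalar checks used across constructors
assert_scalar_num <- function(x, name, min = -Inf, max = Inf,
                              strict_min = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    stop(sprintf("`%s` must be a single non-missing number", name),
         call. = FALSE)
  }
  lo_ok <- if (strict_min) x > min else x >= min
  if (!lo_ok || x > max) {
    stop(sprintf("`%s` = %s is outside its allowed range", name,
                 format(x)), call. = FALSE)
  }
  invisible(x)
}
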