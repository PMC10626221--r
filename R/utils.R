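#' Round half away from zero
#'
#' Decimal rounding where ties go up (.5 rounds away from zero), the
#' convention used when rendering FISH percentages and ratios to one
#' decimal. Base \code{round()} uses round-half-even, which is kept for
#' integer copy-number calls but is wrong for report rendering.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @keywords internal
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' @keywords internal
`%||%` <- function(a, b) if (is.null(a)) b else a

#' Stop unless a condition holds, with a sprintf-style message
#' @keywords internal
assert_that <- function(cond, fmt, ...) {
  if (!isTRUE(cond)) stop(sprintf(fmt, ...), call. = FALSE)
  invisible(TRUE)
}

#' Package version string used in output stamps
#' @keywords internal
hc_version <- function() {
  as.character(utils::packageVersion("hemaclone"))
}
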