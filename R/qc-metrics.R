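#' Coefficient of variation of per-bin read counts
#'
#' Sample standard deviation (n-1 denominator) divided by the mean, the
#' standard bin-uniformity summary for shallow sequencing libraries.
#'
#' @param values per-bin counts (or densities); length >= 2, mean > 0.
#' @return CV, dimensionless.
#' @examples
#' coefficient_of_variation(c(90, 100, 110)) # 0.1
#' @export
coefficient_of_variation <- function(values) {
  assert_that(length(values) >= 2, "need at least 2 values")
  m <- mean(values)
  assert_that(m > 0, "mean must be positive")
  stats::sd(values) / m
}

#' Median absolute pairwise difference (MAPD)
#'
#' Adjacent-bin differences scaled by the overall mean,
#' \code{d_i = (x[i+1] - x[i]) / mean(x)}, summarized in one of two
#' ways:
#' \describe{
#'   \item{mad}{\code{median(|d - median(d)|)} -- the median absolute
#'     deviation of the scaled differences. Exactly 0 for any
#'     arithmetic progression (all d equal).}
#'   \item{median}{\code{median(|d|)} -- the field-standard noise
#'     metric. For an arithmetic progression this equals
#'     |step| / mean.}
#' }
#' Both definitions are scale invariant; a QC report carries both.
#'
#' @param values per-bin counts or copy-number ratios; length >= 3.
#' @param variant "mad" (default) or "median".
#' @return MAPD value, dimensionless.
#' @export
mapd <- function(values, variant = c("mad", "median")) {
  variant <- match.arg(variant)
  assert_that(length(values) >= 3, "need at least 3 values")
  m <- mean(values)
  assert_that(m != 0, "mean must be non-zero")
  d <- diff(values) / m
  if (variant == "mad") {
    stats::median(abs(d - stats::median(d)))
  } else {
    stats::median(abs(d))
  }
}

#' Bin-uniformity QC report
#'
#' Bundles the CV and both MAPD variants for a vector of per-bin counts
#' or copy-number ratios.
#'
#' @param values per-bin counts or ratios.
#' @param sample_id label.
#' @param space what the values are ("counts", "density", or
#'   "cn_ratio"); recorded only.
#' @return object of class \code{qc_report}.
#' @export
qc_report <- function(values, sample_id = "sample", space = "counts") {
  structure(list(
    sample = sample_id,
    n_bins = length(values),
    cv = coefficient_of_variation(values),
    mapd_mad = mapd(values, "mad"),
    mapd_median = mapd(values, "median"),
    settings = list(space = space)
  ), class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("qc_report '%s' (%d bins, %s): CV %.4f, MAPD %.4f (MAD form) / %.4f (median |d|)\n",
              x$sample, x$n_bins, x$settings$space,
              x$cv, x$mapd_mad, x$mapd_median))
  invisible(x)
}

#' Write a QC report as JSON
#' @param report a \code{qc_report}.
#' @param path output path.
#' @export
write_qc_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA)
  invisible(report)
}
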