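# Distributional summaries of mechanical characteristics: median,
# 25th-to-75th percentile confidence interval (PCI), and Gaussian-kernel
# density estimates. Quantiles use the linear-interpolation convention
# (stats::quantile type 7); the KDE bandwidth follows Silverman's
# rule of thumb (stats::bw.nrd0).

#' Median and 25th-75th percentile interval of a characteristic
#'
#' The percentile interval (PCI) is the preferred spread measure for the
#' skewed distributions that arise for the collagen parameters.
#'
#' @param values numeric vector (NAs dropped); must contain at least one
#'   finite value.
#' @return List with `median`, `pci_lo` (25th), `pci_hi` (75th), `n`.
#' @examples
#' median_pci(1:100)
#' @export
median_pci <- function(values) {
  values <- values[is.finite(values)]
  if (length(values) < 1) stop("no finite values")
  q <- stats::quantile(values, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  list(median = q[2], pci_lo = q[1], pci_hi = q[3], n = length(values))
}

#' Gaussian kernel density estimate of a characteristic's distribution
#'
#' Evaluates a Gaussian-kernel estimate on a 512-point grid spanning the
#' data plus three bandwidths on either side, with Silverman's
#' rule-of-thumb bandwidth by default.
#'
#' @param values numeric vector, at least two distinct values.
#' @param bandwidth optional numeric bandwidth override (standard deviation
#'   of the Gaussian kernel); Silverman's rule when `NULL`.
#' @return data.frame with columns `x` (abscissa) and `density`.
#' @export
kde <- function(values, bandwidth = NULL) {
  values <- values[is.finite(values)]
  if (length(values) < 2) stop("need at least two finite values")
  if (stats::sd(values) == 0) {
    stop("zero variance: distribution is a point mass, KDE undefined")
  }
  bw <- if (is.null(bandwidth)) stats::bw.nrd0(values) else bandwidth
  d <- stats::density(values, bw = bw, kernel = "gaussian", n = 512, cut = 3)
  data.frame(x = d$x, density = d$y)
}

#' Full distribution summary (quantiles + KDE)
#'
#' @inheritParams kde
#' @return List with the [median_pci()] fields plus `kde_grid`.
#' @export
distribution_summary <- function(values, bandwidth = NULL) {
  out <- median_pci(values)
  out$kde_grid <- kde(values, bandwidth)
  out
}
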