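#' Pearson correlation with a t-based p-value
#'
#' Sample Pearson correlation between two co-measured series (e.g.
#' densitometric quantifications of two proteins across cell lines or
#' tumors), with the two-sided p-value from
#' `t = r * sqrt((n - 2) / (1 - r^2))` on n - 2 degrees of freedom.
#'
#' @param x,y Numeric vectors of equal length >= 3; neither may be
#'   constant.
#' @return List with `r`, `p`, `t`, `df` and `n`. Perfect correlation
#'   (|r| = 1) yields p = 0.
#' @export
pearson_with_p <- function(x, y) {
  if (length(x) != length(y)) stop("`x` and `y` must have equal length")
  n <- length(x)
  if (n < 3L) stop("need at least 3 paired observations")
  if (!all(is.finite(x)) || !all(is.finite(y))) stop("inputs must be finite")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("correlation is undefined for a constant vector")
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  r <- max(-1, min(1, r))
  if (abs(r) == 1) {
    t_stat <- sign(r) * Inf
    p <- 0
  } else {
    t_stat <- r * sqrt((n - 2) / (1 - r^2))
    p <- 2 * stats::pt(-abs(t_stat), n - 2)
  }
  list(r = r, p = p, t = t_stat, df = n - 2, n = n)
}

#' Caliper tumor volume
#'
#' `V = L * W^2 / 2` in cubic millimeters, with the two caliper readings
#' reordered so the larger is the length (length is by definition the
#' larger reading, making the function symmetric and robust to
#' data-entry order). Vectorized.
#'
#' @param L,W Caliper readings in millimeters (non-negative).
#' @return Tumor volume(s) in cubic millimeters.
#' @export
tumor_volume <- function(L, W) {
  if (!is.numeric(L) || !is.numeric(W) || any(!is.finite(L)) || any(!is.finite(W)))
    stop("caliper readings must be finite numbers")
  if (any(L < 0) || any(W < 0)) stop("caliper readings must be non-negative")
  len <- pmax(L, W)
  wid <- pmin(L, W)
  len * wid^2 / 2
}

#' Percent-of-control normalization
#'
#' Expresses viability readouts (e.g. MTT metabolization) as a
#' percentage of the untreated-control mean: `100 * value / control`.
#'
#' @param values Numeric vector of measurements.
#' @param control_mean Positive scalar, the mean of the control wells.
#' @return Numeric vector of percentages.
#' @export
percent_of_control <- function(values, control_mean) {
  if (!is.numeric(control_mean) || length(control_mean) != 1L ||
      !is.finite(control_mean) || control_mean <= 0)
    stop("`control_mean` must be a single positive number")
  if (!is.numeric(values) || any(!is.finite(values)))
    stop("`values` must be finite numbers")
  100 * values / control_mean
}
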