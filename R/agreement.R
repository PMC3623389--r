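#' Bland-Altman agreement between two measurement methods
#'
#' Computes the mean bias and 95% limits of agreement for paired
#' measurements of the same quantity (here, point-of-care vs laboratory
#' reference hemoglobin). Differences are taken as `x - y`; the limits are
#' bias +/- 1.96 times the sample standard deviation of the differences
#' (n-1 denominator). 1.96 rather than 2.0 is used, matching the normal
#' 95% quantile convention.
#'
#' @param x,y paired numeric vectors of equal length >= 2 (g/dL for Hb);
#'   pairs with any missing value are an error, not silently dropped.
#' @return A list of class `agreement_report`: `n_pairs`, `bias`,
#'   `sd_diff`, `loa_low`, `loa_high`.
#' @examples
#' bland_altman(c(10, 12, 14), c(10, 11, 15))
#' @export
bland_altman <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have the same length")
  if (length(x) < 2) stop("at least 2 pairs are required")
  if (any(is.na(x)) || any(is.na(y))) stop("pairs must be complete")
  d <- x - y
  bias <- mean(d)
  s <- stats::sd(d)
  structure(
    list(n_pairs = length(d), bias = bias, sd_diff = s,
         loa_low = bias - 1.96 * s, loa_high = bias + 1.96 * s),
    class = "agreement_report")
}

#' @export
print.agreement_report <- function(x, ...) {
  cat(sprintf("Bland-Altman agreement (n = %d pairs)\n", x$n_pairs))
  cat(sprintf("  bias: %+.3f   limits of agreement: [%+.3f, %+.3f]\n",
              x$bias, x$loa_low, x$loa_high))
  invisible(x)
}

#' Cronbach's alpha for a two-item scale
#'
#' Reliability of two parallel measurements, in the covariance form
#' `alpha = 2 * (1 - (var(x) + var(y)) / var(x + y))` with sample (n-1)
#' variances. This equals the general k-item formula at k = 2; the
#' standardized form `2 r / (1 + r)` with `r` the Pearson correlation is
#' equivalent when the two items have equal variance.
#'
#' @param x,y paired numeric vectors, equal length >= 2.
#' @return Alpha (at most 1; can be negative). `NA` when the total score
#'   has zero variance (reliability undefined).
#' @examples
#' cronbach_alpha(1:4, 1:4) # 1
#' @export
cronbach_alpha <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have the same length")
  if (any(is.na(x)) || any(is.na(y))) stop("pairs must be complete")
  vt <- stats::var(x + y)
  if (vt == 0) return(NA_real_)
  2 * (1 - (stats::var(x) + stats::var(y)) / vt)
}

#' Pearson product-moment correlation
#'
#' Thin, argument-checked wrapper around [stats::cor()] used for the
#' method-reliability report; undefined (error) when either vector has zero
#' variance.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return Correlation coefficient in \[-1, 1\].
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have the same length")
  if (length(x) < 3) stop("at least 3 pairs are required")
  if (any(is.na(x)) || any(is.na(y))) stop("pairs must be complete")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("correlation undefined: zero variance")
  }
  stats::cor(x, y)
}

#' Full method-agreement report for paired Hb measurements
#'
#' Bundles [bland_altman()], [pearson_r()] and [cronbach_alpha()] for one
#' pair of measurement series.
#'
#' @param x,y paired numeric vectors (e.g. reference and POCT Hb, g/dL).
#' @return A list of class `agreement_report` with the Bland-Altman fields
#'   plus `pearson_r` and `cronbach_alpha`.
#' @export
agreement_report <- function(x, y) {
  rep <- bland_altman(x, y)
  rep$pearson_r <- pearson_r(x, y)
  rep$cronbach_alpha <- cronbach_alpha(x, y)
  rep
}

#' Bland-Altman plot
#'
#' Difference (`x - y`) against pair mean, with the bias as a solid line
#' and the limits of agreement as dashed lines.
#'
#' @inheritParams bland_altman
#' @return A ggplot object.
#' @export
plot_bland_altman <- function(x, y) {
  rep <- bland_altman(x, y)
  df <- data.frame(m = (x + y) / 2, d = x - y)
  ggplot2::ggplot(df, ggplot2::aes(x = m, y = d)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_hline(yintercept = rep$bias, linewidth = 0.7) +
    ggplot2::geom_hline(yintercept = c(rep$loa_low, rep$loa_high),
                        linetype = "dashed") +
    ggplot2::labs(x = "Mean of paired measurements (g/dL)",
                  y = "Difference (g/dL)",
                  title = sprintf("Bland-Altman: bias %+.2f, LoA [%+.2f, %+.2f]",
                                  rep$bias, rep$loa_low, rep$loa_high)) +
    ggplot2::theme_minimal()
}
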