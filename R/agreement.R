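#' Absolute percent error of a device reading
#'
#' `|device - reference| / reference * 100`, the per-trial accuracy measure
#' every summary starts from. The reference is the criterion (ECG-derived)
#' value, assumed strictly positive for HR and rMSSD.
#'
#' @param device_value,reference_value Numeric vectors, same units.
#' @return Percent error, same length as the inputs.
#' @examples
#' absolute_percent_error(110, 100)  # 10
#' @export
absolute_percent_error <- function(device_value, reference_value) {
  if (any(!is.finite(reference_value)) || any(reference_value <= 0)) {
    stop("reference values must be finite and positive", call. = FALSE)
  }
  abs(device_value - reference_value) / reference_value * 100
}

#' Flag extreme outliers by the Tukey outer fence
#'
#' A value is "extreme" when it lies more than `k` times the interquartile
#' range above the third quartile or below the first quartile (the Tukey
#' outer fence at the default `k = 3`). Applied per device/metric group to
#' APE values, once, before all downstream statistics; removal accounts for
#' procedural errors rather than genuine device behaviour. Quartiles use
#' linear interpolation between order statistics (R's type 7) by default;
#' fence membership can flip near boundaries under other conventions, so
#' the type is a knob.
#'
#' @param x Numeric vector (typically APE values for one device/metric).
#' @param k Fence multiplier; 3 is the outer fence, 1.5 the inner.
#' @param quartile_type Quantile algorithm type passed to
#'   [stats::quantile()].
#' @return Logical vector, `TRUE` where the value is an extreme outlier.
#'   With fewer than 4 values no fences are computed (warning, all `FALSE`).
#' @examples
#' tukey_extreme_outliers(c(1, 2, 3, 4, 5, 100))  # flags only 100
#' @export
tukey_extreme_outliers <- function(x, k = 3, quartile_type = 7) {
  if (length(x) < 4) {
    warning("fewer than 4 values; quartiles not meaningful, nothing flagged")
    return(rep(FALSE, length(x)))
  }
  q <- stats::quantile(x, c(0.25, 0.75), type = quartile_type, names = FALSE)
  iqr <- q[2] - q[1]
  x < q[1] - k * iqr | x > q[2] + k * iqr
}

#' Summary statistics of absolute percent errors
#'
#' The per-device/metric executive summary: sample size after outlier
#' removal, mean APE (MAPE), minimum, median, maximum and IQR, all in
#' percent.
#'
#' @param ape Numeric vector of APE values, after outlier removal.
#' @param quartile_type Quantile type used for the IQR (kept consistent
#'   with [tukey_extreme_outliers()]).
#' @return One-row tibble: `n`, `mape_pct`, `min_pct`, `median_pct`,
#'   `max_pct`, `iqr_pct`.
#' @export
ape_summary <- function(ape, quartile_type = 7) {
  if (length(ape) == 0) stop("no APE values to summarize", call. = FALSE)
  q <- stats::quantile(ape, c(0.25, 0.75), type = quartile_type,
                       names = FALSE)
  tibble::tibble(
    n = length(ape),
    mape_pct = mean(ape),
    min_pct = min(ape),
    median_pct = stats::median(ape),
    max_pct = max(ape),
    iqr_pct = q[2] - q[1]
  )
}

#' Lin's concordance correlation coefficient
#'
#' Measures agreement of paired measurements with the identity line:
#' `CCC = 2 s_xy / (s_x^2 + s_y^2 + (mean(x) - mean(y))^2)` with
#' population (1/n) moments, Lin's 1989 sample version. Ranges over
#' \[-1, 1\], equals 1 only for identical pairs, and never exceeds the
#' Pearson correlation in magnitude (the bias-correction factor is at most
#' 1).
#'
#' @param device_values,reference_values Paired numeric vectors, `n >= 2`,
#'   neither constant.
#' @return One-row tibble: `n`, `ccc`.
#' @examples
#' lin_ccc(c(1, 2, 3), c(2, 4, 6))$ccc  # 8/22
#' @export
lin_ccc <- function(device_values, reference_values) {
  x <- device_values
  y <- reference_values
  n <- length(x)
  stopifnot(length(y) == n)
  if (n < 2) stop("CCC needs at least 2 pairs", call. = FALSE)
  if (stats::var(x) == 0 || stats::var(y) == 0) {
    stop("CCC is undefined for constant inputs", call. = FALSE)
  }
  sx2 <- mean((x - mean(x))^2)
  sy2 <- mean((y - mean(y))^2)
  sxy <- mean((x - mean(x)) * (y - mean(y)))
  tibble::tibble(n = n, ccc = 2 * sxy / (sx2 + sy2 + (mean(x) - mean(y))^2))
}

#' Bland-Altman limits of agreement
#'
#' Differences are taken as `device - reference`, so a positive bias means
#' the device overestimates the criterion. Bias is the mean difference;
#' the limits of agreement (LOA) are `bias +/- 1.96 SD` with the sample
#' (n-1) SD; the 95% CI of the bias uses the t quantile times `SD/sqrt(n)`,
#' and of each LOA the t quantile times `SD * sqrt(3/n)` -- the classic
#' Bland-Altman 1986 recipe.
#'
#' @param device_values,reference_values Paired numeric vectors, `n >= 3`.
#' @param loa_multiplier LOA half-width in SD units (1.96 = 95% normal
#'   coverage).
#' @param conf_level Confidence level for the CIs.
#' @return One-row tibble: `n`, `bias`, `bias_lo`, `bias_hi`, `lower_loa`,
#'   `lower_loa_lo`, `lower_loa_hi`, `upper_loa`, `upper_loa_lo`,
#'   `upper_loa_hi`, `loa_range`, `sd_diff`.
#' @export
bland_altman <- function(device_values, reference_values,
                         loa_multiplier = 1.96, conf_level = 0.95) {
  d <- device_values - reference_values
  n <- length(d)
  if (n < 3) stop("Bland-Altman needs at least 3 pairs", call. = FALSE)
  bias <- mean(d)
  s <- stats::sd(d)
  tq <- stats::qt(1 - (1 - conf_level) / 2, df = n - 1)
  se_bias <- s / sqrt(n)
  se_loa <- s * sqrt(3 / n)
  lower <- bias - loa_multiplier * s
  upper <- bias + loa_multiplier * s
  tibble::tibble(
    n = n,
    bias = bias, bias_lo = bias - tq * se_bias, bias_hi = bias + tq * se_bias,
    lower_loa = lower, lower_loa_lo = lower - tq * se_loa,
    lower_loa_hi = lower + tq * se_loa,
    upper_loa = upper, upper_loa_lo = upper - tq * se_loa,
    upper_loa_hi = upper + tq * se_loa,
    loa_range = upper - lower,
    sd_diff = s
  )
}

#' Bonferroni-corrected paired bias test
#'
#' Two-sided one-sample t test of whether the mean paired difference is
#' zero, with the p-value multiplied by the number of device comparisons in
#' the family (Bonferroni, capped at 1). Significance at adjusted p < 0.05
#' flags a device with systematic over- or underestimation.
#'
#' @param differences Numeric vector of paired differences
#'   (device - reference).
#' @param n_comparisons Bonferroni family size (number of devices compared
#'   for the metric).
#' @return One-row tibble: `n`, `t`, `p`, `p_adj`, `significant`.
#' @export
paired_bias_test <- function(differences, n_comparisons = 1) {
  d <- differences
  if (length(d) < 2) stop("paired test needs at least 2 differences",
                          call. = FALSE)
  if (stats::sd(d) == 0) {
    stop("paired test is degenerate when all differences are equal",
         call. = FALSE)
  }
  tt <- stats::t.test(d, mu = 0)
  p_adj <- min(1, n_comparisons * tt$p.value)
  tibble::tibble(
    n = length(d),
    t = unname(tt$statistic),
    p = tt$p.value,
    p_adj = p_adj,
    significant = p_adj < 0.05
  )
}
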