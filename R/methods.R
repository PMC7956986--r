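#' Tidy an agreement report into one long table
#'
#' One row per device, metric and statistic, ready for filtering and
#' plotting.
#'
#' @param x An `agreement_report`.
#' @param ... Unused.
#' @return A tibble with columns `metric`, `device_label`, `statistic`,
#'   `value`.
#' @export
tidy.agreement_report <- function(x, ...) {
  long <- function(df, keep) {
    tidyr::pivot_longer(df[, c("metric", "device_label", keep)],
                        dplyr::all_of(keep),
                        names_to = "statistic", values_to = "value")
  }
  dplyr::bind_rows(
    long(x$ape, c("n", "mape_pct", "min_pct", "median_pct", "max_pct",
                  "iqr_pct")),
    long(x$ba, c("bias", "lower_loa", "upper_loa", "loa_range", "p_adj")),
    long(x$ccc, "ccc")
  ) |>
    dplyr::arrange(.data$metric, .data$device_label)
}

#' One-row summary of an agreement report
#'
#' @inheritParams tidy.agreement_report
#' @return A one-row tibble: pair counts, outliers removed, devices, and
#'   how many devices show significant bias per the adjusted tests.
#' @export
glance.agreement_report <- function(x, ...) {
  tibble::tibble(
    n_pairs = nrow(x$pairs),
    n_outliers = sum(x$pairs$outlier),
    n_devices = length(unique(x$pairs$device_label)),
    n_significant_bias = sum(x$ba$significant, na.rm = TRUE),
    n_group_errors = length(x$errors)
  )
}

#' Bland-Altman panel plot of an agreement report
#'
#' One panel per device for the chosen metric: paired means against
#' differences, with the bias line and the limits of agreement. Outliers
#' removed by the Tukey fence are drawn hollow.
#'
#' @param object An `agreement_report`.
#' @param metric `"rMSSD"` (default) or `"HR"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.agreement_report <- function(object, metric = "rMSSD", ...) {
  p <- object$pairs[object$pairs$metric == metric, ]
  p$mean_val <- (p$device_value + p$reference_value) / 2
  p$diff_val <- p$device_value - p$reference_value
  b <- object$ba[object$ba$metric == metric, ]
  units <- if (metric == "HR") "bpm" else "ms"
  ggplot2::ggplot(p, ggplot2::aes(.data$mean_val, .data$diff_val)) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey70") +
    ggplot2::geom_hline(data = b, ggplot2::aes(yintercept = .data$bias),
                        colour = "steelblue") +
    ggplot2::geom_hline(data = b, ggplot2::aes(yintercept = .data$lower_loa),
                        linetype = "dashed", colour = "steelblue") +
    ggplot2::geom_hline(data = b, ggplot2::aes(yintercept = .data$upper_loa),
                        linetype = "dashed", colour = "steelblue") +
    ggplot2::geom_point(ggplot2::aes(shape = .data$outlier), size = 1.5) +
    ggplot2::scale_shape_manual(values = c(`FALSE` = 16, `TRUE` = 1),
                                guide = "none") +
    ggplot2::facet_wrap(~device_label, scales = "free") +
    ggplot2::labs(
      x = paste0("Mean of device and reference (", units, ")"),
      y = paste0("Device - reference (", units, ")"),
      title = paste("Bland-Altman:", metric)
    ) +
    ggplot2::theme_minimal()
}

#' Ordered APE box plot
#'
#' Box plots of per-trial absolute percent error by device, ordered by
#' MAPE, the conventional at-a-glance comparison of device accuracy.
#'
#' @param report An `agreement_report`.
#' @param metric `"HR"` or `"rMSSD"`.
#' @param include_outliers Show Tukey-flagged values (hollow points)?
#' @return A ggplot object.
#' @export
plot_ape_box <- function(report, metric = "HR", include_outliers = FALSE) {
  p <- report$pairs[report$pairs$metric == metric, ]
  if (!include_outliers) p <- p[!p$outlier, ]
  ord <- report$ape$device_label[report$ape$metric == metric]
  p$device_label <- factor(p$device_label, levels = ord)
  ggplot2::ggplot(p, ggplot2::aes(.data$device_label, .data$ape_pct)) +
    ggplot2::geom_boxplot(outlier.size = 0.8) +
    ggplot2::labs(x = NULL, y = "Absolute percent error (%)",
                  title = paste("APE by device:", metric)) +
    ggplot2::theme_minimal()
}
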