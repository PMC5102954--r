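#' Heatmap of the overall inter-metric co-variance
#'
#' @param object An [overall_covariance()] result.
#' @param ... Unused.
#' @return A ggplot object: mean Fisher-Z per metric pair, metrics ordered as
#'   configured.
#' @method autoplot overall_covariance
#' @export
autoplot.overall_covariance <- function(object, ...) {
  tb <- tidy(object) |>
    dplyr::bind_rows(tidy(object) |>
                       dplyr::rename(metric_i = "metric_j",
                                     metric_j = "metric_i"))
  tb$metric_i <- factor(tb$metric_i, levels = object$metrics)
  tb$metric_j <- factor(tb$metric_j, levels = rev(object$metrics))
  ggplot2::ggplot(tb, ggplot2::aes(.data$metric_i, .data$metric_j,
                                   fill = .data$mean_z)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "#2166ac", mid = "white",
                                  high = "#b2182b", midpoint = 0,
                                  name = "mean Z") +
    ggplot2::labs(x = NULL, y = NULL,
                  title = "Overall inter-metric co-variance") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' Observed ICCs against the permutation null
#'
#' @param object A `validation_report`.
#' @param ... Unused.
#' @return A ggplot object: null ICC histogram with the fair threshold, the
#'   percentile cut and each unit's observed ICC.
#' @method autoplot validation_report
#' @export
autoplot.validation_report <- function(object, ...) {
  null_tb <- tibble::tibble(icc = object$null_icc)
  ggplot2::ggplot(null_tb, ggplot2::aes(.data$icc)) +
    ggplot2::geom_histogram(bins = 60, fill = "grey70") +
    ggplot2::geom_vline(xintercept = object$fair_threshold,
                        linetype = "dashed") +
    ggplot2::geom_vline(xintercept = object$percentile_cut,
                        colour = "#b2182b") +
    ggplot2::geom_rug(data = object$units,
                      ggplot2::aes(.data$icc, colour = .data$label),
                      inherit.aes = FALSE, linewidth = 1) +
    ggplot2::labs(x = "ICC", y = "null count",
                  title = "Unit reproducibility vs permutation null",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Heatmap of one unit's inter-metric co-variance matrix
#'
#' @param mmcu A unit element of an `mmcu_set`.
#' @return A ggplot object.
#' @export
plot_mmcu_covariance <- function(mmcu) {
  cv <- mmcu$covariance
  tb <- tibble::as_tibble(as.table(cv), .name_repair = "minimal")
  names(tb) <- c("metric_i", "metric_j", "r")
  tb$metric_i <- factor(tb$metric_i, levels = rownames(cv))
  tb$metric_j <- factor(tb$metric_j, levels = rev(rownames(cv)))
  ggplot2::ggplot(tb, ggplot2::aes(.data$metric_i, .data$metric_j,
                                   fill = .data$r)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "#2166ac", mid = "white",
                                  high = "#b2182b", midpoint = 0,
                                  limits = c(-1, 1)) +
    ggplot2::labs(x = NULL, y = NULL,
                  title = paste0("Unit ", mmcu$unit_id,
                                 " inter-metric co-variance")) +
    ggplot2::theme_minimal()
}
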