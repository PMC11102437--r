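#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot the eigenvalue spectrum of a decomposition
#'
#' Frequency against per-second rate for every dynamic mode, point size
#' proportional to the mode amplitude `|b_k|`; the dashed line at rate 1
#' separates growing from decaying modes.
#'
#' @param object A `dmd` object.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.dmd <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(.data$frequency, .data$rate)) +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed", colour = "grey50") +
    ggplot2::geom_point(ggplot2::aes(size = .data$amplitude), alpha = 0.8) +
    ggplot2::scale_size_continuous(range = c(1, 5)) +
    ggplot2::labs(
      x = "frequency (Hz)", y = "rate (amplitude multiplier / s)",
      size = "|b|", title = "Dynamic mode spectrum"
    ) +
    ggplot2::theme_minimal()
}

sdm_heat <- function(m, title, fill_lab) {
  d <- tidyr::pivot_longer(
    dplyr::mutate(tibble::as_tibble(m, rownames = "row"),
      row = factor(.data$row, levels = rev(rownames(m)))
    ),
    -"row",
    names_to = "col", values_to = "value"
  )
  d$col <- factor(d$col, levels = colnames(m))
  ggplot2::ggplot(d, ggplot2::aes(.data$col, .data$row, fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = NULL, y = NULL, fill = fill_lab, title = title) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5))
}

#' Heatmap of an sDM feature matrix
#'
#' @param object An [sdm_features()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.sdm_feature <- function(object, ...) {
  title <- if (is.null(object$band)) {
    "sDM features"
  } else {
    sprintf("sDM features (%s)", object$band)
  }
  sdm_heat(object$matrix, title, "value")
}

#' Heatmap of a projection-kernel Gram matrix
#'
#' @param object A [gram_matrix()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.gram_matrix <- function(object, ...) {
  sdm_heat(object$values, "Projection-kernel Gram matrix", "k_p")
}

#' Per-channel PSD plot
#'
#' @param object A [psd_features()] result.
#' @param ... Unused.
#' @return A ggplot (log10 power against frequency, one line per channel).
#' @export
autoplot.power_feature <- function(object, ...) {
  d <- tibble::as_tibble(t(object$psd), .name_repair = "minimal")
  names(d) <- object$channel_ids
  d$frequency <- object$frequencies
  d <- tidyr::pivot_longer(d, -"frequency",
    names_to = "channel",
    values_to = "power"
  )
  ggplot2::ggplot(
    d,
    ggplot2::aes(.data$frequency, .data$power, colour = .data$channel)
  ) +
    ggplot2::geom_line(show.legend = FALSE) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(
      x = "frequency (Hz)", y = "power spectral density",
      title = "Single-window PSD"
    ) +
    ggplot2::theme_minimal()
}

#' Distribution of per-fold decoding scores
#'
#' @param object A `decoding_result`.
#' @param ... Unused.
#' @return A ggplot of fold scores by repeat with the mean highlighted.
#' @export
autoplot.decoding_result <- function(object, ...) {
  d <- object$scores
  ggplot2::ggplot(
    d, ggplot2::aes(factor(.data$repeat_), .data$score)
  ) +
    ggplot2::geom_boxplot(outlier.shape = NA, fill = "grey90") +
    ggplot2::geom_jitter(width = 0.12, alpha = 0.6) +
    ggplot2::geom_hline(
      yintercept = object$mean_score,
      colour = "firebrick", linetype = "dashed"
    ) +
    ggplot2::labs(
      x = "outer repeat", y = object$metric,
      title = sprintf("%s decoding (mean = %.3f)", object$model, object$mean_score)
    ) +
    ggplot2::theme_minimal()
}
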