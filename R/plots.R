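#' Plot an Az curve
#'
#' Discriminator performance across window centres, with the chance level
#' (0.5) and, if a [permutation_threshold()] result is supplied, the
#' permutation significance line and shading of significant intervals.
#'
#' @param object A `sliding_decode` object.
#' @param null Optional `permutation_null`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.sliding_decode <- function(object, null = NULL, ...) {
  df <- object$az
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$window_ms, y = .data$az)) +
    ggplot2::geom_hline(yintercept = 0.5, linetype = "dotted",
                        colour = "grey50") +
    ggplot2::geom_line(colour = "#2166AC") +
    ggplot2::labs(x = "window centre (ms, cue-locked)",
                  y = expression(A[z] ~ "(leave-one-out)")) +
    ggplot2::theme_minimal()
  if (!is.null(null)) {
    thr <- if (null$pooling == "pooled") null$threshold else {
      mean(null$threshold)
    }
    si <- significant_intervals(object, null)
    if (nrow(si)) {
      p <- p + ggplot2::geom_rect(
        data = si, inherit.aes = FALSE,
        ggplot2::aes(xmin = .data$start_ms, xmax = .data$end_ms,
                     ymin = -Inf, ymax = Inf),
        fill = "grey80", alpha = 0.4)
    }
    p <- p + ggplot2::geom_hline(yintercept = thr, linetype = "dashed",
                                 colour = "#B2182B")
  }
  p
}

#' Plot a group Az-curve comparison
#'
#' Per-timepoint t statistic with the cluster-forming threshold and
#' significant clusters shaded.
#'
#' @param object An `az_comparison` object.
#' @param alpha Shade clusters with `p` below this value (default 0.05).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.az_comparison <- function(object, alpha = 0.05, ...) {
  sig <- object$clusters[object$clusters$p < alpha, , drop = FALSE]
  p <- ggplot2::ggplot(object$t,
                       ggplot2::aes(x = .data$window_ms, y = .data$t)) +
    ggplot2::geom_hline(yintercept = object$crit, linetype = "dashed",
                        colour = "#B2182B") +
    ggplot2::geom_line() +
    ggplot2::labs(x = "window centre (ms, cue-locked)",
                  y = "t (group difference)") +
    ggplot2::theme_minimal()
  if (nrow(sig)) {
    p <- p + ggplot2::geom_rect(
      data = sig, inherit.aes = FALSE,
      ggplot2::aes(xmin = .data$start_ms, xmax = .data$end_ms,
                   ymin = -Inf, ymax = Inf),
      fill = "grey80", alpha = 0.4)
  }
  p
}

#' Plot a permutation null distribution
#'
#' Histogram of the null Az draws with the significance threshold.
#'
#' @param object A `permutation_null` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.permutation_null <- function(object, ...) {
  thr <- if (object$pooling == "pooled") object$threshold else {
    mean(object$threshold)
  }
  ggplot2::ggplot(tidy(object), ggplot2::aes(x = .data$az)) +
    ggplot2::geom_histogram(bins = 40, fill = "grey70", colour = "white") +
    ggplot2::geom_vline(xintercept = thr, linetype = "dashed",
                        colour = "#B2182B") +
    ggplot2::labs(x = expression("null" ~ A[z]), y = "draws") +
    ggplot2::theme_minimal()
}
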