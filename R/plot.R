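#' Plot a fixation curve against the Moran baseline
#'
#' @param object a `fixation_curve`.
#' @param baseline draw the Moran-process curve for the same `N` and `i`.
#' @param ... unused.
#' @return a ggplot object: fixation probability versus fitness on a log-x
#'   axis, with confidence ribbons for simulated curves and the neutral point
#'   `(1, i/N)` marked.
#' @importFrom ggplot2 autoplot
#' @export
autoplot.fixation_curve <- function(object, baseline = TRUE, ...) {
  N <- attr(object, "N"); i <- attr(object, "i")
  df <- tibble::as_tibble(object)
  df$which <- attr(object, "target") %||% "curve"
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$r, y = .data$x))
  if (baseline && !is.null(N)) {
    bl <- tibble::tibble(r = sort(unique(c(df$r, exp(seq(log(min(df$r)), log(max(df$r)), length.out = 101))))))
    bl$x <- moran_fixation(N, bl$r, i)
    p <- p + ggplot2::geom_line(
      data = bl, ggplot2::aes(x = .data$r, y = .data$x),
      linetype = "dashed", colour = "grey40"
    )
  }
  if ("ci_low" %in% names(df)) {
    p <- p + ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$ci_low, ymax = .data$ci_high),
      alpha = 0.2, fill = "steelblue"
    )
  }
  p <- p +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::geom_point(size = 0.9, colour = "steelblue") +
    ggplot2::annotate("point", x = 1, y = i / N, shape = 4, size = 2) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(
      x = "relative fitness r",
      y = sprintf("fixation probability x_%d", i),
      title = sprintf("%s, model %s, N = %s",
                      attr(object, "target") %||% "fixation curve",
                      attr(object, "model"), N),
      subtitle = "dashed: Moran baseline; cross: neutral anchor i/N"
    ) +
    ggplot2::theme_minimal()
  p
}

#' Plot the per-point evidence behind a selection verdict
#'
#' @param object a `selection_verdict`.
#' @param ... unused.
#' @return a ggplot of `x(r) - x_Moran(r)` versus `r`, coloured by sign.
#' @export
autoplot.selection_verdict <- function(object, ...) {
  ev <- object$evidence
  ev$sign <- factor(ev$sign, levels = c(-1, 0, 1),
                    labels = c("below Moran", "tied", "above Moran"))
  ggplot2::ggplot(ev, ggplot2::aes(x = .data$r, y = .data$delta, colour = .data$sign)) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey60") +
    ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "relative fitness r", y = "x(r) - Moran baseline",
                  title = paste("verdict:", object$classification)) +
    ggplot2::theme_minimal()
}

#' @export
plot.fixation_curve <- function(x, ...) print(autoplot(x, ...))

#' @export
plot.selection_verdict <- function(x, ...) print(autoplot(x, ...))
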