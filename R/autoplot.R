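# ggplot2 convenience views for interactive use; publication output goes
# through the SVG renderer, which owns the editability guarantees.

#' Quick ggplot2 view of Kaplan-Meier curves
#'
#' An interactive companion to the SVG renderer: draws the step curves with
#' ggplot2 for use at the console or in reports. Legend statistics, captions
#' and the hand-editability contract are features of
#' [render_survival_plot()], not of this view.
#'
#' @param object A `km_curve`, a list of them, or an `experiment_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot km_curve
#' @export
autoplot.km_curve <- function(object, ...) {
  autoplot_km_list(list(object))
}

#' @rdname autoplot.km_curve
#' @method autoplot experiment_result
#' @export
autoplot.experiment_result <- function(object, ...) {
  colors <- resolve_colors(object$legend$condition, object$table$colors)
  labels <- setNames(object$legend$text, object$legend$condition)
  autoplot_km_list(object$curves, colors = colors, labels = labels) +
    ggplot2::labs(title = object$title, caption = object$caption)
}

autoplot_km_list <- function(curves, colors = NULL, labels = NULL) {
  steps <- purrr::map_dfr(curves, function(cv) {
    tibble::tibble(
      condition = attr(cv, "condition"),
      time = c(0, cv$time, attr(cv, "max_time")),
      survival = c(1, cv$survival, if (nrow(cv) > 0) cv$survival[nrow(cv)] else 1)
    )
  })
  conds <- unique(steps$condition)
  colors <- colors %||% resolve_colors(conds)
  steps$condition <- factor(steps$condition, levels = conds)
  p <- ggplot2::ggplot(steps,
                       ggplot2::aes(.data$time, 100 * .data$survival,
                                    color = .data$condition)) +
    ggplot2::geom_step(linewidth = 0.8) +
    ggplot2::scale_color_manual(values = colors,
                                labels = labels %||% ggplot2::waiver()) +
    ggplot2::labs(x = "Time (days)", y = "Survival (%)", color = NULL) +
    ggplot2::coord_cartesian(ylim = c(0, 100)) +
    ggplot2::theme_classic()
  p
}
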