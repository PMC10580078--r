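#' Plot specification for survival plots
#'
#' Collects the presentation choices for an SVG survival plot: title, x-axis
#' limits, per-condition colors, canvas size and caption metadata. Conditions
#' without an explicit color are assigned from a fixed colorblind-safe
#' palette (Okabe-Ito) in plotting order, control first, so colors are
#' deterministic and stable between the all-conditions plot and any
#' single-comparison subplots.
#'
#' @param title Plot title.
#' @param x_min,x_max X-axis limits in days, or `NULL` for automatic
#'   (0 to the latest observed time).
#' @param colors Named character vector `condition -> color`, or `NULL`.
#' @param width_px,height_px Canvas size in pixels.
#' @param temperature_c,researchers Caption metadata (see [build_caption()]).
#' @param output_path Where the SVG should be written, or `NULL`.
#' @return An object of class `plot_spec`.
#' @export
plot_spec <- function(title = "lifespan", x_min = NULL, x_max = NULL,
                      colors = NULL, width_px = 800, height_px = 600,
                      temperature_c = NULL, researchers = NULL,
                      output_path = NULL) {
  if (!is.null(x_min) && !is.null(x_max) && x_min >= x_max) {
    ws_error("x_min must be smaller than x_max", "wormspan_argument_error")
  }
  stopifnot(width_px > 0, height_px > 0)
  structure(
    list(
      title = as.character(title),
      x_min = x_min, x_max = x_max,
      colors = colors,
      width_px = width_px, height_px = height_px,
      temperature_c = temperature_c, researchers = researchers,
      output_path = output_path
    ),
    class = "plot_spec"
  )
}

# Okabe-Ito colorblind-safe cycle; control gets the first (black)
default_palette <- function() {
  c("#000000", "#E69F00", "#56B4E9", "#009E73",
    "#F0E442", "#0072B2", "#D55E00", "#CC79A7")
}

#' Resolve one color per condition
#'
#' Explicit entries in `colors` win; remaining conditions take the default
#' palette in order (cycling if there are more than eight conditions).
#'
#' @param conditions Character vector of condition labels in plotting order.
#' @param colors Optional named character vector of explicit colors.
#' @return Named character vector, one color per condition.
#' @export
resolve_colors <- function(conditions, colors = NULL) {
  pal <- default_palette()
  out <- setNames(rep(NA_character_, length(conditions)), conditions)
  if (!is.null(colors)) {
    known <- intersect(names(colors), conditions)
    out[known] <- unname(colors[known])
  }
  free <- which(is.na(out))
  out[free] <- pal[((seq_along(free) - 1) %% length(pal)) + 1]
  out
}

xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  x <- gsub(">", "&gt;", x, fixed = TRUE)
  gsub("\"", "&quot;", x, fixed = TRUE)
}

# stable id fragment from a condition label
svg_id_fragment <- function(label) {
  frag <- gsub("[^A-Za-z0-9._-]+", "_", label)
  if (frag == "" || grepl("^[^A-Za-z]", frag)) frag <- paste0("c_", frag)
  frag
}

num <- function(x) sprintf("%.2f", x)

#' Render survival curves to an editable SVG document
#'
#' Draws Kaplan-Meier step functions (right-continuous: horizontal segment to
#' each death time, then a vertical drop), a y axis in percent survival, an x
#' axis in days, the title, a legend and a caption. The document is built so
#' a vector editor can manipulate it element by element: every condition is a
#' single `<path>` carrying `id="curve-<condition>"` and a `data-condition`
#' attribute, every legend entry is its own `<text>` element (italic gene
#' names become `font-style="italic"` tspans), and the title and caption are
#' distinct `<text>` elements. Output is deterministic: identical inputs give
#' byte-identical markup.
#'
#' @param curves Named list of [km_estimate()] curves (names = condition
#'   labels), control first by convention.
#' @param legend Tibble from [build_legend()] covering the same conditions.
#' @param spec A [plot_spec()].
#' @return An object of class `svg_document` (a single character string of
#'   SVG 1.1 markup).
#' @export
render_survival_plot <- function(curves, legend, spec = plot_spec()) {
  if (inherits(curves, "km_curve")) curves <- list(curves)
  if (length(curves) == 0) {
    ws_error("render_survival_plot() needs at least one curve",
             "wormspan_argument_error")
  }
  conds <- vapply(curves, function(cv) attr(cv, "condition"), character(1))
  names(curves) <- conds
  if (!setequal(conds, legend$condition)) {
    ws_error("legend and curves must cover the same set of conditions",
             "wormspan_argument_error")
  }
  # legend order (control first) drives drawing and palette order
  conds <- legend$condition
  colors <- resolve_colors(conds, spec$colors)

  w <- spec$width_px
  h <- spec$height_px
  # plot area with ~10% margins; extra room at bottom for caption
  px0 <- 0.10 * w
  px1 <- 0.95 * w
  py0 <- 0.10 * h   # top
  py1 <- 0.82 * h   # bottom (x axis)

  max_obs <- max(vapply(curves, function(cv) attr(cv, "max_time"), numeric(1)))
  x_min <- spec$x_min %||% 0
  x_max <- spec$x_max %||% max(max_obs, x_min + 1)
  if (x_min >= x_max) {
    ws_error("x_min must be smaller than x_max", "wormspan_argument_error")
  }
  xpix <- function(d) px0 + (d - x_min) / (x_max - x_min) * (px1 - px0)
  ypix <- function(s) py1 - s * (py1 - py0)

  out <- c(
    "<?xml version=\"1.0\" encoding=\"UTF-8\"?>",
    sprintf(paste0(
      "<svg xmlns=\"http://www.w3.org/2000/svg\" version=\"1.1\" ",
      "width=\"%d\" height=\"%d\" viewBox=\"0 0 %d %d\" ",
      "font-family=\"sans-serif\">"), w, h, w, h),
    sprintf("<title>%s</title>", xml_escape(spec$title)),
    sprintf("<rect id=\"background\" x=\"0\" y=\"0\" width=\"%d\" height=\"%d\" fill=\"white\"/>", w, h),
    sprintf(
      "<text id=\"plot-title\" x=\"%s\" y=\"%s\" text-anchor=\"middle\" font-size=\"20\">%s</text>",
      num((px0 + px1) / 2), num(0.06 * h), xml_escape(spec$title))
  )

  # axes
  axis <- c(
    sprintf("<g id=\"axes\" stroke=\"black\" stroke-width=\"1\">"),
    sprintf("<line x1=\"%s\" y1=\"%s\" x2=\"%s\" y2=\"%s\"/>",
            num(px0), num(py1), num(px1), num(py1)),
    sprintf("<line x1=\"%s\" y1=\"%s\" x2=\"%s\" y2=\"%s\"/>",
            num(px0), num(py0), num(px0), num(py1))
  )
  xticks <- pretty(c(x_min, x_max), n = 6)
  xticks <- xticks[xticks >= x_min & xticks <= x_max]
  labels <- character()
  for (tk in xticks) {
    axis <- c(axis, sprintf("<line x1=\"%s\" y1=\"%s\" x2=\"%s\" y2=\"%s\"/>",
                            num(xpix(tk)), num(py1), num(xpix(tk)), num(py1 + 5)))
    labels <- c(labels, sprintf(
      "<text x=\"%s\" y=\"%s\" text-anchor=\"middle\" font-size=\"12\">%g</text>",
      num(xpix(tk)), num(py1 + 20), tk))
  }
  for (sv in seq(0, 1, by = 0.25)) {
    axis <- c(axis, sprintf("<line x1=\"%s\" y1=\"%s\" x2=\"%s\" y2=\"%s\"/>",
                            num(px0 - 5), num(ypix(sv)), num(px0), num(ypix(sv))))
    labels <- c(labels, sprintf(
      "<text x=\"%s\" y=\"%s\" text-anchor=\"end\" font-size=\"12\">%g</text>",
      num(px0 - 9), num(ypix(sv) + 4), 100 * sv))
  }
  axis <- c(axis, "</g>")
  labels <- c(
    labels,
    sprintf("<text id=\"x-axis-label\" x=\"%s\" y=\"%s\" text-anchor=\"middle\" font-size=\"14\">Time (days)</text>",
            num((px0 + px1) / 2), num(py1 + 42)),
    sprintf(paste0(
      "<text id=\"y-axis-label\" x=\"%s\" y=\"%s\" text-anchor=\"middle\" ",
      "font-size=\"14\" transform=\"rotate(-90 %s %s)\">Survival (%%)</text>"),
      num(px0 - 45), num((py0 + py1) / 2), num(px0 - 45), num((py0 + py1) / 2))
  )
  out <- c(out, axis, labels)

  # one step path per condition, clipped to [x_min, x_max]
  for (k in seq_along(conds)) {
    cond <- conds[k]
    cv <- curves[[cond]]
    end_day <- min(max(attr(cv, "max_time"), x_min), x_max)
    last_day <- x_min
    d <- paste0("M", num(xpix(x_min)), " ", num(ypix(1)))
    for (i in seq_len(nrow(cv))) {
      ti <- cv$time[i]
      if (ti < x_min) next
      if (ti > x_max) break
      d <- paste0(d, " H", num(xpix(ti)), " V", num(ypix(cv$survival[i])))
      last_day <- ti
    }
    if (end_day > last_day) d <- paste0(d, " H", num(xpix(end_day)))
    out <- c(out, sprintf(
      "<path id=\"curve-%s\" data-condition=\"%s\" d=\"%s\" fill=\"none\" stroke=\"%s\" stroke-width=\"2\"/>",
      svg_id_fragment(cond), xml_escape(cond), d, colors[[cond]]))
  }

  # legend: swatch + one text element per entry, top-right inside plot area
  lx <- px0 + 0.55 * (px1 - px0)
  ly <- py0 + 14
  leg <- sprintf("<g id=\"legend\" font-size=\"13\">")
  for (k in seq_len(nrow(legend))) {
    cond <- legend$condition[k]
    y <- ly + (k - 1) * 18
    leg <- c(leg, sprintf(
      "<line x1=\"%s\" y1=\"%s\" x2=\"%s\" y2=\"%s\" stroke=\"%s\" stroke-width=\"2\"/>",
      num(lx), num(y - 4), num(lx + 24), num(y - 4), colors[[cond]]))
    rich <- legend$label[[k]]
    spans <- paste0(vapply(seq_len(nrow(rich)), function(i) {
      style <- if (rich$style[i] == "italic") " font-style=\"italic\"" else ""
      sprintf("<tspan%s>%s</tspan>", style, xml_escape(rich$text[i]))
    }, character(1)), collapse = "")
    leg <- c(leg, sprintf(
      "<text id=\"legend-%s\" x=\"%s\" y=\"%s\" xml:space=\"preserve\">%s<tspan>%s</tspan></text>",
      svg_id_fragment(cond), num(lx + 30), num(y), spans,
      xml_escape(legend$suffix[k])))
  }
  leg <- c(leg, "</g>")
  out <- c(out, leg)

  caption <- build_caption(spec$temperature_c, spec$researchers)
  out <- c(out, sprintf(
    "<text id=\"caption\" x=\"%s\" y=\"%s\" font-size=\"12\" fill=\"#444444\">%s</text>",
    num(px0), num(0.93 * h), xml_escape(caption)),
    "</svg>")

  structure(paste(out, collapse = "\n"), class = "svg_document")
}

#' Render a control-vs-one-condition comparison plot
#'
#' Subplot for a condition whose lifespan differs significantly from the
#' control: the same rendering rules as [render_survival_plot()], restricted
#' to the control curve and one condition curve. The condition keeps exactly
#' the color it has in the all-conditions plot (pass the full plotting order
#' via `all_conditions` so palette assignment is unchanged).
#'
#' @param control_curve,condition_curve [km_estimate()] curves.
#' @param legend Legend tibble covering at least these two conditions.
#' @param spec A [plot_spec()].
#' @param all_conditions Plotting order of the full experiment, used to pin
#'   palette colors; defaults to the two plotted conditions.
#' @return An `svg_document`.
#' @export
render_single_comparison <- function(control_curve, condition_curve, legend,
                                     spec = plot_spec(),
                                     all_conditions = NULL) {
  pair <- c(attr(control_curve, "condition"), attr(condition_curve, "condition"))
  if (!is.null(all_conditions)) {
    full <- resolve_colors(all_conditions, spec$colors)
    spec$colors <- full
  }
  legend <- legend[legend$condition %in% pair, , drop = FALSE]
  render_survival_plot(list(control_curve, condition_curve), legend, spec)
}

#' @export
print.svg_document <- function(x, ...) {
  cat("<svg_document> ", nchar(x), " bytes\n", sep = "")
  invisible(x)
}

#' Write an SVG document to disk
#'
#' @param doc An `svg_document`.
#' @param path Output path (conventionally `<experiment>.svg`).
#' @return `path`, invisibly.
#' @export
write_svg <- function(doc, path) {
  stopifnot(inherits(doc, "svg_document"))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(unclass(doc), con, sep = "\n", useBytes = TRUE)
  invisible(path)
}
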