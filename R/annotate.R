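# Standalone C. elegans gene token: 3-4 lowercase letters, hyphen, digits,
# optional isoform suffix (e.g. daf-2, rsks-1, ceh-20.1). Lowercase
# hyphen-number drug codes can false-positive; documented limitation.
GENE_PATTERN <- "\\b[a-z]{3,4}-[0-9]+(\\.[0-9]+)?\\b"

#' Mark C. elegans gene names for italicization
#'
#' Scans a condition label for tokens matching the C. elegans gene
#' nomenclature (three or four lowercase letters, a hyphen, digits, optional
#' `.n` isoform suffix, as a whole word) and splits the label into styled
#' segments. Concatenating the segment texts always reproduces the input
#' exactly, so no characters are lost.
#'
#' @param label A single character string.
#' @return A tibble of class `rich_label` with columns `text` and `style`
#'   (`"plain"` or `"italic"`), in display order.
#' @export
#' @examples
#' italicize_gene_names("daf-2 RNAi")
#' italicize_gene_names("eat-2(ad1116); rsks-1")
italicize_gene_names <- function(label) {
  stopifnot(is.character(label), length(label) == 1)
  if (is.na(label) || nchar(label) == 0) {
    return(structure(tibble::tibble(text = character(), style = character()),
                     class = c("rich_label", "tbl_df", "tbl", "data.frame")))
  }
  loc <- stringr::str_locate_all(label, GENE_PATTERN)[[1]]
  segments <- list()
  pos <- 1L
  if (nrow(loc) > 0) {
    for (k in seq_len(nrow(loc))) {
      if (loc[k, "start"] > pos) {
        segments[[length(segments) + 1]] <-
          list(text = substr(label, pos, loc[k, "start"] - 1L), style = "plain")
      }
      segments[[length(segments) + 1]] <-
        list(text = substr(label, loc[k, "start"], loc[k, "end"]), style = "italic")
      pos <- loc[k, "end"] + 1L
    }
  }
  if (pos <= nchar(label)) {
    segments[[length(segments) + 1]] <-
      list(text = substr(label, pos, nchar(label)), style = "plain")
  }
  out <- tibble::tibble(
    text = vapply(segments, `[[`, character(1), "text"),
    style = vapply(segments, `[[`, character(1), "style")
  )
  structure(out, class = c("rich_label", class(tibble::tibble())))
}

#' @export
print.rich_label <- function(x, ...) {
  rendered <- ifelse(x$style == "italic", paste0("/", x$text, "/"), x$text)
  cat("<rich_label> ", paste(rendered, collapse = ""), "\n", sep = "")
  invisible(x)
}

#' Asterisk annotation for a p-value
#'
#' `"***"` for p < 0.001, `"**"` for p < 0.01, `"*"` for p < 0.05
#' (strict inequalities), `""` otherwise. Vectorized.
#'
#' @param p Numeric p-values in (0, 1].
#' @return Character vector of star strings.
#' @export
#' @examples
#' significance_stars(c(0.04, 0.005, 0.0005, 0.05))
significance_stars <- function(p) {
  if (length(p) == 0) return(character())
  if (any(is.na(p)) || any(p <= 0 | p > 1)) {
    ws_error("p-values must lie in (0, 1]", "wormspan_argument_error")
  }
  dplyr::case_when(
    p < 0.001 ~ "***",
    p < 0.01 ~ "**",
    p < 0.05 ~ "*",
    TRUE ~ ""
  )
}

# p to 3 significant digits; '<0.001' below that
# (element-wise: vectorized format() would pad all entries to a common width)
format_pvalue <- function(p) {
  vapply(p, function(x) {
    if (is.na(x)) return(NA_character_)
    if (x < 0.001) return("<0.001")
    format(signif(x, 3), scientific = FALSE, trim = TRUE)
  }, character(1))
}

#' Build legend entries from per-condition reports
#'
#' Assembles the legend text shown on survival plots: the condition label
#' (with gene names italicized), its mean lifespan and n, and -- for
#' non-control conditions -- the p-value against the control with its star
#' annotation. The control is listed first and shows mean and n only.
#'
#' @param reports A data frame with columns `condition`, `mean_lifespan`,
#'   `n`, and `p_value` (`NA` for the control), e.g. the `reports` element of
#'   an [autoplot_lifespan()] result.
#' @param control Label of the control condition (must be present).
#' @return A tibble with columns `condition`, `label` (list of `rich_label`),
#'   `text` (full legend line), `suffix` (the parenthesized stats part),
#'   `is_control`, `mean_lifespan`, `n`, `p_value`, `stars`; control row
#'   first.
#' @export
build_legend <- function(reports, control) {
  reports <- tibble::as_tibble(reports)
  if (!control %in% reports$condition) {
    ws_error(sprintf("control '%s' not among the reported conditions", control),
             "wormspan_argument_error")
  }
  ord <- c(which(reports$condition == control),
           which(reports$condition != control))
  reports <- reports[ord, ]
  is_control <- reports$condition == control
  stars <- rep("", nrow(reports))
  has_p <- !is_control & !is.na(reports$p_value)
  if (any(has_p)) stars[has_p] <- significance_stars(reports$p_value[has_p])
  mean_part <- ifelse(is.na(reports$mean_lifespan), "",
                      sprintf("mean %s d, ", format_days(reports$mean_lifespan)))
  p_part <- ifelse(is_control | is.na(reports$p_value), "",
                   sprintf(", p=%s%s", format_pvalue(reports$p_value), stars))
  suffix <- sprintf(" (%sn=%d%s)", mean_part, as.integer(reports$n), p_part)
  tibble::tibble(
    condition = reports$condition,
    label = lapply(reports$condition, italicize_gene_names),
    text = paste0(reports$condition, suffix),
    suffix = suffix,
    is_control = is_control,
    mean_lifespan = reports$mean_lifespan,
    n = as.integer(reports$n),
    p_value = reports$p_value,
    stars = stars
  )
}

# one-decimal day formatting for legends ("14.0", "24.5")
format_days <- function(x) sprintf("%.1f", x)

#' Build the plot caption
#'
#' The caption explains the asterisk annotations and credits the assay
#' metadata: temperature (when recorded) and the initials of the researchers
#' who scored the lifespan (when recorded). Absent fields leave no
#' placeholder text.
#'
#' @param temperature_c Assay temperature in degrees Celsius, or `NULL`.
#' @param researchers Character vector of initials, or `NULL`.
#' @return A single caption string.
#' @export
#' @examples
#' build_caption(temperature_c = 20, researchers = c("BLM", "JP"))
build_caption <- function(temperature_c = NULL, researchers = NULL) {
  parts <- "* p<0.05, ** p<0.01, *** p<0.001 vs control"
  if (!is.null(temperature_c) && length(temperature_c) == 1 && !is.na(temperature_c)) {
    parts <- c(parts, sprintf("%g\u00b0C", temperature_c))
  }
  if (!is.null(researchers) && length(researchers) > 0) {
    parts <- c(parts, paste0("Scored by: ", paste(researchers, collapse = ", ")))
  }
  paste(parts, collapse = ". ")
}
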