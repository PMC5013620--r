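LINE_STYLES <- c(solid = 1L, dashed = 2L, dotted = 3L, dashdot = 4L)

# matplotlib-style integer legend location codes
LEGEND_CODES <- c("0" = "bottomright",  # "best": ROC curves hug the top left
                  "1" = "topright", "2" = "topleft", "3" = "bottomleft",
                  "4" = "bottomright", "5" = "right", "6" = "left",
                  "7" = "right", "8" = "bottom", "9" = "top", "10" = "center")

# CSS/matplotlib color names absent from grDevices::colors()
EXTRA_COLORS <- c(teal = "#008080", olive = "#808000", lime = "#00FF00",
                  silver = "#C0C0C0", fuchsia = "#FF00FF", aqua = "#00FFFF",
                  crimson = "#DC143C", indigo = "#4B0082")

#' Resolve a color token
#'
#' Accepts any base R color name, a `#RRGGBB`/`#RRGGBBAA` hex string, or a
#' handful of common CSS names (e.g. `"teal"`) that base R lacks; anything
#' else is an error naming the offending token.
#'
#' @param x color token.
#' @return A color string usable by the graphics device.
#' @keywords internal
resolve_color <- function(x) {
  if (x %in% grDevices::colors() ||
      grepl("^#[0-9A-Fa-f]{6}([0-9A-Fa-f]{2})?$", x))
    return(x)
  if (tolower(x) %in% names(EXTRA_COLORS))
    return(unname(EXTRA_COLORS[[tolower(x)]]))
  stop("unknown color: ", x, call. = FALSE)
}

#' Style for one plotted ROC curve
#'
#' @param label legend label for the curve.
#' @param color named R color or hex string (`"#RRGGBB"`).
#' @param line_style one of `"solid"`, `"dashed"`, `"dotted"`, `"dashdot"`.
#' @param line_width positive line width.
#' @return A `curve_style` list; every field has a default so a bare curve
#'   renders.
#' @export
curve_style <- function(label = "ROC", color = "black",
                        line_style = c("solid", "dashed", "dotted", "dashdot"),
                        line_width = 2) {
  line_style <- match.arg(line_style)
  color <- resolve_color(color)
  stopifnot(line_width > 0)
  structure(list(label = label, color = color, line_style = line_style,
                 line_width = line_width),
            class = "curve_style")
}

#' Declarative description of one ROC figure
#'
#' Collects everything needed to render a figure: the curves with their
#' styles, the axis mode (linear, or semi-logarithmic when `x_log_min` is
#' given), geometry, typography and the output path. [render_figure()]
#' consumes this object; nothing is drawn until then, so metrics-only runs
#' never touch the graphics subsystem.
#'
#' @param curves list of `roc_curve` objects, or a single `roc_curve`.
#' @param styles list of [curve_style()] objects, recycled defaults if `NULL`.
#' @param x_log_min if non-`NULL`, a value in (0, 1): the x axis is drawn
#'   logarithmically starting at this false-positive rate, and plotted FPR
#'   values below it are clipped up to it so every curve reaches the left
#'   edge of the panel.
#' @param size_inches numeric length-2, figure width and height in inches.
#' @param dpi raster resolution; pixel size is `size_inches * dpi`.
#' @param axis_labels character length-2: x then y axis title.
#' @param axis_label_size,tick_label_size,legend_font_size font sizes in
#'   points.
#' @param legend_location `"best"` or an integer location code
#'   (0 best, 1 upper right, 2 upper left, 3 lower left, 4 lower right,
#'   5-7 right/left, 8 lower center, 9 upper center, 10 center).
#' @param legend_frame draw a box around the legend?
#' @param axis_line_width line width of the axes and panel box.
#' @param font_family font family name (empty = device default).
#' @param show_random_line draw the random-selection reference, the
#'   identity line y = x in data coordinates (a curve in log mode).
#' @param random_label legend label for the random line.
#' @param suppress_origin_labels drop the `0.0` tick labels at both axes'
#'   origins (annotations can re-add text anywhere, including at negative
#'   offsets outside the panel).
#' @param annotations list of annotations, each a list with elements `x`,
#'   `y`, `text` and optional `font_size`.
#' @param output_path image file to write; format inferred from the
#'   extension (`png` baseline; `jpg`/`jpeg`, `tiff`, `bmp`, `pdf` also
#'   accepted).
#' @return A `figure_spec` list.
#' @export
figure_spec <- function(curves, styles = NULL, x_log_min = NULL,
                        size_inches = c(8, 6), dpi = 100,
                        axis_labels = c("False positive rate",
                                        "True positive rate"),
                        axis_label_size = 12, tick_label_size = 10,
                        legend_location = "best", legend_font_size = 10,
                        legend_frame = TRUE, axis_line_width = 1,
                        font_family = "", show_random_line = TRUE,
                        random_label = "random",
                        suppress_origin_labels = FALSE, annotations = list(),
                        output_path = "roc.png") {
  if (inherits(curves, "roc_curve")) curves <- list(curves)
  if (length(curves) == 0L) stop("'curves' must be non-empty", call. = FALSE)
  if (!all(vapply(curves, inherits, logical(1), "roc_curve")))
    stop("'curves' must be roc_curve objects", call. = FALSE)
  if (!is.null(x_log_min) &&
      (!is.numeric(x_log_min) || x_log_min <= 0 || x_log_min >= 1))
    stop("'x_log_min' must lie in (0, 1)", call. = FALSE)
  stopifnot(length(size_inches) == 2L, all(size_inches > 0), dpi > 0)

  default_cols <- c("black", "red2", "blue2", "green4", "darkorange2",
                    "purple3", "deepskyblue3", "magenta3")
  if (is.null(styles)) {
    styles <- lapply(seq_along(curves), function(i)
      curve_style(label = paste0("data", i),
                  color = default_cols[(i - 1L) %% length(default_cols) + 1L]))
  }
  if (inherits(styles, "curve_style")) styles <- list(styles)
  if (length(styles) != length(curves))
    stop("need one style per curve", call. = FALSE)

  structure(list(curves = curves, styles = styles, x_log_min = x_log_min,
                 size_inches = as.numeric(size_inches), dpi = as.integer(dpi),
                 axis_labels = axis_labels,
                 axis_label_size = axis_label_size,
                 tick_label_size = tick_label_size,
                 legend_location = legend_location,
                 legend_font_size = legend_font_size,
                 legend_frame = legend_frame,
                 axis_line_width = axis_line_width,
                 font_family = font_family,
                 show_random_line = show_random_line,
                 random_label = random_label,
                 suppress_origin_labels = suppress_origin_labels,
                 annotations = annotations,
                 output_path = output_path),
            class = "figure_spec")
}

open_device <- function(path, width, height, dpi) {
  ext <- tolower(tools::file_ext(path))
  px_w <- round(width * dpi)
  px_h <- round(height * dpi)
  switch(ext,
    png = grDevices::png(path, width = px_w, height = px_h, res = dpi),
    jpg = ,
    jpeg = grDevices::jpeg(path, width = px_w, height = px_h, res = dpi),
    tiff = ,
    tif = grDevices::tiff(path, width = px_w, height = px_h, res = dpi),
    bmp = grDevices::bmp(path, width = px_w, height = px_h, res = dpi),
    pdf = grDevices::pdf(path, width = width, height = height),
    stop("unsupported image format: .", ext, call. = FALSE))
}

#' Render a ROC figure to an image file
#'
#' Draws every curve of a [figure_spec()] in input order, the
#' random-selection identity line last, the legend (curve labels in order,
#' random last), any annotations, and writes the image. Raster output has
#' pixel dimensions `size_inches * dpi`. In semi-logarithmic mode every
#' plotted false-positive rate below `x_log_min` is clipped up to
#' `x_log_min`, so curves start at the left panel edge instead of running
#' to minus infinity. Rendering is deterministic: the same spec yields an
#' image of identical dimensions and content.
#'
#' @param spec a [figure_spec()].
#' @return The output path, invisibly.
#' @examples
#' d <- label_by_pattern(data.frame(name = c("ACT1", "ACT2", "DEC1", "DEC2"),
#'                                  score = c(4, 3, 2, 1)), "ACT")
#' path <- file.path(tempdir(), "roc.png")
#' render_figure(figure_spec(roc_curve(d), size_inches = c(5, 5),
#'                           output_path = path))
#' @export
render_figure <- function(spec) {
  stopifnot(inherits(spec, "figure_spec"))
  for (st in spec$styles) resolve_color(st$color)
  out_dir <- dirname(spec$output_path)
  if (!dir.exists(out_dir))
    stop("output directory does not exist: ", out_dir, call. = FALSE)

  log_mode <- !is.null(spec$x_log_min)
  xlim <- if (log_mode) c(spec$x_log_min, 1) else c(0, 1)

  open_device(spec$output_path, spec$size_inches[1], spec$size_inches[2],
              spec$dpi)
  on.exit(grDevices::dev.off(), add = TRUE)

  op <- graphics::par(mar = c(4.5, 4.5, 1.5, 1.5), ps = 12)
  on.exit(graphics::par(op), add = TRUE)
  if (nzchar(spec$font_family)) graphics::par(family = spec$font_family)

  graphics::plot.new()
  graphics::plot.window(xlim = xlim, ylim = c(0, 1),
                        log = if (log_mode) "x" else "",
                        xaxs = "i", yaxs = "i")

  # axes with optional origin-label suppression
  draw_axis <- function(side, at) {
    labels <- format(at, drop0trailing = FALSE)
    if (spec$suppress_origin_labels) {
      origin <- if (side == 1) xlim[1] else 0
      labels[at == origin] <- ""
    }
    graphics::axis(side, at = at, labels = labels,
                   cex.axis = spec$tick_label_size / 12,
                   lwd = spec$axis_line_width,
                   lwd.ticks = spec$axis_line_width)
  }
  x_at <- if (log_mode) 10^seq(floor(log10(spec$x_log_min)), 0) else
    graphics::axTicks(1)
  draw_axis(1, x_at)
  draw_axis(2, graphics::axTicks(2))
  graphics::box(lwd = spec$axis_line_width)
  graphics::title(xlab = spec$axis_labels[1], ylab = spec$axis_labels[2],
                  cex.lab = spec$axis_label_size / 12)

  clip_x <- function(v) if (log_mode) pmax(v, spec$x_log_min) else v
  for (i in seq_along(spec$curves)) {
    cur <- spec$curves[[i]]
    st <- spec$styles[[i]]
    graphics::lines(clip_x(cur$fpr), cur$tpr, col = st$color,
                    lty = LINE_STYLES[[st$line_style]],
                    lwd = st$line_width)
  }

  if (spec$show_random_line) {
    # identity line y = x in data coordinates; a curve on a log axis
    rx <- if (log_mode)
      10^seq(log10(spec$x_log_min), 0, length.out = 200) else c(0, 1)
    graphics::lines(rx, rx, col = "grey35", lty = LINE_STYLES[["dashed"]],
                    lwd = 1)
  }

  labels <- vapply(spec$styles, `[[`, character(1), "label")
  cols <- vapply(spec$styles, `[[`, character(1), "color")
  ltys <- LINE_STYLES[vapply(spec$styles, `[[`, character(1), "line_style")]
  lwds <- vapply(spec$styles, `[[`, numeric(1), "line_width")
  if (spec$show_random_line) {
    labels <- c(labels, spec$random_label)
    cols <- c(cols, "grey35")
    ltys <- c(ltys, LINE_STYLES[["dashed"]])
    lwds <- c(lwds, 1)
  }
  loc <- spec$legend_location
  loc <- if (identical(loc, "best")) LEGEND_CODES[["0"]]
         else if (as.character(loc) %in% names(LEGEND_CODES))
           LEGEND_CODES[[as.character(loc)]]
         else as.character(loc)
  graphics::legend(loc, legend = labels, col = cols, lty = unname(ltys),
                   lwd = lwds, cex = spec$legend_font_size / 12,
                   bty = if (spec$legend_frame) "o" else "n")

  for (a in spec$annotations) {
    sz <- if (is.null(a$font_size)) 12 else a$font_size
    graphics::text(a$x, a$y, a$text, cex = sz / 12, xpd = NA)
  }

  invisible(spec$output_path)
}

#' Parse renderer keyword passthrough
#'
#' A restricted `component:{key:value, ...}` grammar for tweaking named
#' figure components, e.g. `"legend:{frameon:False}"` turns the legend
#' frame off. Recognised components/keys: `legend:frameon` (logical).
#' Unknown components or keys produce a warning and are ignored rather
#' than failing the run.
#'
#' @param text the keyword string.
#' @return Named list of figure_spec overrides (possibly empty).
#' @export
parse_renderer_keywords <- function(text) {
  overrides <- list()
  m <- regmatches(text, gregexpr("([A-Za-z_]+)\\s*:\\s*\\{([^}]*)\\}", text))[[1]]
  if (length(m) == 0L && nzchar(trimws(text))) {
    warning("unparseable renderer keyword spec: ", text, call. = FALSE)
    return(overrides)
  }
  for (piece in m) {
    comp <- sub("\\s*:\\s*\\{.*$", "", piece)
    body <- sub("^[^{]*\\{", "", sub("\\}$", "", piece))
    kvs <- strsplit(body, ",")[[1]]
    for (kv in kvs) {
      parts <- strsplit(trimws(kv), "\\s*:\\s*")[[1]]
      if (length(parts) != 2L) next
      key <- parts[1]; val <- parts[2]
      if (comp == "legend" && key == "frameon") {
        overrides$legend_frame <- tolower(val) %in% c("true", "1", "yes")
      } else {
        warning(sprintf("ignoring unknown renderer keyword %s:%s", comp, key),
                call. = FALSE)
      }
    }
  }
  overrides
}
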