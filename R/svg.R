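# Scene backends. A scene is a flat list of screen-space primitives
# (circle / line / path / text), rendered either as SVG text — the canonical
# output, written with fixed number formatting so identical scenes give
# byte-identical files — or rasterized to PNG through the grDevices device.

fmt <- function(x) sprintf("%.3f", x)

xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

prim_circle <- function(cx, cy, r, fill = "none", stroke = "none",
                        width = 1, class = NULL, dash = NULL) {
  list(type = "circle", cx = cx, cy = cy, r = r, fill = fill, stroke = stroke,
       width = width, class = class, dash = dash)
}

prim_line <- function(x1, y1, x2, y2, stroke = "#000000", width = 1,
                      arrow_end = FALSE, arrow_start = FALSE, class = NULL,
                      dash = NULL) {
  list(type = "line", x1 = x1, y1 = y1, x2 = x2, y2 = y2, stroke = stroke,
       width = width, arrow_end = arrow_end, arrow_start = arrow_start,
       class = class, dash = dash)
}

# quadratic bezier, used for the optional curved edge style
prim_path <- function(x1, y1, cx, cy, x2, y2, stroke = "#000000", width = 1,
                      arrow_end = FALSE, arrow_start = FALSE, class = NULL) {
  list(type = "path", x1 = x1, y1 = y1, cx = cx, cy = cy, x2 = x2, y2 = y2,
       stroke = stroke, width = width, arrow_end = arrow_end,
       arrow_start = arrow_start, class = class)
}

prim_text <- function(x, y, text, size = 10, fill = "#000000",
                      anchor = "middle", class = NULL) {
  list(type = "text", x = x, y = y, text = text, size = size, fill = fill,
       anchor = anchor, class = class)
}

scene_to_svg <- function(prims, width, height, background = "#FFFFFF") {
  needs_marker <- any(vapply(prims, function(p) {
    isTRUE(p$arrow_end) || isTRUE(p$arrow_start)
  }, logical(1)))
  lines <- c(
    "<?xml version=\"1.0\" encoding=\"UTF-8\"?>",
    sprintf(paste0("<svg xmlns=\"http://www.w3.org/2000/svg\" width=\"%s\" ",
                   "height=\"%s\" viewBox=\"0 0 %s %s\">"),
            fmt(width), fmt(height), fmt(width), fmt(height))
  )
  if (needs_marker) {
    lines <- c(lines,
      "<defs>",
      paste0("<marker id=\"arrowhead\" viewBox=\"0 0 10 10\" refX=\"9\" ",
             "refY=\"5\" markerWidth=\"7\" markerHeight=\"7\" ",
             "orient=\"auto-start-reverse\">",
             "<path d=\"M 0 0 L 10 5 L 0 10 z\" fill=\"#555555\"/>",
             "</marker>"),
      "</defs>")
  }
  lines <- c(lines, sprintf(
    "<rect x=\"0\" y=\"0\" width=\"%s\" height=\"%s\" fill=\"%s\"/>",
    fmt(width), fmt(height), background))
  for (p in prims) {
    cls <- if (is.null(p$class)) "" else sprintf(" class=\"%s\"", p$class)
    dash <- if (is.null(p$dash)) "" else
      sprintf(" stroke-dasharray=\"%s\"", p$dash)
    el <- switch(p$type,
      circle = sprintf(
        "<circle%s cx=\"%s\" cy=\"%s\" r=\"%s\" fill=\"%s\" stroke=\"%s\" stroke-width=\"%s\"%s/>",
        cls, fmt(p$cx), fmt(p$cy), fmt(p$r), p$fill, p$stroke, fmt(p$width),
        dash),
      line = sprintf(
        "<line%s x1=\"%s\" y1=\"%s\" x2=\"%s\" y2=\"%s\" stroke=\"%s\" stroke-width=\"%s\"%s%s%s/>",
        cls, fmt(p$x1), fmt(p$y1), fmt(p$x2), fmt(p$y2), p$stroke,
        fmt(p$width), dash,
        if (isTRUE(p$arrow_end)) " marker-end=\"url(#arrowhead)\"" else "",
        if (isTRUE(p$arrow_start)) " marker-start=\"url(#arrowhead)\"" else ""),
      path = sprintf(
        "<path%s d=\"M %s %s Q %s %s %s %s\" fill=\"none\" stroke=\"%s\" stroke-width=\"%s\"%s%s/>",
        cls, fmt(p$x1), fmt(p$y1), fmt(p$cx), fmt(p$cy), fmt(p$x2),
        fmt(p$y2), p$stroke, fmt(p$width),
        if (isTRUE(p$arrow_end)) " marker-end=\"url(#arrowhead)\"" else "",
        if (isTRUE(p$arrow_start)) " marker-start=\"url(#arrowhead)\"" else ""),
      text = sprintf(
        paste0("<text%s x=\"%s\" y=\"%s\" font-size=\"%s\" fill=\"%s\" ",
               "text-anchor=\"%s\" font-family=\"Helvetica, Arial, sans-serif\">%s</text>"),
        cls, fmt(p$x), fmt(p$y), fmt(p$size), p$fill, p$anchor,
        xml_escape(p$text)),
      stop("unknown primitive type: ", p$type)
    )
    lines <- c(lines, el)
  }
  c(lines, "</svg>")
}

write_scene_svg <- function(prims, width, height, path,
                            background = "#FFFFFF") {
  con <- file(path, open = "wb")  # binary: fixed \n line endings
  on.exit(close(con))
  writeLines(scene_to_svg(prims, width, height, background), con, sep = "\n")
  invisible(path)
}

# PNG rasterization of the same scene via the grDevices device. User
# coordinates are set up 1:1 with pixels, y downward, to match the SVG.
write_scene_png <- function(prims, width, height, path,
                            background = "#FFFFFF", dpi = 96) {
  grDevices::png(path, width = width, height = height, res = dpi,
                 bg = background)
  on.exit(grDevices::dev.off())
  graphics::par(mar = c(0, 0, 0, 0), xaxs = "i", yaxs = "i")
  graphics::plot.new()
  graphics::plot.window(xlim = c(0, width), ylim = c(height, 0), asp = 1)
  for (p in prims) {
    if (p$type == "circle") {
      graphics::symbols(p$cx, p$cy, circles = p$r, inches = FALSE,
                        add = TRUE,
                        fg = if (p$stroke == "none") NA else p$stroke,
                        bg = if (p$fill == "none") NA else p$fill,
                        lwd = p$width)
    } else if (p$type == "line") {
      lty <- if (is.null(p$dash)) 1 else 2
      graphics::segments(p$x1, p$y1, p$x2, p$y2, col = p$stroke,
                         lwd = p$width, lty = lty)
      draw_png_arrows(p)
    } else if (p$type == "path") {
      t <- seq(0, 1, length.out = 24)
      bx <- (1 - t)^2 * p$x1 + 2 * (1 - t) * t * p$cx + t^2 * p$x2
      by <- (1 - t)^2 * p$y1 + 2 * (1 - t) * t * p$cy + t^2 * p$y2
      graphics::lines(bx, by, col = p$stroke, lwd = p$width)
      draw_png_arrows(list(x1 = bx[23], y1 = by[23], x2 = p$x2, y2 = p$y2,
                           stroke = p$stroke, width = p$width,
                           arrow_end = p$arrow_end,
                           arrow_start = p$arrow_start))
    } else if (p$type == "text") {
      adj <- switch(p$anchor, start = 0, middle = 0.5, end = 1)
      graphics::text(p$x, p$y, labels = p$text, col = p$fill,
                     cex = p$size / 12, adj = c(adj, 0.5))
    }
  }
  invisible(path)
}

draw_png_arrows <- function(p) {
  if (isTRUE(p$arrow_end)) {
    graphics::arrows(p$x1, p$y1, p$x2, p$y2, length = 0.07, angle = 25,
                     col = p$stroke, lwd = p$width)
  }
  if (isTRUE(p$arrow_start)) {
    graphics::arrows(p$x2, p$y2, p$x1, p$y1, length = 0.07, angle = 25,
                     col = p$stroke, lwd = p$width)
  }
}
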