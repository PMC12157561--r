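# Map rendering: pathway graph + layout -> styled scene -> SVG/PNG.

CATEGORICAL_PALETTE <- c("#4477AA", "#EE6677", "#228833", "#CCBB44",
                         "#66CCEE", "#AA3377", "#BBBBBB")
DIVERGING_ENDS <- c("#2166AC", "#F7F7F7", "#B2182B")

#' Rendering style
#'
#' @param node_size Node marker radius in pixels.
#' @param node_color Default node fill (hex). Overlay-driven coloring takes
#'   precedence: numeric overlays use a blue–white–red diverging palette with
#'   limits symmetric about zero (so sign is always legible), categorical
#'   overlays a fixed qualitative palette assigned to sorted unique labels.
#' @param edge_color,edge_width Edge stroke styling.
#' @param arrowheads Draw directed arrowheads (reversible edges get both).
#' @param curved Draw edges as shallow quadratic curves instead of straight
#'   chords.
#' @param label_mode `"none"`, `"all"`, or a character vector of compound ids
#'   to label.
#' @param label_size Label font size (px).
#' @param grid Draw reference geometry: in polar mode the fixed outer
#'   boundary circle, concentric radial rings, and angular spokes at the H:C
#'   values in `spokes_hc` (same-H:C compounds line up on a spoke, a natural
#'   landmark); in Cartesian mode plain axes.
#' @param spokes_hc H:C values at which to draw labelled spokes; `NULL` means
#'   integer values inside the angular full scale.
#' @param figure_size Width/height of one map in pixels.
#' @param dpi Raster resolution for PNG output.
#' @param background Background color.
#' @return A `style_spec`.
#' @export
style_spec <- function(node_size = 5, node_color = "#4477AA",
                       edge_color = "#555555", edge_width = 1.2,
                       arrowheads = TRUE, curved = FALSE,
                       label_mode = "none", label_size = 10, grid = TRUE,
                       spokes_hc = NULL, figure_size = c(640, 640),
                       dpi = 96, background = "#FFFFFF") {
  stopifnot(node_size > 0, length(figure_size) == 2, all(figure_size > 0))
  structure(
    list(node_size = node_size, node_color = node_color,
         edge_color = edge_color, edge_width = edge_width,
         arrowheads = arrowheads, curved = curved, label_mode = label_mode,
         label_size = label_size, grid = grid, spokes_hc = spokes_hc,
         figure_size = figure_size, dpi = dpi, background = background),
    class = "style_spec"
  )
}

# Node fill colors from overlay columns. Numeric: diverging ramp symmetric
# about 0. Categorical (overlay_label, else merge `source`): qualitative
# palette over sorted unique labels. NA -> default color.
col_or_null <- function(tab, col) {
  if (col %in% names(tab)) tab[[col]] else NULL
}

node_fill_colors <- function(compounds, style) {
  n <- nrow(compounds)
  fills <- rep(style$node_color, n)
  v <- col_or_null(compounds, "overlay_value")
  if (!is.null(v)) {
    vmax <- max(abs(v), na.rm = TRUE)
    if (!is.finite(vmax) || vmax == 0) vmax <- 1
    ramp <- grDevices::colorRamp(DIVERGING_ENDS)
    t <- (pmax(pmin(v, vmax), -vmax) / vmax + 1) / 2
    ok <- !is.na(t)
    cols <- ramp(t[ok])
    fills[ok] <- grDevices::rgb(cols[, 1], cols[, 2], cols[, 3],
                                maxColorValue = 255)
  } else {
    lab <- col_or_null(compounds, "overlay_label")
    if (is.null(lab)) lab <- col_or_null(compounds, "source")
    if (!is.null(lab)) {
      lev <- sort(unique(lab[!is.na(lab)]))
      pal <- rep_len(CATEGORICAL_PALETTE, length(lev))
      ok <- !is.na(lab)
      fills[ok] <- pal[match(lab[ok], lev)]
    }
  }
  fills
}

#' @export
print.render_report <- function(x, ...) {
  cat("<render_report>", x$out, "\n")
  cat(sprintf("  nodes %d  edges %d  labels %d (suppressed %d)\n",
              x$nodes_drawn, x$edges_drawn, x$labels_placed,
              x$labels_suppressed))
  cat(sprintf("  clipped %d  residual collisions %d  carbon-free excluded %d\n",
              x$nodes_clipped, x$residual_collisions, x$carbon_free_excluded))
  invisible(x)
}

# screen transform for one panel
panel_transform <- function(mode, layout, style, r_bound, offset_x = 0) {
  w <- style$figure_size[1]; h <- style$figure_size[2]
  margin <- 40
  if (mode == "polar") {
    half <- min(w, h) / 2 - margin
    scale <- half / (r_bound * 1.05)
    cx <- offset_x + w / 2; cy <- h / 2
    list(
      to_screen = function(x, y) list(x = cx + x * scale, y = cy - y * scale),
      px_per_unit = scale, cx = cx, cy = cy
    )
  } else {
    xmax <- max(max(layout$x), 1e-9) * 1.08
    ymax <- max(max(layout$y), 1e-9) * 1.08
    sx <- (w - 2 * margin) / xmax
    sy <- (h - 2 * margin) / ymax
    list(
      to_screen = function(x, y) {
        list(x = offset_x + margin + x * sx, y = h - margin - y * sy)
      },
      px_per_unit = min(sx, sy), xmax = xmax, ymax = ymax, margin = margin
    )
  }
}

build_panel_scene <- function(graph, layout, style, mode, r_bound,
                              offset_x = 0, title = NULL) {
  tf <- panel_transform(mode, layout, style, r_bound, offset_x)
  prims <- list()
  add <- function(p) prims[[length(prims) + 1]] <<- p
  w <- style$figure_size[1]; h <- style$figure_size[2]
  config <- attr(layout, "config")

  if (style$grid && mode == "polar") {
    ctr <- tf$to_screen(0, 0)
    # fixed outer boundary: constant space for the chemistry
    add(prim_circle(ctr$x, ctr$y, r_bound * tf$px_per_unit,
                    stroke = "#333333", width = 1.2, class = "boundary"))
    rings <- pretty(c(0, r_bound), n = 4)
    rings <- rings[rings > 0 & rings < r_bound]
    for (rr in rings) {
      add(prim_circle(ctr$x, ctr$y, rr * tf$px_per_unit, stroke = "#DDDDDD",
                      width = 0.8, class = "ring", dash = "3,3"))
      add(prim_text(ctr$x + 3, ctr$y - rr * tf$px_per_unit - 3,
                    format(rr, trim = TRUE), size = 8, fill = "#999999",
                    anchor = "start", class = "ring-label"))
    }
    spokes <- style$spokes_hc
    if (is.null(spokes)) {
      spokes <- seq(0, ceiling(config$hc_max) - 1)
      spokes <- spokes[spokes < config$hc_max]
    }
    dir_sign <- if (config$direction == "ccw") 1 else -1
    for (hcv in spokes) {
      th <- (config$theta_origin +
               dir_sign * 2 * pi * min(hcv, config$hc_max) / config$hc_max) %%
        (2 * pi)
      tip <- tf$to_screen(r_bound * cos(th), r_bound * sin(th))
      add(prim_line(ctr$x, ctr$y, tip$x, tip$y, stroke = "#DDDDDD",
                    width = 0.8, class = "spoke", dash = "3,3"))
      lab <- tf$to_screen(r_bound * 1.03 * cos(th), r_bound * 1.03 * sin(th))
      add(prim_text(lab$x, lab$y, paste0("H:C=", format(hcv)), size = 8,
                    fill = "#999999",
                    anchor = if (cos(th) >= 0) "start" else "end",
                    class = "spoke-label"))
    }
  }
  if (style$grid && mode == "cartesian") {
    m <- tf$margin
    add(prim_line(offset_x + m, h - m, offset_x + w - m, h - m,
                  stroke = "#333333", width = 1, class = "axis"))
    add(prim_line(offset_x + m, h - m, offset_x + m, m,
                  stroke = "#333333", width = 1, class = "axis"))
    for (tick in pretty(c(0, tf$xmax), 5)) {
      if (tick < 0 || tick > tf$xmax) next
      p <- tf$to_screen(tick, 0)
      add(prim_line(p$x, p$y, p$x, p$y + 4, stroke = "#333333", width = 1,
                    class = "tick"))
      add(prim_text(p$x, p$y + 14, format(tick), size = 8, fill = "#666666",
                    class = "tick-label"))
    }
    for (tick in pretty(c(0, tf$ymax), 5)) {
      if (tick < 0 || tick > tf$ymax) next
      p <- tf$to_screen(0, tick)
      add(prim_line(p$x - 4, p$y, p$x, p$y, stroke = "#333333", width = 1,
                    class = "tick"))
      add(prim_text(p$x - 6, p$y, format(tick), size = 8, fill = "#666666",
                    anchor = "end", class = "tick-label"))
    }
  }

  # edges under nodes; shorten ends so arrowheads sit outside the markers
  pos <- stats::setNames(seq_len(nrow(layout)), layout$compound_id)
  edges_drawn <- 0L
  for (i in seq_len(nrow(graph$reactions))) {
    rx <- graph$reactions[i, ]
    a <- layout[pos[[rx$substrate]], ]; b <- layout[pos[[rx$product]], ]
    p1 <- tf$to_screen(a$x, a$y); p2 <- tf$to_screen(b$x, b$y)
    dx <- p2$x - p1$x; dy <- p2$y - p1$y
    len <- sqrt(dx^2 + dy^2)
    if (len < 1e-9) {  # coincident endpoints: degenerate but still drawn
      ux <- 0; uy <- 0; trim <- 0
    } else {
      trim <- min(style$node_size + 2, len / 3)
      ux <- dx / len; uy <- dy / len
    }
    x1 <- p1$x + ux * trim; y1 <- p1$y + uy * trim
    x2 <- p2$x - ux * trim; y2 <- p2$y - uy * trim
    if (style$curved) {
      mx <- (x1 + x2) / 2 - uy * len * 0.15
      my <- (y1 + y2) / 2 + ux * len * 0.15
      add(prim_path(x1, y1, mx, my, x2, y2, stroke = style$edge_color,
                    width = style$edge_width,
                    arrow_end = style$arrowheads,
                    arrow_start = style$arrowheads && isTRUE(rx$reversible),
                    class = "edge"))
    } else {
      add(prim_line(x1, y1, x2, y2, stroke = style$edge_color,
                    width = style$edge_width,
                    arrow_end = style$arrowheads,
                    arrow_start = style$arrowheads && isTRUE(rx$reversible),
                    class = "edge"))
    }
    edges_drawn <- edges_drawn + 1L
  }

  cpd <- graph$compounds[match(layout$compound_id, graph$compounds$id), ]
  fills <- node_fill_colors(cpd, style)
  for (i in seq_len(nrow(layout))) {
    p <- tf$to_screen(layout$x[i], layout$y[i])
    add(prim_circle(p$x, p$y, style$node_size, fill = fills[i],
                    stroke = "#222222", width = 0.8, class = "node"))
  }

  labels_placed <- 0L; labels_suppressed <- 0L
  wanted <- if (identical(style$label_mode, "all")) layout$compound_id
            else if (identical(style$label_mode, "none")) character(0)
            else intersect(style$label_mode, layout$compound_id)
  for (id in wanted) {
    i <- pos[[id]]
    p <- tf$to_screen(layout$x[i], layout$y[i])
    if (mode == "polar" && layout$r[i] > 1e-9) {
      ux <- cos(layout$theta[i]); uy <- -sin(layout$theta[i])
      lx <- p$x + ux * (style$node_size + 6)
      ly <- p$y + uy * (style$node_size + 6)
      anchor <- if (ux >= 0) "start" else "end"
    } else {
      lx <- p$x; ly <- p$y - style$node_size - 5; anchor <- "middle"
    }
    if (lx < offset_x || lx > offset_x + w || ly < 0 || ly > h) {
      labels_suppressed <- labels_suppressed + 1L
      next
    }
    add(prim_text(lx, ly, cpd$name[i], size = style$label_size,
                  fill = "#222222", anchor = anchor, class = "label"))
    labels_placed <- labels_placed + 1L
  }

  if (!is.null(title)) {
    add(prim_text(offset_x + w / 2, 18, title, size = style$label_size + 2,
                  fill = "#222222", class = "title"))
  }

  list(prims = prims, edges_drawn = edges_drawn,
       labels_placed = labels_placed, labels_suppressed = labels_suppressed)
}

check_layout_matches <- function(graph, layout) {
  if (!setequal(graph$compounds$id, layout$compound_id) ||
      nrow(layout) != nrow(graph$compounds)) {
    stop("layout does not correspond to graph: compound ids differ",
         call. = FALSE)
  }
}

write_scene <- function(prims, width, height, out, style) {
  ext <- tolower(tools::file_ext(out))
  if (ext == "svg") {
    write_scene_svg(prims, width, height, out, style$background)
  } else if (ext == "png") {
    write_scene_png(prims, width, height, out, style$background, style$dpi)
  } else {
    stop("unsupported output extension '", ext, "' (use .svg or .png)",
         call. = FALSE)
  }
}

#' Render a pathway map
#'
#' Draws one van Krevelen pathway map — nodes at their layout coordinates,
#' reactions as directed connectors with arrowheads (double-headed when
#' reversible), optional labels and reference geometry — and writes SVG
#' (canonical, byte-identical for identical inputs) or PNG by file
#' extension.
#'
#' @param graph A [pathway_graph()].
#' @param layout A `layout_result` for the same compounds, from
#'   [cartesian_layout()] or [polar_layout()] (optionally passed through
#'   [resolve_overlaps()]).
#' @param style A [style_spec()].
#' @param out Output path ending in `.svg` or `.png`.
#' @param mode `"auto"` (from the layout), `"cartesian"` or `"polar"`.
#' @return A `render_report` with counts of nodes, edges and labels drawn,
#'   nodes clipped, residual collisions and carbon-free exclusions. Nodes
#'   drawn plus carbon-free exclusions equals the number of compounds in the
#'   input tables.
#' @export
render_map <- function(graph, layout, style = style_spec(), out,
                       mode = c("auto", "cartesian", "polar")) {
  stopifnot(inherits(graph, "pathway_graph"), inherits(layout, "layout_result"))
  mode <- match.arg(mode)
  if (mode == "auto") mode <- attr(layout, "mode")
  check_layout_matches(graph, layout)
  r_bound <- if (mode == "polar") bounding_circle(layout) else NA_real_
  scene <- build_panel_scene(graph, layout, style, mode, r_bound)
  write_scene(scene$prims, style$figure_size[1], style$figure_size[2], out,
              style)
  structure(
    list(nodes_drawn = nrow(layout), edges_drawn = scene$edges_drawn,
         labels_placed = scene$labels_placed,
         labels_suppressed = scene$labels_suppressed,
         nodes_clipped = sum(layout$clipped),
         residual_collisions = attr(layout, "residual_collisions") %||% 0L,
         carbon_free_excluded = graph$metadata$carbon_free_excluded %||% 0L,
         out = out, mode = mode),
    class = "render_report"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Render a small-multiple panel of circular maps
#'
#' One circular map per graph, side by side, sharing a single angular
#' convention and a single radial full scale so the same compound occupies
#' the same position in every panel.
#'
#' @param graphs Non-empty list of [pathway_graph()] objects.
#' @param config Shared [layout_config()]. When `r_max` is unset the shared
#'   radial scale is the largest radius over all panels.
#' @param style A [style_spec()]; `figure_size` is the size of one panel.
#' @param out Output path (`.svg` or `.png`).
#' @param resolve Run [resolve_overlaps()] within each panel.
#' @return A `render_report` with counts summed over panels.
#' @export
render_panel <- function(graphs, config = layout_config(),
                         style = style_spec(), out, resolve = TRUE) {
  if (!is.list(graphs) || length(graphs) == 0 ||
      !all(vapply(graphs, inherits, logical(1), "pathway_graph"))) {
    stop("graphs must be a non-empty list of pathway_graph objects",
         call. = FALSE)
  }
  layouts <- lapply(graphs, function(g) {
    l <- polar_layout(g, config)
    if (resolve) l <- resolve_overlaps(l, config)
    l
  })
  r_shared <- config$r_max %||% max(vapply(layouts, bounding_circle, double(1)))
  w <- style$figure_size[1]; h <- style$figure_size[2]
  prims <- list()
  totals <- list(nodes = 0L, edges = 0L, labels = 0L, suppressed = 0L,
                 clipped = 0L, residual = 0L, carbon_free = 0L)
  for (k in seq_along(graphs)) {
    scene <- build_panel_scene(graphs[[k]], layouts[[k]], style, "polar",
                               r_shared, offset_x = (k - 1) * w,
                               title = graphs[[k]]$metadata$name %||% "")
    prims <- c(prims, scene$prims)
    totals$nodes <- totals$nodes + nrow(layouts[[k]])
    totals$edges <- totals$edges + scene$edges_drawn
    totals$labels <- totals$labels + scene$labels_placed
    totals$suppressed <- totals$suppressed + scene$labels_suppressed
    totals$clipped <- totals$clipped + sum(layouts[[k]]$clipped)
    totals$residual <- totals$residual +
      (attr(layouts[[k]], "residual_collisions") %||% 0L)
    totals$carbon_free <- totals$carbon_free +
      (graphs[[k]]$metadata$carbon_free_excluded %||% 0L)
  }
  write_scene(prims, w * length(graphs), h, out, style)
  structure(
    list(nodes_drawn = totals$nodes, edges_drawn = totals$edges,
         labels_placed = totals$labels, labels_suppressed = totals$suppressed,
         nodes_clipped = totals$clipped, residual_collisions = totals$residual,
         carbon_free_excluded = totals$carbon_free, out = out,
         mode = "polar-panel"),
    class = "render_report"
  )
}
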