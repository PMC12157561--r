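# Coordinate assignment. Positions are pure functions of a compound's
# elemental ratios and a layout_config — never of the other compounds on the
# map — which is what makes coordinates comparable across pathways, datasets
# and collaborators. Overlap resolution is the one deliberate exception and
# is bounded, deterministic and flagged per node.

#' Layout configuration
#'
#' @param y_ratio Which ratio drives the y-axis (Cartesian) or radius
#'   (polar): `"nops"` for the mass-weighted NOPS:C ratio, `"oc"` for O:C.
#' @param hc_max Angular full scale (unitless H:C). The interval
#'   `[0, hc_max]` is mapped linearly onto one full turn; H:C values above
#'   `hc_max` saturate at the full-scale angle (flagged, never wrapped, so
#'   distinct compounds are never aliased). The default 4 covers methane
#'   (H:C = 4), the saturated extreme of CHNOPS chemistry.
#' @param r_max Optional radial clip value; radii above it are clipped and
#'   flagged. Also fixes the outer boundary circle, see [bounding_circle()].
#' @param theta_origin Angle of H:C = 0, radians; default 0 (east).
#' @param direction `"ccw"` (default, mathematical convention) or `"cw"`.
#' @param min_sep Minimum node separation for [resolve_overlaps()], as a
#'   fraction of the bounding radius. Default 0.01.
#' @param max_iter Iteration cap for overlap resolution.
#' @param seed Integer seed reserved for stochastic resolution strategies;
#'   the built-in symmetric fan is fully deterministic.
#' @return A `layout_config`.
#' @export
layout_config <- function(y_ratio = c("nops", "oc"), hc_max = 4, r_max = NULL,
                          theta_origin = 0, direction = c("ccw", "cw"),
                          min_sep = 0.01, max_iter = 25, seed = 1L) {
  y_ratio <- match.arg(y_ratio)
  direction <- match.arg(direction)
  if (!is.numeric(hc_max) || hc_max <= 0) {
    stop("hc_max must be > 0", call. = FALSE)
  }
  if (!is.null(r_max) && (!is.numeric(r_max) || r_max <= 0)) {
    stop("r_max must be > 0 when set", call. = FALSE)
  }
  if (min_sep < 0) stop("min_sep must be >= 0", call. = FALSE)
  if (max_iter < 0) stop("max_iter must be >= 0", call. = FALSE)
  structure(
    list(y_ratio = y_ratio, hc_max = hc_max, r_max = r_max,
         theta_origin = theta_origin, direction = direction,
         min_sep = min_sep, max_iter = as.integer(max_iter),
         seed = as.integer(seed)),
    class = "layout_config"
  )
}

selected_ratio <- function(graph, config) {
  if (config$y_ratio == "nops") graph$compounds$nops_c else graph$compounds$oc
}

new_layout_result <- function(tab, mode, config) {
  structure(tab, class = c("layout_result", class(tab)),
            mode = mode, config = config, residual_collisions = 0L)
}

#' Cartesian van Krevelen layout
#'
#' The conventional van Krevelen scatter: x = H:C, y = the selected ratio
#' (O:C or NOPS:C). No clipping or displacement is applied.
#'
#' @param graph A [pathway_graph()] with cached ratios.
#' @param config A [layout_config()].
#' @return A `layout_result` tibble with one row per compound: `compound_id`,
#'   `formula`, `hc`, `ratio`, `theta`, `r`, `x`, `y`, `clipped`,
#'   `hc_saturated`, `displaced`, `displacement`. For Cartesian layouts
#'   `theta`/`r` are the polar equivalent of `(x, y)`, kept so overlap
#'   resolution works identically in both modes.
#' @export
cartesian_layout <- function(graph, config = layout_config()) {
  stopifnot(inherits(graph, "pathway_graph"), inherits(config, "layout_config"))
  x <- graph$compounds$hc
  y <- selected_ratio(graph, config)
  tab <- tibble::tibble(
    compound_id = graph$compounds$id,
    formula = graph$compounds$formula,
    hc = x, ratio = y,
    theta = atan2(y, x) %% (2 * pi),
    r = sqrt(x^2 + y^2),
    x = x, y = y,
    clipped = FALSE,
    hc_saturated = FALSE,
    displaced = FALSE,
    displacement = 0
  )
  new_layout_result(tab, "cartesian", config)
}

#' Polar (circular) van Krevelen layout
#'
#' H:C maps linearly to the angular coordinate,
#' `theta = theta_origin + dir * 2*pi * min(hc, hc_max) / hc_max` reduced to
#' `[0, 2*pi)`; the selected ratio (NOPS:C or O:C) is the radial distance,
#' clipped at `r_max` when configured. Each coordinate depends only on the
#' compound's own formula and the config, so a compound occupies the same
#' point on every map drawn with the same config.
#'
#' @inheritParams cartesian_layout
#' @return A `layout_result`, see [cartesian_layout()].
#' @export
polar_layout <- function(graph, config = layout_config()) {
  stopifnot(inherits(graph, "pathway_graph"), inherits(config, "layout_config"))
  hc <- graph$compounds$hc
  ratio <- selected_ratio(graph, config)
  dir_sign <- if (config$direction == "ccw") 1 else -1
  hc_eff <- pmin(hc, config$hc_max)
  theta <- (config$theta_origin + dir_sign * 2 * pi * hc_eff / config$hc_max) %%
    (2 * pi)
  clipped <- rep(FALSE, length(ratio))
  r <- ratio
  if (!is.null(config$r_max)) {
    clipped <- r > config$r_max
    r <- pmin(r, config$r_max)
  }
  tab <- tibble::tibble(
    compound_id = graph$compounds$id,
    formula = graph$compounds$formula,
    hc = hc, ratio = ratio,
    theta = theta, r = r,
    x = r * cos(theta), y = r * sin(theta),
    clipped = clipped,
    hc_saturated = hc > config$hc_max,
    displaced = FALSE,
    displacement = 0
  )
  new_layout_result(tab, "polar", config)
}

#' Outer boundary radius
#'
#' The fixed outer circle the renderer draws in polar mode: the configured
#' `r_max` when set (a constant space for the chemistry, independent of the
#' data), otherwise the maximum radius present in the layout.
#'
#' @param layout A non-empty `layout_result`.
#' @return A single radius.
#' @export
bounding_circle <- function(layout) {
  stopifnot(inherits(layout, "layout_result"))
  if (nrow(layout) == 0) stop("empty layout", call. = FALSE)
  config <- attr(layout, "config")
  if (!is.null(config$r_max)) config$r_max else max(layout$r)
}

circular_mean <- function(theta) {
  atan2(mean(sin(theta)), mean(cos(theta))) %% (2 * pi)
}

# signed smallest angular difference a - b in (-pi, pi]
ang_diff <- function(a, b) {
  d <- (a - b) %% (2 * pi)
  ifelse(d > pi, d - 2 * pi, d)
}

#' Resolve node overlaps
#'
#' Compounds with identical formulas (cohabitant isomers) share a coordinate;
#' this pass separates them — and any other nodes closer than
#' `min_sep * r_max` — by small angular offsets distributed symmetrically
#' around the original angle, processed in compound-id order so the result is
#' fully deterministic and independent of input row order.
#'
#' Two hard guarantees hold for every node: its radius is unchanged (the
#' radial coordinate keeps its chemical meaning exactly) and its Euclidean
#' displacement never exceeds `min_sep * r_max`. On a fixed-radius circle
#' those bounds cap how many mutually separated nodes can share one point
#' (three at full separation); larger coincident groups are fanned to
#' distinct coordinates at reduced spacing and the remaining close pairs are
#' counted in `attr(result, "residual_collisions")` rather than forced apart.
#'
#' @param layout A `layout_result`.
#' @param config Defaults to the config stored in `layout`.
#' @return A `layout_result` with updated `theta`, `x`, `y`, `displaced`,
#'   `displacement`; undisplaced rows are bit-identical to the input.
#' @export
resolve_overlaps <- function(layout, config = attr(layout, "config")) {
  stopifnot(inherits(layout, "layout_result"))
  n <- nrow(layout)
  sep <- config$min_sep * bounding_circle(layout)
  out <- layout
  attr(out, "residual_collisions") <- 0L
  if (n < 2 || sep <= 0) return(out)

  ord <- order(layout$compound_id)          # id-sorted processing order
  work <- layout[ord, , drop = FALSE]
  theta0 <- work$theta                      # originals: bounds refer to these
  r0 <- work$r
  # max angular excursion keeping chord displacement 2 r sin(d/2) <= sep
  d_max <- ifelse(r0 <= sep / 2, pi, 2 * asin(pmin(1, sep / (2 * r0))))

  for (iter in seq_len(config$max_iter)) {
    d2 <- as.matrix(stats::dist(cbind(work$x, work$y)))
    close <- d2 < sep - 1e-12
    diag(close) <- FALSE
    if (!any(close)) break
    clusters <- components_of(close)
    moved <- FALSE
    for (cl in clusters) {
      if (length(cl) < 2) next
      k <- length(cl)
      mu <- circular_mean(work$theta[cl])
      r_c <- mean(work$r[cl])
      # adjacent spacing achieving chord sep at the cluster radius
      d_sep <- if (r_c <= sep / 2) 2 * pi / k else 2 * asin(min(1, sep / (2 * r_c)))
      # cap the fan so no node leaves its displacement budget
      half_width <- min(min(d_max[cl]), d_sep * (k - 1) / 2)
      spacing <- if (k > 1) 2 * half_width / (k - 1) else 0
      # members ordered by current angle relative to mu, ties by id order
      rel <- ang_diff(work$theta[cl], mu)
      members <- cl[order(rel, seq_along(cl))]
      offsets <- (seq_len(k) - (k + 1) / 2) * spacing
      for (j in seq_len(k)) {
        i <- members[j]
        target <- mu + offsets[j]
        # clamp against the node's own original angle and budget
        delta <- pmin(pmax(ang_diff(target, theta0[i]), -d_max[i]), d_max[i])
        new_theta <- (theta0[i] + delta) %% (2 * pi)
        if (!isTRUE(all.equal(new_theta, work$theta[i], tolerance = 1e-15))) {
          moved <- TRUE
        }
        work$theta[i] <- new_theta
        work$x[i] <- work$r[i] * cos(new_theta)
        work$y[i] <- work$r[i] * sin(new_theta)
      }
    }
    if (!moved) break
  }

  disp <- 2 * r0 * abs(sin(ang_diff(work$theta, theta0) / 2))
  work$displaced <- disp > 1e-12
  work$displacement <- disp
  # bit-identical pass-through for undisplaced nodes
  keep <- !work$displaced
  work$theta[keep] <- theta0[keep]
  work$x[keep] <- layout$x[ord][keep]
  work$y[keep] <- layout$y[ord][keep]

  d2 <- as.matrix(stats::dist(cbind(work$x, work$y)))
  residual <- sum(d2[upper.tri(d2)] < sep - 1e-12)

  out[ord, ] <- work
  attr(out, "residual_collisions") <- as.integer(residual)
  out
}

# connected components of a logical adjacency matrix (tiny n; plain BFS)
components_of <- function(adj) {
  n <- nrow(adj)
  seen <- rep(FALSE, n)
  comps <- list()
  for (s in seq_len(n)) {
    if (seen[s]) next
    queue <- s; seen[s] <- TRUE; comp <- integer(0)
    while (length(queue) > 0) {
      v <- queue[1]; queue <- queue[-1]
      comp <- c(comp, v)
      nb <- which(adj[v, ] & !seen)
      seen[nb] <- TRUE
      queue <- c(queue, nb)
    }
    comps[[length(comps) + 1]] <- sort(comp)
  }
  comps
}

#' Export a layout as a tab-separated table
#'
#' Columns: `compound_id`, `formula`, `hc`, `selected_ratio`, `theta_rad`,
#' `r`, `x`, `y`, `displaced`, `clipped`, full floating precision.
#'
#' @param layout A `layout_result`.
#' @param path Output file.
#' @return `layout`, invisibly.
#' @export
write_layout <- function(layout, path) {
  stopifnot(inherits(layout, "layout_result"))
  tab <- tibble::tibble(
    compound_id = layout$compound_id, formula = layout$formula,
    hc = layout$hc, selected_ratio = layout$ratio, theta_rad = layout$theta,
    r = layout$r, x = layout$x, y = layout$y,
    displaced = layout$displaced, clipped = layout$clipped
  )
  readr::write_tsv(tab, path)
  invisible(layout)
}

#' @export
print.layout_result <- function(x, ...) {
  cat(sprintf("<layout_result> %s, %d compounds", attr(x, "mode"), nrow(x)))
  rc <- attr(x, "residual_collisions")
  if (!is.null(rc) && rc > 0) cat(sprintf(", %d residual collision(s)", rc))
  cat("\n")
  NextMethod()
}
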