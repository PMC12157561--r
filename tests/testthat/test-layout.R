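# Coordinate assignment and deterministic overlap resolution.

single_compound_graph <- function(formula, id = "c1") {
  pathway_graph(tibble::tibble(id = id, name = id, formula = formula))
}

test_that("Cartesian layout is the plain van Krevelen projection", {
  g <- single_compound_graph("C26H43NO5")
  l <- cartesian_layout(g, layout_config(y_ratio = "nops"))
  expect_equal(round(l$x, 3), 1.654)
  expect_equal(round(l$y, 3), 0.301)
  l_oc <- cartesian_layout(g, layout_config(y_ratio = "oc"))
  expect_equal(round(l_oc$y, 3), 0.192)
  m <- cartesian_layout(single_compound_graph("CH4"), layout_config())
  expect_equal(c(m$x, m$y), c(4, 0))
  expect_false(any(l$clipped) || any(l$displaced))
})

test_that("polar layout maps H:C linearly onto the angle", {
  cfg <- layout_config(hc_max = 4)
  # H:C = 0 is impossible chemically at C >= 1 H = 0; use a formula with no H
  g0 <- single_compound_graph("C6O6")
  expect_equal(polar_layout(g0, cfg)$theta, 0)
  expect_equal(polar_layout(g0, layout_config(theta_origin = 1.25))$theta, 1.25)
  # half scale lands at pi
  g2 <- single_compound_graph("C2H4O2")  # hc = 2
  expect_equal(polar_layout(g2, cfg)$theta, pi)
  # worked example: theta = 2*pi*(43/26)/4, r = nops_c
  gw <- single_compound_graph("C26H43NO5")
  lw <- polar_layout(gw, cfg)
  expect_equal(lw$theta, 2 * pi * (43 / 26) / 4)
  expect_equal(round(lw$theta, 3), 2.598)
  expect_equal(round(lw$r, 3), 0.301)
  expect_equal(lw$x, lw$r * cos(lw$theta))
  expect_equal(lw$y, lw$r * sin(lw$theta))
  # clockwise direction mirrors the angle
  lw_cw <- polar_layout(gw, layout_config(direction = "cw"))
  expect_equal(lw_cw$theta, (2 * pi - lw$theta) %% (2 * pi))
  expect_error(layout_config(hc_max = 0), "hc_max")
})

test_that("H:C beyond the full scale saturates (never wraps) and r_max clips", {
  g <- single_compound_graph("CH4")  # hc = 4 = full scale
  cfg <- layout_config(hc_max = 3)
  l <- polar_layout(g, cfg)
  expect_true(l$hc_saturated)
  expect_equal(l$theta, 0)  # saturated at full turn, reduced mod 2*pi
  gg <- single_compound_graph("C2H12N12")  # impossible-ish but legal: hc = 6
  expect_error(pathway_graph(tibble::tibble(id = "x", name = "x",
                                            formula = "C2H12N12")), NA)
  l2 <- polar_layout(single_compound_graph("C1H3N1O4"),
                     layout_config(r_max = 1.0))
  expect_true(l2$clipped)
  expect_equal(l2$r, 1.0)
  expect_equal(l2$ratio, (14 + 4 * 16) / 12)  # raw ratio retained
})

test_that("coordinates are fixed: same formula + config => bit-identical position", {
  cfg <- layout_config()
  for (i in 1:200) {
    ga <- make_random_graph(sample(2:10, 1), 0, seed = 1000 + i)
    gb <- make_random_graph(sample(2:10, 1), 0, seed = 5000 + i)
    # plant one shared formula in both graphs
    shared <- ga$compounds$formula[1]
    gb$compounds$formula[1] <- shared
    gb <- pathway_graph(gb$compounds[, c("id", "name", "formula")], NULL)
    la <- polar_layout(ga, cfg)
    lb <- polar_layout(gb, cfg)
    expect_identical(c(la$theta[1], la$r[1], la$x[1], la$y[1]),
                     c(lb$theta[1], lb$r[1], lb$x[1], lb$y[1]))
  }
})

test_that("layout is order-invariant, including after overlap resolution", {
  g <- demo_pathway("aminosugar")
  cfg <- layout_config()
  l <- resolve_overlaps(polar_layout(g, cfg))
  perm <- sample(nrow(g$compounds))
  gp <- pathway_graph(g$compounds[perm, c("id", "name", "formula")],
                      g$reactions, metadata = g$metadata)
  lp <- resolve_overlaps(polar_layout(gp, cfg))
  m <- match(l$compound_id, lp$compound_id)
  expect_identical(l$theta, lp$theta[m])
  expect_identical(l$x, lp$x[m])
  expect_identical(l$displacement, lp$displacement[m])
})

test_that("angular range and radial nonnegativity hold on random graphs", {
  for (i in 1:20) {
    g <- make_random_graph(15, 10, seed = 200 + i)
    l <- polar_layout(g, layout_config())
    expect_true(all(l$theta >= 0 & l$theta < 2 * pi))
    expect_true(all(l$r >= 0))
  }
})

test_that("overlap resolution is a no-op on well-separated layouts", {
  g <- demo_pathway("caffeine")
  # drop one of each isomer pair so all coordinates are distinct and far
  keep <- !g$compounds$id %in% c("tb", "tp", "3mx", "7mx", "17dmu")
  g2 <- pathway_graph(g$compounds[keep, c("id", "name", "formula")], NULL)
  l <- polar_layout(g2, layout_config())
  r <- resolve_overlaps(l)
  expect_identical(tibble::as_tibble(r), tibble::as_tibble(l))
  expect_equal(attr(r, "residual_collisions"), 0L)
})

test_that("a coincident pair separates symmetrically within the displacement budget", {
  cfg <- layout_config(min_sep = 0.01)
  l <- coincident_layout(2, config = cfg)
  res <- resolve_overlaps(l, cfg)
  s <- cfg$min_sep * bounding_circle(l)
  d <- sqrt(diff(res$x)^2 + diff(res$y)^2)
  expect_gte(d, s * (1 - 1e-9))
  expect_true(all(res$displacement <= s * (1 + 1e-9)))
  expect_identical(res$r, l$r)  # radii untouched
  # midpoint of the two displaced angles is the original angle
  expect_equal(mean(res$theta), l$theta[1])
  expect_true(all(res$displaced))
})

test_that("coincident groups get distinct deterministic coordinates within budget", {
  cfg <- layout_config(min_sep = 0.01)
  for (k in c(3, 5, 8)) {
    l <- coincident_layout(k, config = cfg)
    s <- cfg$min_sep * bounding_circle(l)
    res <- resolve_overlaps(l, cfg)
    # distinct coordinates for every node
    coords <- paste(res$x, res$y)
    expect_equal(length(unique(coords)), k)
    # displacement bound and radius preservation
    expect_true(all(res$displacement <= s * (1 + 1e-9)))
    expect_identical(res$r, l$r)
    expect_true(all(abs(sqrt(res$x^2 + res$y^2) - l$r) < 1e-12))
    # deterministic: bit-identical on a second run
    expect_identical(tibble::as_tibble(resolve_overlaps(l, cfg)),
                     tibble::as_tibble(res))
    # brute-force distance matrix: groups of 3 or fewer reach full separation
    d <- as.matrix(stats::dist(cbind(res$x, res$y)))
    if (k <= 3) {
      expect_gte(min(d[upper.tri(d)]), s * (1 - 1e-9))
      expect_equal(attr(res, "residual_collisions"), 0L)
    } else {
      expect_gt(attr(res, "residual_collisions"), 0L)
    }
  }
})

test_that("displacement bound holds across random layouts with collisions", {
  for (i in 1:15) {
    g <- make_random_graph(20, 0, carbon_range = c(3, 8), seed = 300 + i)
    cfg <- layout_config(min_sep = 0.05)
    l <- polar_layout(g, cfg)
    res <- resolve_overlaps(l, cfg)
    s <- cfg$min_sep * bounding_circle(l)
    expect_true(all(res$displacement <= s * (1 + 1e-9)))
    expect_identical(res$r, l$r)
    undisplaced <- !res$displaced
    expect_identical(res$x[undisplaced], l$x[undisplaced])
    expect_identical(res$y[undisplaced], l$y[undisplaced])
  }
})

test_that("max_iter = 0 leaves positions alone but still reports collisions", {
  cfg <- layout_config(min_sep = 0.01, max_iter = 0)
  l <- coincident_layout(4, config = cfg)
  res <- resolve_overlaps(l, cfg)
  expect_identical(res$x, l$x)
  expect_equal(attr(res, "residual_collisions"), choose(4, 2))
})

test_that("bounding circle prefers the configured r_max", {
  g <- demo_pathway("caffeine")
  expect_equal(bounding_circle(polar_layout(g, layout_config(r_max = 3))), 3)
  l <- polar_layout(g, layout_config())
  expect_equal(bounding_circle(l), max(l$r))
  empty <- pathway_graph(tibble::tibble(id = character(), name = character(),
                                        formula = character()))
  expect_error(bounding_circle(polar_layout(empty, layout_config())), "empty")
})

test_that("layout export writes the documented columns at full precision", {
  g <- demo_pathway("caffeine")
  l <- resolve_overlaps(polar_layout(g, layout_config()))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_layout(l, f)
  back <- readr::read_tsv(f, show_col_types = FALSE)
  expect_equal(names(back),
               c("compound_id", "formula", "hc", "selected_ratio", "theta_rad",
                 "r", "x", "y", "displaced", "clipped"))
  expect_equal(back$theta_rad, l$theta, tolerance = 1e-12)
})
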