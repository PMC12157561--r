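# Pathway graph construction, validation, I/O, overlays and merging.

toy_tables <- function() {
  list(
    compounds = tibble::tibble(id = c("a", "b"), name = c("A", "B"),
                               formula = c("C8H10N4O2", "C7H8N4O2")),
    reactions = tibble::tibble(id = "r1", substrate = "a", product = "b")
  )
}

test_that("smallest valid pathway builds and reads from the two-table format", {
  t <- toy_tables()
  g <- pathway_graph(t$compounds, t$reactions)
  expect_s3_class(g, "pathway_graph")
  expect_equal(nrow(g$compounds), 2)
  expect_equal(nrow(g$reactions), 1)
  expect_false(g$reactions$reversible)
  expect_equal(g$metadata$carbon_free_excluded, 0)

  cf <- withr::local_tempfile(fileext = ".tsv")
  rf <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(t$compounds, cf)
  readr::write_tsv(t$reactions, rf)
  g2 <- read_pathway(cf, rf)
  expect_equal(g2$compounds[, c("id", "formula", "hc", "nops_c")],
               g$compounds[, c("id", "formula", "hc", "nops_c")])
})

test_that("validation rejects malformed graphs with informative errors", {
  t <- toy_tables()
  expect_error(pathway_graph(t$compounds[, c("id", "name")], t$reactions),
               "formula")
  expect_error(
    pathway_graph(rbind(t$compounds, t$compounds[1, ]), t$reactions),
    "duplicate compound")
  expect_error(
    pathway_graph(t$compounds,
                  tibble::tibble(id = c("r1", "r1"), substrate = c("a", "b"),
                                 product = c("b", "a"))),
    "duplicate reaction")
  expect_error(
    pathway_graph(t$compounds,
                  tibble::tibble(id = "r1", substrate = "a", product = "a")),
    "self-loop")
  expect_error(
    pathway_graph(t$compounds,
                  tibble::tibble(id = "r1", substrate = "a", product = "zz")),
    "zz")
  expect_error(
    pathway_graph(tibble::tibble(id = "bad", name = "bad", formula = "C6?"),
                  NULL),
    "bad")
  # parallel reactions under distinct ids are allowed
  g <- pathway_graph(t$compounds,
                     tibble::tibble(id = c("r1", "r2"),
                                    substrate = c("a", "a"),
                                    product = c("b", "b")))
  expect_equal(nrow(g$reactions), 2)
})

test_that("carbon-free compounds are excluded and edges to them become integrity errors", {
  compounds <- tibble::tibble(id = c("a", "w"), name = c("A", "water"),
                              formula = c("C8H10N4O2", "H2O"))
  # exclusion alone: warning + metadata count
  expect_warning(g <- pathway_graph(compounds, NULL), "carbon-free")
  expect_equal(nrow(g$compounds), 1)
  expect_equal(g$metadata$carbon_free_excluded, 1)
  # an edge referencing the excluded compound now dangles
  expect_warning(
    expect_error(
      pathway_graph(compounds,
                    tibble::tibble(id = "r1", substrate = "a", product = "w")),
      "w"),
    "carbon-free")
})

test_that("pathway write/read round trip preserves ids, edges and formulas", {
  set.seed(5)
  for (i in 1:10) {
    g <- make_random_graph(sample(3:12, 1), sample(0:8, 1), seed = i)
    paths <- write_temp_pathway(g)
    g2 <- read_pathway(paths$compounds, paths$reactions)
    expect_equal(graph_fingerprint(g2), graph_fingerprint(g))
  }
})

test_that("overlay matching is exact and mismatches are reported, not dropped", {
  g <- demo_pathway("caffeine")
  full <- tibble::tibble(compound_id = g$compounds$id,
                         value = seq_len(nrow(g$compounds)) - 7.5)
  ann <- attach_overlay(g, full)
  expect_equal(ann$overlay_report$n_unmatched, 0)
  expect_equal(ann$overlay_report$n_unannotated, 0)
  # mixed-sign numeric values survive exactly, in graph order
  expect_equal(ann$compounds$overlay_value,
               full$value[match(ann$compounds$id, full$compound_id)])

  foreign <- rbind(full[1:3, ],
                   tibble::tibble(compound_id = "nope", value = 1))
  ann2 <- attach_overlay(g, foreign)
  expect_equal(ann2$overlay_report$n_unmatched, 1)
  expect_equal(ann2$overlay_report$unmatched_keys, "nope")
  expect_equal(ann2$overlay_report$n_unannotated, nrow(g$compounds) - 3)

  # categorical values go to overlay_label, numeric detection is by parse
  cat_ov <- attach_overlay(g, demo_overlay())
  expect_false(cat_ov$overlay_report$numeric)
  expect_equal(sum(cat_ov$compounds$overlay_label == "new"), 1)
  num_as_text <- tibble::tibble(compound_id = g$compounds$id[1:2],
                                value = c("-1.5", "2.25"))
  ann3 <- attach_overlay(g, num_as_text)
  expect_true(ann3$overlay_report$numeric)
  expect_equal(sort(ann3$compounds$overlay_value[!is.na(ann3$compounds$overlay_value)]),
               c(-1.5, 2.25))
  expect_error(attach_overlay(g, tibble::tibble(compound_id = character(),
                                                value = numeric())),
               "non-empty")
})

test_that("merging graphs unions nodes/edges and labels provenance", {
  a <- make_random_graph(3, 2, seed = 21)
  b <- make_random_graph(3, 2, seed = 22)
  b$compounds$id <- paste0("b_", b$compounds$id)
  b$reactions$id <- paste0("b_", b$reactions$id)
  b$reactions$substrate <- paste0("b_", b$reactions$substrate)
  b$reactions$product <- paste0("b_", b$reactions$product)

  m <- merge_graphs(a, b, "human", "worm")
  expect_equal(nrow(m$compounds), 6)
  expect_equal(nrow(m$reactions), 4)
  expect_setequal(unique(m$compounds$source), c("human", "worm"))

  # shared id with identical formula collapses to one dual-labeled node
  b2 <- b
  old_id <- b2$compounds$id[1]
  b2$compounds$id[1] <- a$compounds$id[1]
  b2$compounds$formula[1] <- a$compounds$formula[1]
  b2$reactions$substrate[b2$reactions$substrate == old_id] <- a$compounds$id[1]
  b2$reactions$product[b2$reactions$product == old_id] <- a$compounds$id[1]
  m2 <- merge_graphs(a, b2, "human", "worm")
  expect_equal(nrow(m2$compounds), 5)
  shared <- m2$compounds$source[m2$compounds$id == a$compounds$id[1]]
  expect_equal(shared, "human;worm")

  # shared id with conflicting formula is an error naming the id
  b3 <- b
  b3$compounds$id[1] <- a$compounds$id[1]
  b3$compounds$formula[1] <- "C2H6"
  expect_error(merge_graphs(a, b3), a$compounds$id[1])

  # merging with an empty graph is identity up to labels
  empty <- pathway_graph(tibble::tibble(id = character(), name = character(),
                                        formula = character()), NULL)
  me <- merge_graphs(a, empty, "only", "none")
  expect_equal(graph_fingerprint(me), graph_fingerprint(a))
  expect_true(all(me$compounds$source == "only"))
})

test_that("merge is associative up to label sets on small random graphs", {
  set.seed(99)
  for (i in 1:5) {
    gs <- lapply(1:3, function(k) {
      g <- make_random_graph(4, 2, seed = 30 * i + k)
      g$compounds$id <- sprintf("g%d_%s", k, g$compounds$id)
      g$reactions$id <- sprintf("g%d_%s", k, g$reactions$id)
      g$reactions$substrate <- sprintf("g%d_%s", k, g$reactions$substrate)
      g$reactions$product <- sprintf("g%d_%s", k, g$reactions$product)
      # one shared compound across all three
      g$compounds$id[1] <- "shared"
      g$compounds$formula[1] <- "C6H12O6"
      g$reactions$substrate[g$reactions$substrate == sprintf("g%d_cpd_001", k)] <- "shared"
      g$reactions$product[g$reactions$product == sprintf("g%d_cpd_001", k)] <- "shared"
      pathway_graph(g$compounds[, c("id", "name", "formula")],
                    g$reactions[, c("id", "substrate", "product", "reversible")])
    })
    left <- merge_graphs(merge_graphs(gs[[1]], gs[[2]], "a", "b"), gs[[3]],
                         "ab", "c")
    right <- merge_graphs(gs[[1]], merge_graphs(gs[[2]], gs[[3]], "b", "c"),
                          "a", "bc")
    expect_equal(graph_fingerprint(left), graph_fingerprint(right))
  }
})
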