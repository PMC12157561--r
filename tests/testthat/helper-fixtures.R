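# Shared test helpers: in-code generators for random element counts and tiny
# pathway tables. Kept independent of the package's own random-graph
# generator where they serve as oracles against it.

# Random CHNOPS counts as a plain named vector (oracle side: no package
# types involved until the test converts them).
random_chnops <- function() {
  n_c <- sample(1:40, 1)
  counts <- c(C = n_c, H = sample(1:(2 * n_c + 2), 1))
  for (el in c("N", "O", "P", "S")) {
    if (runif(1) < 0.6) counts[el] <- sample(1:max(1, n_c), 1)
  }
  counts
}

# Random counts that sometimes include isotope-qualified species, for
# round-trip tests of the parser/serializer.
random_counts_iso <- function() {
  counts <- random_chnops()
  if (runif(1) < 0.3) counts["D"] <- sample(1:3, 1)
  if (runif(1) < 0.3) counts["[13C]"] <- sample(1:3, 1)
  if (runif(1) < 0.2) counts["[15N]"] <- 1
  counts
}

# Write a pathway_graph's tables to tempfiles; returns the two paths.
write_temp_pathway <- function(graph) {
  cf <- withr::local_tempfile(fileext = ".tsv", .local_envir = parent.frame())
  rf <- withr::local_tempfile(fileext = ".tsv", .local_envir = parent.frame())
  write_pathway(graph, cf, rf)
  list(compounds = cf, reactions = rf)
}

# Structural fingerprint of a graph, ignoring dataset-of-origin labels.
graph_fingerprint <- function(g) {
  list(
    compounds = g$compounds[order(g$compounds$id),
                            c("id", "formula", "hc", "oc", "nc", "nops_c")],
    reactions = g$reactions[order(g$reactions$id),
                            c("id", "substrate", "product", "reversible")]
  )
}

# A layout_result holding k nodes at one exact polar position, built through
# the public API (k compounds sharing one formula).
coincident_layout <- function(k, formula = "C6H6N4O2", config = layout_config()) {
  g <- pathway_graph(
    tibble::tibble(id = sprintf("iso%02d", seq_len(k)),
                   name = sprintf("isomer %d", seq_len(k)),
                   formula = rep(formula, k))
  )
  polar_layout(g, config)
}

svg_nodes <- function(path, xpath) {
  doc <- xml2::read_xml(path)
  xml2::xml_find_all(doc, xpath, ns = c(svg = "http://www.w3.org/2000/svg"))
}
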