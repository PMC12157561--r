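# Synthetic pathway generators. These produce the chemical motifs the
# circular layout is designed to reveal — demethylation chains walking down
# in H:C, homologous series converging toward H:C = 2 — plus seeded random
# graphs for property testing. All emit ordinary pathway_graph objects and
# therefore the same two-table text format the readers consume.

counts_to_named <- function(counts) {
  stats::setNames(as.integer(counts), names(counts))
}

#' Generate a demethylation chain
#'
#' A linear degradation pathway in which each step removes one CH2 unit
#' (a methyl group replaced by hydrogen): step *i* has counts `C - i`,
#' `H - 2i` relative to the start. Such chains descend in H:C whenever the
#' starting H:C exceeds 2; the realized trend is computed from the generated
#' formulas, not assumed, and recorded in
#' `metadata$hc_monotone_decreasing`.
#'
#' @param start_counts [element_count()] of the chain head. Must have at
#'   least `n_steps + 1` carbons and `2 * n_steps + 1` hydrogens.
#' @param n_steps Number of removal steps (0 gives a single-node graph).
#' @param id_prefix Prefix for generated compound/reaction ids.
#' @return A [pathway_graph()] of `n_steps + 1` compounds chained by
#'   directed edges along the degradation.
#' @export
#' @examples
#' make_demethylation_chain(element_count(C = 8, H = 10, N = 4, O = 2), 2)
make_demethylation_chain <- function(start_counts, n_steps,
                                     id_prefix = "demeth") {
  if (!inherits(start_counts, "element_count")) {
    start_counts <- element_count(start_counts)
  }
  n_steps <- as.integer(n_steps)
  stopifnot(n_steps >= 0)
  base <- counts_to_named(start_counts)
  if (is.na(base["C"]) || base["C"] < n_steps + 1) {
    stop("start formula needs at least n_steps + 1 carbons", call. = FALSE)
  }
  if (is.na(base["H"]) || base["H"] < 2 * n_steps + 1) {
    stop("start formula needs at least 2 * n_steps + 1 hydrogens",
         call. = FALSE)
  }
  formulas <- vapply(0:n_steps, function(i) {
    cc <- base
    cc["C"] <- cc["C"] - i
    cc["H"] <- cc["H"] - 2L * i
    to_hill_notation(element_count(cc[cc > 0]))
  }, character(1))
  ids <- sprintf("%s_%02d", id_prefix, 0:n_steps)
  compounds <- tibble::tibble(id = ids, name = formulas, formula = formulas)
  reactions <- if (n_steps > 0) {
    tibble::tibble(id = sprintf("%s_r%02d", id_prefix, seq_len(n_steps)),
                   substrate = ids[seq_len(n_steps)],
                   product = ids[seq_len(n_steps) + 1],
                   reversible = FALSE)
  } else NULL
  g <- pathway_graph(compounds, reactions,
                     metadata = list(name = "demethylation chain",
                                     kind = "demethylation_chain"))
  hc <- g$compounds$hc[match(ids, g$compounds$id)]
  g$metadata$hc_monotone_decreasing <- all(diff(hc) < 0)
  g
}

#' Generate a homologous series
#'
#' Compounds differing by a repeated chain unit (CH2 by default), as in
#' fatty-acid or lipid families: member *j* is `head + j * unit`, chained by
#' elongation edges. On the circular map a CH2 series traces a regular arc
#' whose H:C approaches 2 from the head's value.
#'
#' @param head_counts [element_count()] of the first member.
#' @param n_members Number of members (>= 1).
#' @param unit Increment per step, default CH2.
#' @param id_prefix Prefix for generated ids.
#' @return A [pathway_graph()].
#' @export
#' @examples
#' make_homologous_series(element_count(C = 16, H = 32, O = 2), 5)
make_homologous_series <- function(head_counts, n_members,
                                   unit = element_count(C = 1, H = 2),
                                   id_prefix = "series") {
  if (!inherits(head_counts, "element_count")) {
    head_counts <- element_count(head_counts)
  }
  if (!inherits(unit, "element_count")) unit <- element_count(unit)
  n_members <- as.integer(n_members)
  stopifnot(n_members >= 1)
  u <- counts_to_named(unit)
  formulas <- vapply(0:(n_members - 1), function(j) {
    cc <- counts_to_named(head_counts)
    for (sym in names(u)) {
      cc[sym] <- if (is.na(cc[sym])) j * u[[sym]] else cc[[sym]] + j * u[[sym]]
    }
    to_hill_notation(element_count(cc[cc > 0]))
  }, character(1))
  ids <- sprintf("%s_%02d", id_prefix, seq_len(n_members))
  compounds <- tibble::tibble(id = ids, name = formulas, formula = formulas)
  reactions <- if (n_members > 1) {
    tibble::tibble(id = sprintf("%s_r%02d", id_prefix, seq_len(n_members - 1)),
                   substrate = ids[seq_len(n_members - 1)],
                   product = ids[seq_len(n_members - 1) + 1],
                   reversible = FALSE)
  } else NULL
  pathway_graph(compounds, reactions,
                metadata = list(name = "homologous series",
                                kind = "homologous_series",
                                unit = to_hill_notation(unit)))
}

#' Generate a seeded random pathway graph
#'
#' Random CHNOPS formulas constrained to plausible elemental ranges
#' (`H <= 2C + 2`, each heteroatom `<= C`) and random simple directed edges.
#' Fully deterministic for a fixed seed; the caller's RNG state is left
#' untouched.
#'
#' @param n_compounds Number of compounds (>= 1).
#' @param n_edges Number of directed edges, at most
#'   `n_compounds * (n_compounds - 1)`.
#' @param carbon_range Length-2 integer range for carbon counts.
#' @param seed Integer seed.
#' @return A [pathway_graph()].
#' @export
make_random_graph <- function(n_compounds, n_edges = 0,
                              carbon_range = c(3, 30), seed = 1L) {
  n_compounds <- as.integer(n_compounds)
  n_edges <- as.integer(n_edges)
  stopifnot(n_compounds >= 1, n_edges >= 0)
  if (n_edges > n_compounds * (n_compounds - 1)) {
    stop("n_edges exceeds the number of possible simple directed edges",
         call. = FALSE)
  }
  withr::with_seed(seed, {
    formulas <- vapply(seq_len(n_compounds), function(i) {
      to_hill_notation(random_counts(carbon_range))
    }, character(1))
    ids <- sprintf("cpd_%03d", seq_len(n_compounds))
    compounds <- tibble::tibble(
      id = ids, name = ids, formula = formulas)
    reactions <- NULL
    if (n_edges > 0) {
      pairs <- expand.grid(substrate = seq_len(n_compounds),
                           product = seq_len(n_compounds))
      pairs <- pairs[pairs$substrate != pairs$product, , drop = FALSE]
      pick <- pairs[sample.int(nrow(pairs), n_edges), , drop = FALSE]
      reactions <- tibble::tibble(
        id = sprintf("rxn_%03d", seq_len(n_edges)),
        substrate = ids[pick$substrate],
        product = ids[pick$product],
        reversible = FALSE)
    }
    pathway_graph(compounds, reactions,
                  metadata = list(name = "random graph", kind = "random_graph",
                                  seed = seed))
  })
}

random_counts <- function(carbon_range) {
  n_c <- sample(carbon_range[1]:carbon_range[2], 1)
  n_h <- sample.int(2 * n_c + 2, 1)
  counts <- c(C = n_c, H = n_h)
  for (het in c("N", "O", "P", "S")) {
    if (stats::runif(1) < 0.5) {
      counts[het] <- sample.int(max(1, n_c %/% 2), 1)
    }
  }
  element_count(counts)
}
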