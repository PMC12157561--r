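# Hand-curated demonstration pathways. Formulas are standard textbook
# chemistry; the edge sets are illustrative simplifications intended for
# demos and tests, not curated biochemical reference networks.

#' Built-in demonstration pathways
#'
#' Two small illustrative pathways:
#'
#' * `"caffeine"` — human caffeine degradation: successive demethylations
#'   (caffeine to the dimethyl- and monomethylxanthines down to xanthine)
#'   and oxidations to the uric acids, 14 compounds. Demethylation removes
#'   methyl groups that are hydrogen-rich relative to the purine core, so
#'   the chain steps down in H:C — the motif the circular layout displays as
#'   an inward-ordered sweep. Includes 1,3,7-trimethyldihydrouric acid, a
#'   recently described human caffeine metabolite, as the customary
#'   highlight target.
#' * `"aminosugar"` — aminosugar metabolism around UDP-N-acetylglucosamine,
#'   11 compounds, including an isomer pair (N-acetylglucosamine /
#'   N-acetylmannosamine, both C8H15NO6) that exercises cohabitant-node
#'   overlap resolution.
#'
#' @param name Which pathway to build.
#' @param masses Mass table, see [default_mass_table()].
#' @return A [pathway_graph()].
#' @export
#' @examples
#' demo_pathway("caffeine")
demo_pathway <- function(name = c("caffeine", "aminosugar"),
                         masses = default_mass_table()) {
  name <- match.arg(name)
  tabs <- if (name == "caffeine") caffeine_tables() else aminosugar_tables()
  pathway_graph(tabs$compounds, tabs$reactions, masses = masses,
                metadata = list(name = paste(name, "demo pathway"),
                                source = "polarvk built-in demo (illustrative)"))
}

caffeine_tables <- function() {
  compounds <- tibble::tribble(
    ~id,     ~name,                              ~formula,
    "caf",   "caffeine",                         "C8H10N4O2",
    "px",    "paraxanthine",                     "C7H8N4O2",
    "tb",    "theobromine",                      "C7H8N4O2",
    "tp",    "theophylline",                     "C7H8N4O2",
    "1mx",   "1-methylxanthine",                 "C6H6N4O2",
    "3mx",   "3-methylxanthine",                 "C6H6N4O2",
    "7mx",   "7-methylxanthine",                 "C6H6N4O2",
    "x",     "xanthine",                         "C5H4N4O2",
    "1mu",   "1-methyluric acid",                "C6H6N4O3",
    "13dmu", "1,3-dimethyluric acid",            "C7H8N4O3",
    "17dmu", "1,7-dimethyluric acid",            "C7H8N4O3",
    "ua",    "uric acid",                        "C5H4N4O3",
    "tmu",   "1,3,7-trimethyluric acid",         "C8H10N4O3",
    "tmdu",  "1,3,7-trimethyldihydrouric acid",  "C8H12N4O3"
  )
  reactions <- tibble::tribble(
    ~id,    ~substrate, ~product,
    "r01",  "caf",      "px",
    "r02",  "caf",      "tb",
    "r03",  "caf",      "tp",
    "r04",  "caf",      "tmu",
    "r05",  "tmu",      "tmdu",
    "r06",  "px",       "1mx",
    "r07",  "px",       "7mx",
    "r08",  "px",       "17dmu",
    "r09",  "tb",       "3mx",
    "r10",  "tb",       "7mx",
    "r11",  "tp",       "1mx",
    "r12",  "tp",       "13dmu",
    "r13",  "1mx",      "1mu",
    "r14",  "3mx",      "x",
    "r15",  "7mx",      "x",
    "r16",  "x",        "ua"
  )
  list(compounds = compounds, reactions = reactions)
}

aminosugar_tables <- function() {
  compounds <- tibble::tribble(
    ~id,       ~name,                               ~formula,
    "f6p",     "fructose 6-phosphate",              "C6H13O9P",
    "gln",     "glutamine",                         "C5H10N2O3",
    "glu",     "glutamate",                         "C5H9NO4",
    "glcn",    "glucosamine",                       "C6H13NO5",
    "glcn6p",  "glucosamine 6-phosphate",           "C6H14NO8P",
    "glcnac",  "N-acetylglucosamine",               "C8H15NO6",
    "glcnac6p","N-acetylglucosamine 6-phosphate",   "C8H16NO9P",
    "glcnac1p","N-acetylglucosamine 1-phosphate",   "C8H16NO9P",
    "udpglcnac","UDP-N-acetylglucosamine",          "C17H27N3O17P2",
    "mannac",  "N-acetylmannosamine",               "C8H15NO6",
    "neu5ac",  "N-acetylneuraminate",               "C11H19NO9"
  )
  reactions <- tibble::tribble(
    ~id,    ~substrate,  ~product,   ~reversible,
    "r01",  "f6p",       "glcn6p",   FALSE,
    "r02",  "gln",       "glu",      FALSE,
    "r03",  "glcn6p",    "glcnac6p", FALSE,
    "r04",  "glcnac6p",  "glcnac1p", TRUE,
    "r05",  "glcnac1p",  "udpglcnac", FALSE,
    "r06",  "udpglcnac", "mannac",   FALSE,
    "r07",  "mannac",    "neu5ac",   FALSE,
    "r08",  "glcnac",    "glcnac6p", FALSE,
    "r09",  "glcn",      "glcn6p",   FALSE,
    "r10",  "glcnac",    "glcn",     FALSE
  )
  list(compounds = compounds, reactions = reactions)
}

#' Example overlay for the caffeine demo
#'
#' A small illustrative overlay marking the recently identified metabolite
#' (1,3,7-trimethyldihydrouric acid) as `"new"` and everything else as
#' `"known"` — the highlight-one-node styling case.
#'
#' @return A tibble with columns `compound_id`, `value`.
#' @export
demo_overlay <- function() {
  g <- demo_pathway("caffeine")
  tibble::tibble(
    compound_id = g$compounds$id,
    value = ifelse(g$compounds$id == "tmdu", "new", "known")
  )
}
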