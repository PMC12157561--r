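# Pathway graphs: compounds as nodes, reactions as directed edges, plus
# optional per-compound overlays. A pathway_graph is a light S3 container
# over two tibbles; all constructors validate referential integrity.

#' Construct a pathway graph
#'
#' @param compounds Data frame with columns `id`, `name`, `formula` (name may
#'   be missing or NA). Elemental ratios are computed and cached per compound;
#'   carbon-free compounds are excluded with a warning and counted in
#'   `metadata$carbon_free_excluded`.
#' @param reactions Data frame with columns `id`, `substrate`, `product` and
#'   optionally `reversible` (logical, default `FALSE`). Substrate and product
#'   must be compound ids present in `compounds`; self-loops and duplicate
#'   reaction ids are rejected.
#' @param masses Mass table used for all cached ratios.
#' @param metadata Named list of free-form annotations (pathway name, source).
#' @return A `pathway_graph`.
#' @export
#' @examples
#' pathway_graph(
#'   data.frame(id = c("a", "b"), name = c("A", "B"),
#'              formula = c("C8H10N4O2", "C7H8N4O2")),
#'   data.frame(id = "r1", substrate = "a", product = "b")
#' )
pathway_graph <- function(compounds, reactions = NULL,
                          masses = default_mass_table(), metadata = list()) {
  compounds <- tibble::as_tibble(compounds)
  need <- setdiff(c("id", "formula"), names(compounds))
  if (length(need) > 0) {
    stop("compound table is missing required column(s): ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  if (!"name" %in% names(compounds)) compounds$name <- compounds$id
  compounds$name[is.na(compounds$name)] <- compounds$id[is.na(compounds$name)]
  if (anyDuplicated(compounds$id)) {
    stop("duplicate compound id(s): ",
         paste(unique(compounds$id[duplicated(compounds$id)]), collapse = ", "),
         call. = FALSE)
  }

  # parse every formula and cache ratios; collect carbon-free ids
  ratios <- vector("list", nrow(compounds))
  carbon_free <- character(0)
  for (i in seq_len(nrow(compounds))) {
    counts <- tryCatch(parse_formula(compounds$formula[i]),
      polarvk_parse_error = function(e) {
        stop("compound ", compounds$id[i], ": ", conditionMessage(e),
             call. = FALSE)
      })
    rs <- tryCatch(compute_ratios(counts, masses),
                   polarvk_carbon_free = function(e) NULL)
    if (is.null(rs)) {
      carbon_free <- c(carbon_free, compounds$id[i])
    } else {
      compounds$formula[i] <- to_hill_notation(counts)  # canonical form
      ratios[[i]] <- rs
    }
  }
  if (length(carbon_free) > 0) {
    warning("excluded ", length(carbon_free), " carbon-free compound(s): ",
            paste(carbon_free, collapse = ", "), call. = FALSE)
    keep <- !compounds$id %in% carbon_free
    compounds <- compounds[keep, , drop = FALSE]
    ratios <- ratios[keep]
  }
  metadata$carbon_free_excluded <- length(carbon_free)
  compounds$hc <- vapply(ratios, function(r) r$hc, double(1))
  compounds$oc <- vapply(ratios, function(r) r$oc, double(1))
  compounds$nc <- vapply(ratios, function(r) r$nc, double(1))
  compounds$nops_c <- vapply(ratios, function(r) r$nops_c, double(1))

  if (is.null(reactions) || nrow(tibble::as_tibble(reactions)) == 0) {
    reactions <- tibble::tibble(id = character(), substrate = character(),
                                product = character(), reversible = logical())
  }
  reactions <- tibble::as_tibble(reactions)
  need <- setdiff(c("id", "substrate", "product"), names(reactions))
  if (length(need) > 0) {
    stop("reaction table is missing required column(s): ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  if (!"reversible" %in% names(reactions)) reactions$reversible <- FALSE
  reactions$reversible <- parse_logical_column(reactions$reversible)
  if (anyDuplicated(reactions$id)) {
    stop("duplicate reaction id(s): ",
         paste(unique(reactions$id[duplicated(reactions$id)]), collapse = ", "),
         call. = FALSE)
  }
  loops <- reactions$id[reactions$substrate == reactions$product]
  if (length(loops) > 0) {
    stop("self-loop reaction(s) rejected: ", paste(loops, collapse = ", "),
         call. = FALSE)
  }
  dangling <- unique(c(
    setdiff(reactions$substrate, compounds$id),
    setdiff(reactions$product, compounds$id)
  ))
  if (length(dangling) > 0) {
    stop("reaction endpoint(s) not in compound table: ",
         paste(dangling, collapse = ", "), call. = FALSE)
  }

  structure(
    list(compounds = compounds,
         reactions = reactions[, c("id", "substrate", "product", "reversible")],
         masses = masses, metadata = metadata),
    class = "pathway_graph"
  )
}

parse_logical_column <- function(x) {
  if (is.logical(x)) return(ifelse(is.na(x), FALSE, x))
  lx <- tolower(as.character(x))
  out <- lx %in% c("true", "t", "1", "yes")
  out
}

#' @export
print.pathway_graph <- function(x, ...) {
  cat(sprintf("<pathway_graph> %d compounds, %d reactions", nrow(x$compounds),
              nrow(x$reactions)))
  if (!is.null(x$metadata$name)) cat(" —", x$metadata$name)
  cat("\n")
  if (x$metadata$carbon_free_excluded > 0) {
    cat("  carbon-free compounds excluded:", x$metadata$carbon_free_excluded, "\n")
  }
  if (any(c("overlay_value", "overlay_label") %in% names(x$compounds))) {
    cat("  overlay attached\n")
  }
  invisible(x)
}

#' Read a pathway from two delimited tables
#'
#' @param compound_file Tab-separated file with columns `id`, `name`,
#'   `formula` (UTF-8, header row).
#' @param reaction_file Tab-separated file with columns `id`, `substrate`,
#'   `product` and optionally `reversible`.
#' @param masses Mass table, see [default_mass_table()].
#' @return A validated [pathway_graph()] with ratios precomputed.
#' @export
read_pathway <- function(compound_file, reaction_file,
                         masses = default_mass_table()) {
  compounds <- read_tsv_strict(compound_file, c("id", "formula"))
  reactions <- read_tsv_strict(reaction_file, c("id", "substrate", "product"))
  g <- pathway_graph(compounds, reactions, masses = masses)
  g$metadata$source <- c(compounds = compound_file, reactions = reaction_file)
  g
}

#' Write a pathway to the two-table format
#'
#' Inverse of [read_pathway()]: re-reading the written tables yields an
#' isomorphic graph (same ids, edges, canonical formulas).
#'
#' @param graph A [pathway_graph()].
#' @param compound_file,reaction_file Output paths.
#' @return `graph`, invisibly.
#' @export
write_pathway <- function(graph, compound_file, reaction_file) {
  stopifnot(inherits(graph, "pathway_graph"))
  readr::write_tsv(graph$compounds[, c("id", "name", "formula")], compound_file)
  readr::write_tsv(graph$reactions, reaction_file)
  invisible(graph)
}

#' Attach a quantitative or categorical overlay
#'
#' Maps per-compound values (e.g. log fold changes) or labels (e.g.
#' dataset-of-origin) onto graph nodes for the renderer. Keys that do not
#' match a compound id are never silently dropped: they are counted and
#' listed in the attached report.
#'
#' @param graph A [pathway_graph()].
#' @param overlay A data frame with columns `compound_id`, `value`, a named
#'   vector (names = compound ids), or the path of a two-column tab-separated
#'   file. Values are treated as numeric when every non-missing value parses
#'   as a number, categorical otherwise.
#' @return The annotated graph. Numeric overlays land in
#'   `$compounds$overlay_value`, categorical ones in `$compounds$overlay_label`;
#'   the match report is in `$overlay_report` (fields `unmatched_keys`,
#'   `n_unmatched`, `unannotated_ids`, `n_unannotated`).
#' @export
attach_overlay <- function(graph, overlay) {
  stopifnot(inherits(graph, "pathway_graph"))
  if (is.character(overlay) && length(overlay) == 1 && file.exists(overlay)) {
    overlay <- read_tsv_strict(overlay, c("compound_id", "value"))
  }
  if (!is.null(names(overlay)) && is.atomic(overlay)) {
    overlay <- tibble::tibble(compound_id = names(overlay),
                              value = unname(overlay))
  }
  overlay <- tibble::as_tibble(overlay)
  if (!all(c("compound_id", "value") %in% names(overlay)) || nrow(overlay) == 0) {
    stop("overlay must be non-empty with columns compound_id and value",
         call. = FALSE)
  }
  vals <- overlay$value
  suppressWarnings(num <- as.numeric(as.character(vals)))
  numeric_overlay <- !anyNA(num[!is.na(vals)])

  matched <- overlay$compound_id %in% graph$compounds$id
  idx <- match(graph$compounds$id, overlay$compound_id)
  if (numeric_overlay) {
    graph$compounds$overlay_value <- num[idx]
  } else {
    graph$compounds$overlay_label <- as.character(vals)[idx]
  }
  unannotated <- graph$compounds$id[is.na(idx)]
  report <- list(
    unmatched_keys = overlay$compound_id[!matched],
    n_unmatched = sum(!matched),
    unannotated_ids = unannotated,
    n_unannotated = length(unannotated),
    numeric = numeric_overlay
  )
  graph$overlay_report <- report
  graph
}

#' Merge two pathway graphs
#'
#' Union of compounds and reactions for cross-dataset comparison. Compounds
#' sharing an id must share a formula (conflicts are an error naming the id)
#' and become a single node tagged with both dataset labels; every node and
#' edge carries a `source` label usable by the renderer as a categorical
#' overlay.
#'
#' @param a,b Graphs built with the same mass table.
#' @param label_a,label_b Dataset-of-origin labels.
#' @return A merged [pathway_graph()] whose `compounds$source` and
#'   `reactions$source` hold semicolon-joined label sets.
#' @export
merge_graphs <- function(a, b, label_a = "a", label_b = "b") {
  stopifnot(inherits(a, "pathway_graph"), inherits(b, "pathway_graph"))
  if (!identical(a$masses, b$masses)) {
    stop("graphs must share the same mass table", call. = FALSE)
  }
  ca <- a$compounds; cb <- b$compounds
  ca$source <- if (!"source" %in% names(ca)) label_a
               else paste_labels(ca$source, rep(label_a, nrow(ca)))
  cb$source <- if (!"source" %in% names(cb)) label_b
               else paste_labels(cb$source, rep(label_b, nrow(cb)))

  shared <- intersect(ca$id, cb$id)
  for (id in shared) {
    fa <- ca$formula[ca$id == id]; fb <- cb$formula[cb$id == id]
    if (!identical(fa, fb)) {
      stop("compound id ", id, " has conflicting formulas: ", fa, " vs ", fb,
           call. = FALSE)
    }
  }
  keep_cols <- union(names(ca), names(cb))
  ca <- fill_missing_cols(ca, keep_cols); cb <- fill_missing_cols(cb, keep_cols)
  merged_c <- ca
  for (id in shared) {
    merged_c$source[merged_c$id == id] <-
      paste_labels(ca$source[ca$id == id], cb$source[cb$id == id])
  }
  merged_c <- rbind(merged_c, cb[!cb$id %in% shared, keep_cols, drop = FALSE])

  ra <- a$reactions; rb <- b$reactions
  ra$source <- if (!"source" %in% names(ra)) label_a
               else paste_labels(ra$source, rep(label_a, nrow(ra)))
  rb$source <- if (!"source" %in% names(rb)) label_b
               else paste_labels(rb$source, rep(label_b, nrow(rb)))
  shared_r <- intersect(ra$id, rb$id)
  for (id in shared_r) {
    ea <- ra[ra$id == id, c("substrate", "product")]
    eb <- rb[rb$id == id, c("substrate", "product")]
    if (!identical(as.list(ea), as.list(eb))) {
      stop("reaction id ", id, " has conflicting endpoints across graphs",
           call. = FALSE)
    }
    ra$source[ra$id == id] <- paste_labels(ra$source[ra$id == id],
                                           rb$source[rb$id == id])
  }
  merged_r <- rbind(ra, rb[!rb$id %in% shared_r, , drop = FALSE])

  meta <- utils::modifyList(a$metadata, b$metadata)
  meta$carbon_free_excluded <- a$metadata$carbon_free_excluded +
    b$metadata$carbon_free_excluded
  out <- pathway_graph(
    merged_c[, c("id", "name", "formula")], merged_r[, c("id", "substrate",
    "product", "reversible")], masses = a$masses, metadata = meta)
  out$compounds$source <- merged_c$source[match(out$compounds$id, merged_c$id)]
  out$reactions$source <- merged_r$source[match(out$reactions$id, merged_r$id)]
  for (col in c("overlay_value", "overlay_label")) {
    if (col %in% names(merged_c)) {
      out$compounds[[col]] <- merged_c[[col]][match(out$compounds$id, merged_c$id)]
    }
  }
  out
}

paste_labels <- function(a, b) {
  vapply(seq_along(a), function(i) {
    paste(unique(c(strsplit(a[i], ";")[[1]], strsplit(b[i], ";")[[1]])),
          collapse = ";")
  }, character(1))
}

fill_missing_cols <- function(tab, cols) {
  for (col in setdiff(cols, names(tab))) tab[[col]] <- NA
  tab[, cols, drop = FALSE]
}
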