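# Chemical formula parsing and elemental-ratio computation.
#
# A formula string is parsed into an `element_count`: a named integer vector
# mapping element symbols (optionally isotope-qualified, e.g. "[13C]", "D")
# to positive atom counts. Ratios derived from those counts define the
# coordinate system of the whole package.

IUPAC_SYMBOLS <- c(
  "H", "He", "Li", "Be", "B", "C", "N", "O", "F", "Ne", "Na", "Mg", "Al",
  "Si", "P", "S", "Cl", "Ar", "K", "Ca", "Sc", "Ti", "V", "Cr", "Mn", "Fe",
  "Co", "Ni", "Cu", "Zn", "Ga", "Ge", "As", "Se", "Br", "Kr", "Rb", "Sr",
  "Y", "Zr", "Nb", "Mo", "Tc", "Ru", "Rh", "Pd", "Ag", "Cd", "In", "Sn",
  "Sb", "Te", "I", "Xe", "Cs", "Ba", "La", "Ce", "Pr", "Nd", "Pm", "Sm",
  "Eu", "Gd", "Tb", "Dy", "Ho", "Er", "Tm", "Yb", "Lu", "Hf", "Ta", "W",
  "Re", "Os", "Ir", "Pt", "Au", "Hg", "Tl", "Pb", "Bi", "Po", "At", "Rn",
  "Fr", "Ra", "Ac", "Th", "Pa", "U", "Np", "Pu", "Am", "Cm", "Bk", "Cf",
  "Es", "Fm", "Md", "No", "Lr", "Rf", "Db", "Sg", "Bh", "Hs", "Mt", "Ds",
  "Rg", "Cn", "Nh", "Fl", "Mc", "Lv", "Ts", "Og"
)

# "D" and "T" are accepted as isotope-qualified hydrogen (mass 2 and 3).
ISOTOPE_SHORTHAND <- c(D = "H", T = "H")

#' Default nominal mass table
#'
#' Nominal integer masses used by the mass-weighted NOPS:C ratio:
#' C = 12, H = 1, N = 14, O = 16, P = 31, S = 32, with deuterium (D = 2)
#' and tritium (T = 3). Isotope-qualified symbols written in bracket form
#' (e.g. `"[13C]"`) need no table entry: their mass number is read from the
#' symbol itself. Pass a modified copy to [compute_ratios()] to substitute
#' other weights (for instance exact monoisotopic masses).
#'
#' @return Named numeric vector of symbol -> nominal mass.
#' @export
#' @examples
#' default_mass_table()
default_mass_table <- function() {
  c(C = 12, H = 1, N = 14, O = 16, P = 31, S = 32, D = 2, T = 3)
}

# Parent element of a (possibly isotope-qualified) symbol: "[13C]" -> "C",
# "D" -> "H", "Fe" -> "Fe".
parent_element <- function(symbols) {
  out <- symbols
  iso <- grepl("^\\[[0-9]+[A-Za-z]+\\]$", symbols)
  out[iso] <- sub("^\\[[0-9]+([A-Za-z]+)\\]$", "\\1", symbols[iso])
  short <- out %in% names(ISOTOPE_SHORTHAND)
  out[short] <- ISOTOPE_SHORTHAND[out[short]]
  out
}

# Mass number carried by the symbol itself, NA for plain symbols.
symbol_mass_number <- function(symbols) {
  out <- rep(NA_real_, length(symbols))
  iso <- grepl("^\\[[0-9]+[A-Za-z]+\\]$", symbols)
  out[iso] <- as.numeric(sub("^\\[([0-9]+).*$", "\\1", symbols[iso]))
  out[symbols == "D"] <- 2
  out[symbols == "T"] <- 3
  out
}

valid_symbol <- function(symbols) {
  parent_element(symbols) %in% IUPAC_SYMBOLS
}

hill_order <- function(symbols) {
  parent <- parent_element(symbols)
  mass <- symbol_mass_number(symbols)
  mass[is.na(mass)] <- 0  # plain symbol sorts before its isotopes
  if ("C" %in% parent) {
    rank <- match(parent, c("C", "H"))
    rank[is.na(rank)] <- 3L
  } else {
    rank <- rep(3L, length(parent))
  }
  order(rank, parent, mass)
}

new_element_count <- function(counts) {
  counts <- counts[hill_order(names(counts))]
  storage.mode(counts) <- "integer"
  structure(counts, class = "element_count")
}

#' Construct an element count
#'
#' @param ... Atom counts named by element symbol (`C = 26, H = 43, N = 1`),
#'   or a single named vector/list. Symbols may be isotope-qualified in
#'   bracket notation (`"[13C]" = 1`) or as `D`/`T` for heavy hydrogen.
#' @return An `element_count`: a named integer vector in Hill order.
#' @export
#' @examples
#' element_count(C = 26, H = 43, N = 1, O = 5)
element_count <- function(...) {
  dots <- list(...)
  if (length(dots) == 1L && is.null(names(dots)) && !is.null(names(dots[[1]]))) {
    dots <- as.list(dots[[1]])
  }
  if (length(dots) == 0L) {
    stop("element_count needs at least one element", call. = FALSE)
  }
  counts <- unlist(dots)
  syms <- names(counts)
  if (is.null(syms) || any(!nzchar(syms))) {
    stop("all counts must be named by element symbol", call. = FALSE)
  }
  bad <- syms[!valid_symbol(syms)]
  if (length(bad) > 0) {
    stop("not a valid element symbol: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(syms)) {
    counts <- tapply(counts, syms, sum)
    counts <- stats::setNames(as.vector(counts), names(counts))
  }
  if (any(counts < 1) || any(counts != round(counts))) {
    stop("atom counts must be positive integers", call. = FALSE)
  }
  new_element_count(counts)
}

#' @export
print.element_count <- function(x, ...) {
  cat("<element_count> ", to_hill_notation(x), "\n", sep = "")
  invisible(x)
}

parse_error <- function(formula, pos, msg) {
  stop(structure(
    class = c("polarvk_parse_error", "error", "condition"),
    list(message = sprintf("cannot parse formula %s at position %d: %s",
                           encodeString(formula, quote = "\""), pos, msg),
         call = NULL)
  ))
}

# Recursive-descent parse of one (sub)formula. `chars` is the character
# vector of the cleaned formula, `pos` the 1-based index to start at.
# Returns list(counts = named numeric, pos = first unconsumed index).
parse_chunk <- function(chars, pos, formula, depth = 0) {
  n <- length(chars)
  counts <- numeric(0)
  add <- function(sym, k) {
    counts[sym] <<- if (sym %in% names(counts)) counts[[sym]] + k else k
  }
  read_count <- function(pos, default = 1) {
    start <- pos
    while (pos <= n && grepl("[0-9]", chars[pos])) pos <- pos + 1
    if (pos == start) return(list(k = default, pos = pos))
    list(k = as.numeric(paste(chars[start:(pos - 1)], collapse = "")),
         pos = pos)
  }
  while (pos <= n) {
    ch <- chars[pos]
    if (ch == ")") {
      if (depth == 0) parse_error(formula, pos, "unmatched ')'")
      return(list(counts = counts, pos = pos))
    } else if (ch == "(") {
      inner <- parse_chunk(chars, pos + 1, formula, depth + 1)
      if (inner$pos > n || chars[inner$pos] != ")") {
        parse_error(formula, pos, "unclosed '('")
      }
      mult <- read_count(inner$pos + 1)
      if (mult$k < 1) parse_error(formula, inner$pos + 1, "zero group multiplier")
      for (sym in names(inner$counts)) add(sym, inner$counts[[sym]] * mult$k)
      pos <- mult$pos
    } else if (ch == "[") {
      close <- pos + 1
      while (close <= n && chars[close] != "]") close <- close + 1
      if (close > n) parse_error(formula, pos, "unclosed '['")
      token <- paste(chars[pos:close], collapse = "")
      if (!grepl("^\\[[0-9]+[A-Z][a-z]?\\]$", token) || !valid_symbol(token)) {
        parse_error(formula, pos, sprintf("invalid isotope token '%s'", token))
      }
      cnt <- read_count(close + 1)
      if (cnt$k < 1) parse_error(formula, close + 1, "zero atom count")
      add(token, cnt$k)
      pos <- cnt$pos
    } else if (grepl("[A-Z]", ch)) {
      sym <- ch
      if (pos + 1 <= n && grepl("[a-z]", chars[pos + 1])) {
        two <- paste0(ch, chars[pos + 1])
        if (!valid_symbol(two)) {
          parse_error(formula, pos, sprintf("unknown element '%s'", two))
        }
        sym <- two
      }
      if (!valid_symbol(sym)) {
        parse_error(formula, pos, sprintf("unknown element '%s'", sym))
      }
      cnt <- read_count(pos + nchar(sym))
      if (cnt$k < 1) parse_error(formula, pos + nchar(sym), "zero atom count")
      add(sym, cnt$k)
      pos <- cnt$pos
    } else {
      parse_error(formula, pos, sprintf("unexpected character '%s'", ch))
    }
  }
  list(counts = counts, pos = pos)
}

#' Parse a chemical formula string
#'
#' Accepts Hill-style formulas with optional parenthesized groups
#' (`"Ca(NO3)2"`), bracketed isotope tokens (`"[13C]6H12O6"`), deuterium and
#' tritium shorthand (`D`, `T`), and an optional trailing charge annotation
#' (`"+"`, `"2-"`) which is stripped and ignored. Whitespace and underscore
#' decorations (as in model exports, `"C_26_H_43_NO_5_"`) are removed before
#' parsing. Hydrate dots and adduct notation are rejected; normalize adducts
#' before calling.
#'
#' @param formula A single formula string.
#' @return An [element_count()].
#' @export
#' @examples
#' parse_formula("C26H43NO5")
#' parse_formula("Ca(NO3)2")
#' parse_formula("C_26_H_43_NO_5_")
parse_formula <- function(formula) {
  if (!is.character(formula) || length(formula) != 1L || is.na(formula)) {
    parse_error(as.character(formula)[1], 0, "formula must be a single string")
  }
  s <- gsub("[[:space:]_]", "", formula)
  # trailing charge: optional single magnitude digit + sign(s): "+", "2-".
  # NB "NH4+"-style ions are ambiguous under this grammar (the 4 is taken as
  # charge magnitude); write the counts explicitly when the charge is omitted.
  s <- sub("[0-9]?[+-]+$", "", s)
  if (!nzchar(s)) parse_error(formula, 0, "empty formula")
  res <- parse_chunk(strsplit(s, "")[[1]], 1, formula)
  if (res$pos <= nchar(s)) parse_error(formula, res$pos, "trailing input")
  element_count(res$counts)
}

#' Serialize an element count to Hill notation
#'
#' Carbon first, hydrogen second, remaining elements alphabetical; for
#' carbon-free formulas all elements are alphabetical. Counts of 1 are
#' omitted. Isotope-qualified symbols sort with their parent element, plain
#' symbol first then by mass number, so the output re-parses to an identical
#' [element_count()].
#'
#' @param counts An [element_count()] (or named vector coercible to one).
#' @return A formula string.
#' @export
#' @examples
#' to_hill_notation(element_count(O = 5, H = 43, C = 26, N = 1))
to_hill_notation <- function(counts) {
  if (!inherits(counts, "element_count")) counts <- element_count(counts)
  if (length(counts) == 0) stop("empty element count", call. = FALSE)
  paste0(names(counts), ifelse(counts == 1L, "", counts), collapse = "")
}

carbon_free_error <- function(what) {
  stop(structure(
    class = c("polarvk_carbon_free", "error", "condition"),
    list(message = paste0("carbon-free compound: ", what,
                          " (elemental ratios are defined per carbon atom)"),
         call = NULL)
  ))
}

#' Elemental ratios of one compound
#'
#' Computes the ratios that position a compound on a van Krevelen map:
#' `hc` = H:C, `oc` = O:C, `nc` = N:C, and the mass-weighted heteroatom ratio
#' \deqn{NOPS{:}C = \frac{n_N m_N + n_O m_O + n_P m_P + n_S m_S}{n_C m_C}}
#' with nominal masses 14, 16, 31, 32 and 12 by default. Isotope-qualified
#' hydrogen and carbon count toward `hc`'s numerator and the carbon
#' denominators, but contribute their own isotope mass to the mass-weighted
#' terms — which is what makes the metric extensible to isotope tracing.
#'
#' @param counts An [element_count()] containing carbon.
#' @param masses Mass table, see [default_mass_table()].
#' @return A `ratio_set` with fields `hc`, `oc`, `nc`, `nops_c`. Values are
#'   kept at full floating precision; 3-decimal rounding is display-only.
#' @export
#' @examples
#' compute_ratios(parse_formula("C26H43NO5"))
compute_ratios <- function(counts, masses = default_mass_table()) {
  if (!inherits(counts, "element_count")) counts <- element_count(counts)
  syms <- names(counts)
  parent <- parent_element(syms)
  mass_of <- function(i) {
    s <- syms[i]
    if (s %in% names(masses)) return(masses[[s]])
    m <- symbol_mass_number(s)
    if (!is.na(m)) return(m)
    stop("no mass known for symbol ", s, call. = FALSE)
  }
  n_c <- sum(counts[parent == "C"])
  if (n_c == 0) carbon_free_error(to_hill_notation(counts))
  n_h <- sum(counts[parent == "H"])
  n_o <- sum(counts[parent == "O"])
  n_n <- sum(counts[parent == "N"])
  num <- 0
  for (i in which(parent %in% c("N", "O", "P", "S"))) {
    num <- num + counts[[i]] * mass_of(i)
  }
  den <- 0
  for (i in which(parent == "C")) den <- den + counts[[i]] * mass_of(i)
  structure(
    list(hc = n_h / n_c, oc = n_o / n_c, nc = n_n / n_c, nops_c = num / den),
    class = "ratio_set"
  )
}

#' @export
print.ratio_set <- function(x, ...) {
  cat(sprintf("<ratio_set> H:C %.3f  O:C %.3f  N:C %.3f  NOPS:C %.3f\n",
              x$hc, x$oc, x$nc, x$nops_c))
  invisible(x)
}

#' Batch ratio table
#'
#' Computes elemental ratios for a table of compounds. Carbon-free compounds
#' (e.g. water) are skipped with a warning — the coordinate system is defined
#' per carbon atom — and unparsable formulas raise an error naming the
#' compound id.
#'
#' @param input Either a data frame with columns `compound_id` and `formula`,
#'   or the path of a tab-separated file with those columns (UTF-8, header).
#' @param output Optional path; when given, the result is also written as a
#'   tab-separated table.
#' @param masses Mass table, see [default_mass_table()].
#' @return A tibble with columns `compound_id`, `formula`, `hc`, `oc`, `nc`,
#'   `nops_c`.
#' @export
#' @examples
#' tabulate_ratios(data.frame(compound_id = "caw", formula = "C26H43NO5"))
tabulate_ratios <- function(input, output = NULL, masses = default_mass_table()) {
  tab <- if (is.character(input)) read_tsv_strict(input, c("compound_id", "formula"))
         else tibble::as_tibble(input)
  if (!all(c("compound_id", "formula") %in% names(tab))) {
    stop("input must have columns compound_id and formula", call. = FALSE)
  }
  rows <- lapply(seq_len(nrow(tab)), function(i) {
    counts <- tryCatch(parse_formula(tab$formula[i]), polarvk_parse_error = function(e) {
      stop("compound ", tab$compound_id[i], ": ", conditionMessage(e),
           call. = FALSE)
    })
    rs <- tryCatch(compute_ratios(counts, masses),
                   polarvk_carbon_free = function(e) NULL)
    if (is.null(rs)) return(NULL)
    tibble::tibble(compound_id = tab$compound_id[i], formula = tab$formula[i],
                   hc = rs$hc, oc = rs$oc, nc = rs$nc, nops_c = rs$nops_c)
  })
  skipped <- sum(vapply(rows, is.null, logical(1)))
  if (skipped > 0) {
    warning(skipped, " carbon-free compound(s) skipped", call. = FALSE)
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out)) {
    out <- tibble::tibble(compound_id = character(), formula = character(),
                          hc = double(), oc = double(), nc = double(),
                          nops_c = double())
  }
  if (!is.null(output)) readr::write_tsv(out, output)
  out
}

# Shared strict TSV reader: UTF-8, header row, named required columns.
read_tsv_strict <- function(path, required) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  tab <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  missing <- setdiff(required, names(tab))
  if (length(missing) > 0) {
    stop("file ", path, " is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  tab
}
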