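#' @importFrom stats lm coef residuals sd approx setNames rnorm
#' @importFrom utils read.csv write.csv
NULL

# All IUPAC element symbols, used to validate parsed tokens.
.element_symbols <- c(
  "H", "He", "Li", "Be", "B", "C", "N", "O", "F", "Ne", "Na", "Mg", "Al",
  "Si", "P", "S", "Cl", "Ar", "K", "Ca", "Sc", "Ti", "V", "Cr", "Mn", "Fe",
  "Co", "Ni", "Cu", "Zn", "Ga", "Ge", "As", "Se", "Br", "Kr", "Rb", "Sr",
  "Y", "Zr", "Nb", "Mo", "Tc", "Ru", "Rh", "Pd", "Ag", "Cd", "In", "Sn",
  "Sb", "Te", "I", "Xe", "Cs", "Ba", "La", "Ce", "Pr", "Nd", "Pm", "Sm",
  "Eu", "Gd", "Tb", "Dy", "Ho", "Er", "Tm", "Yb", "Lu", "Hf", "Ta", "W",
  "Re", "Os", "Ir", "Pt", "Au", "Hg", "Tl", "Pb", "Bi", "Po", "At", "Rn",
  "Fr", "Ra", "Ac", "Th", "Pa", "U", "Np", "Pu", "Am", "Cm", "Bk", "Cf",
  "Es", "Fm", "Md", "No", "Lr", "Rf", "Db", "Sg", "Bh", "Hs", "Mt", "Ds",
  "Rg", "Cn", "Nh", "Fl", "Mc", "Lv", "Ts", "Og")

#' Average atomic masses
#'
#' Named vector of average (conventional) atomic weights in g/mol for the
#' elements most common in organic and sensing chemistry, rounded to 3-4
#' decimal places. Used as the default mass table by [molecular_weight()]
#' and the green-metrics functions.
#'
#' @return Named numeric vector, element symbol -> mass (g/mol).
#' @examples
#' atomic_masses()[["C"]]
#' @export
atomic_masses <- function() {
  c(H = 1.008, He = 4.0026, Li = 6.94, Be = 9.0122, B = 10.81, C = 12.011,
    N = 14.007, O = 15.999, F = 18.9984, Ne = 20.1797, Na = 22.9898,
    Mg = 24.305, Al = 26.9815, Si = 28.085, P = 30.9738, S = 32.06,
    Cl = 35.45, K = 39.098, Ca = 40.078, Ti = 47.867, Cr = 51.9961,
    Mn = 54.938, Fe = 55.845, Co = 58.9332, Ni = 58.6934, Cu = 63.546,
    Zn = 65.38, Ga = 69.723, Ge = 72.63, As = 74.9216, Se = 78.971,
    Br = 79.904, Rb = 85.4678, Sr = 87.62, Mo = 95.95, Pd = 106.42,
    Ag = 107.8682, Cd = 112.414, Sn = 118.71, Sb = 121.76, I = 126.9045,
    Cs = 132.9055, Ba = 137.327, Pt = 195.084, Au = 196.9666,
    Hg = 200.592, Pb = 207.2)
}

.parse_error <- function(msg, text = NULL) {
  if (!is.null(text)) msg <- sprintf("%s (in formula '%s')", msg, text)
  stop(structure(class = c("fluorsense_parse_error", "fluorsense_input_error",
                           "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

# Map Unicode subscript digits to ASCII and drop underscores/whitespace.
.normalize_formula_text <- function(text) {
  txt <- gsub("[_[:space:]]", "", text)
  chartr("\u2080\u2081\u2082\u2083\u2084\u2085\u2086\u2087\u2088\u2089",
         "0123456789", txt)
}

#' Parse a molecular formula
#'
#' Parses a molecular formula string such as `"C25H25NO"` or
#' `"Ca(OH)2"` into element counts. Underscores, whitespace and Unicode
#' subscript digits are stripped before parsing, so formulas copied from
#' typeset text (`"C_25_ H_25_ NO"`) parse directly. Parenthesized groups
#' with integer multipliers are supported, including nesting.
#'
#' @param text Formula as a single character string.
#' @return An object of class `chem_formula`: a list with `source_text`
#'   (the input) and `counts` (named integer vector in Hill order:
#'   C, H, then remaining elements alphabetically).
#' @examples
#' parse_formula("C25H25NO")$counts
#' parse_formula("Ca(OH)2")$counts
#' @seealso [format_formula()], [molecular_weight()], [carbon_count()]
#' @export
parse_formula <- function(text) {
  if (!is.character(text) || length(text) != 1L || is.na(text))
    .parse_error("formula must be a single character string")
  txt <- .normalize_formula_text(text)
  if (!nzchar(txt)) .parse_error("empty formula", text)

  pos <- 1L
  n <- nchar(txt)
  peek <- function() if (pos <= n) substr(txt, pos, pos) else ""
  take <- function() { ch <- peek(); pos <<- pos + 1L; ch }
  read_int <- function() {
    start <- pos
    while (grepl("[0-9]", peek())) pos <<- pos + 1L
    if (pos == start) return(NA_integer_)
    as.integer(substr(txt, start, pos - 1L))
  }
  merge_counts <- function(a, b) {
    for (el in names(b)) a[el] <- if (el %in% names(a)) a[[el]] + b[[el]] else b[[el]]
    a
  }
  parse_group <- function(depth) {
    counts <- integer(0)
    repeat {
      ch <- peek()
      if (ch == "") break
      if (ch == ")") {
        if (depth == 0L) .parse_error("unmatched ')'", text)
        break
      }
      if (ch == "(") {
        take()
        inner <- parse_group(depth + 1L)
        if (peek() != ")") .parse_error("unmatched '('", text)
        take()
        mult <- read_int()
        if (is.na(mult)) mult <- 1L
        if (mult == 0L) .parse_error("zero multiplier", text)
        counts <- merge_counts(counts, inner * mult)
      } else if (grepl("[A-Z]", ch)) {
        sym <- take()
        if (grepl("[a-z]", peek())) sym <- paste0(sym, take())
        if (!(sym %in% .element_symbols))
          .parse_error(sprintf("unknown element symbol '%s'", sym), text)
        cnt <- read_int()
        if (is.na(cnt)) cnt <- 1L
        if (cnt == 0L) .parse_error(sprintf("zero count for element '%s'", sym), text)
        counts <- merge_counts(counts, setNames(cnt, sym))
      } else {
        .parse_error(sprintf("unexpected character '%s'", ch), text)
      }
    }
    counts
  }

  counts <- parse_group(0L)
  if (pos <= n) .parse_error("trailing input after formula", text)
  if (length(counts) == 0L) .parse_error("formula contains no elements", text)
  structure(list(source_text = text, counts = .hill_order(counts)),
            class = "chem_formula")
}

# Hill order: C first, then H, then the rest alphabetically; plain
# alphabetical when no carbon is present.
.hill_order <- function(counts) {
  els <- names(counts)
  if ("C" %in% els) {
    rest <- sort(setdiff(els, c("C", "H")))
    ord <- c("C", intersect("H", els), rest)
  } else {
    ord <- sort(els)
  }
  counts[ord]
}

#' Serialize a formula in Hill order
#'
#' @param f A `chem_formula` (or a formula string, parsed on the fly).
#' @return Canonical Hill-order string, e.g. `"C25H25NO"`.
#' @examples
#' format_formula(parse_formula("H25NOC25"))
#' @export
format_formula <- function(f) {
  f <- as_formula(f)
  paste0(names(f$counts),
         ifelse(f$counts == 1L, "", as.character(f$counts)),
         collapse = "")
}

#' Coerce to a chem_formula
#'
#' @param x A `chem_formula` object or a formula string.
#' @return A `chem_formula`.
#' @export
as_formula <- function(x) {
  if (inherits(x, "chem_formula")) return(x)
  parse_formula(x)
}

#' @export
print.chem_formula <- function(x, ...) {
  cat("<formula>", format_formula(x), "\n")
  invisible(x)
}

#' Average molecular weight of a formula
#'
#' @param f A `chem_formula` or formula string.
#' @param masses Named mass table (g/mol); defaults to [atomic_masses()].
#' @return Molecular weight in g/mol.
#' @examples
#' molecular_weight("H2O")
#' @export
molecular_weight <- function(f, masses = atomic_masses()) {
  f <- as_formula(f)
  missing_el <- setdiff(names(f$counts), names(masses))
  if (length(missing_el) > 0L)
    stop("no atomic mass available for element(s): ",
         paste(missing_el, collapse = ", "))
  sum(f$counts * masses[names(f$counts)])
}

#' Number of carbon atoms in a formula
#'
#' @inheritParams molecular_weight
#' @return Integer carbon count (0 when carbon is absent).
#' @examples
#' carbon_count("C25H25NO")
#' carbon_count("H2O")
#' @export
carbon_count <- function(f) {
  f <- as_formula(f)
  if ("C" %in% names(f$counts)) unname(f$counts[["C"]]) else 0L
}
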