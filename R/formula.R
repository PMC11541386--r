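#' Monoisotopic atomic masses
#'
#' Fixed IUPAC monoisotopic masses (Da) of the elements supported by the
#' package. These values underlie every m/z the package computes; they are
#' deliberately frozen here (rather than taken from an external source at
#' run time) so that computed masses are reproducible across installations.
#'
#' @format Named numeric vector, one entry per element symbol.
#' @export
atomic_masses <- c(
  C  = 12.000000,
  H  = 1.0078250,
  N  = 14.0030740,
  O  = 15.9949146,
  S  = 31.9720707,
  F  = 18.9984032,
  Cl = 34.9688527,
  P  = 30.9737615,
  Na = 22.9897693,
  K  = 38.9637065,
  Br = 78.9183376,
  I  = 126.9044719
)

#' Parse a Hill-notation elemental formula
#'
#' Converts a formula string such as `"C6H10O5"` into a named integer
#' vector of element counts. All counts in a compound formula are
#' non-negative; signed reaction deltas are handled by [parse_delta()].
#'
#' @param x A single formula string. An empty string yields an empty
#'   count vector (the identity formula).
#' @return Named integer vector of element counts.
#' @seealso [parse_delta()], [monoisotopic_mass()]
#' @export
#' @examples
#' parse_formula("C6H10O5")
parse_formula <- function(x) {
  stopifnot(is.character(x), length(x) == 1L, !is.na(x))
  x <- trimws(x)
  if (!nzchar(x)) {
    return(stats::setNames(integer(0), character(0)))
  }
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", x)[[1]]
  tokens <- regmatches(x, list(m))[[1]]
  if (paste(tokens, collapse = "") != x) {
    stop("malformed formula string: '", x, "'", call. = FALSE)
  }
  sym <- sub("[0-9]*$", "", tokens)
  num <- sub("^[A-Za-z]+", "", tokens)
  cnt <- ifelse(nzchar(num), as.integer(num), 1L)
  counts <- tapply(cnt, sym, sum)
  out <- as.integer(counts)
  names(out) <- names(counts)
  out
}

#' Parse a signed reaction delta expression
#'
#' Reaction deltas are written as whitespace-separated signed formula
#' terms, e.g. `"+C6H10O5"`, `"-H2O"`, or `"+O -H2"`. A term without a
#' sign is treated as an addition. Both the ASCII hyphen and the Unicode
#' minus sign are accepted.
#'
#' @param x A single delta expression string.
#' @return Named integer vector of signed element counts.
#' @export
#' @examples
#' parse_delta("+C6H10O5 -H2O")
parse_delta <- function(x) {
  stopifnot(is.character(x), length(x) == 1L, !is.na(x))
  x <- gsub("−", "-", x)
  terms <- strsplit(trimws(x), "[[:space:]]+")[[1]]
  terms <- terms[nzchar(terms)]
  out <- stats::setNames(integer(0), character(0))
  for (term in terms) {
    sign <- 1L
    if (startsWith(term, "+")) {
      term <- substring(term, 2L)
    } else if (startsWith(term, "-")) {
      sign <- -1L
      term <- substring(term, 2L)
    }
    out <- formula_add(out, sign * parse_formula(term))
  }
  out
}

#' Add two element-count vectors elementwise
#'
#' @param a,b Named integer vectors as returned by [parse_formula()] or
#'   [parse_delta()].
#' @return Named integer vector over the union of elements; zero counts
#'   are dropped.
#' @export
formula_add <- function(a, b) {
  elements <- union(names(a), names(b))
  out <- stats::setNames(integer(length(elements)), elements)
  out[names(a)] <- out[names(a)] + a
  out[names(b)] <- out[names(b)] + b
  out[out != 0L]
}

#' Format element counts as a Hill-notation string
#'
#' Carbon first, then hydrogen, then the remaining elements
#' alphabetically; a count of one omits the digit.
#'
#' @param counts Named integer vector of non-negative element counts.
#' @return A single formula string ("" for the empty formula).
#' @export
formula_string <- function(counts) {
  counts <- counts[counts != 0L]
  if (length(counts) == 0L) {
    return("")
  }
  if (any(counts < 0L)) {
    stop("cannot format a formula with negative element counts", call. = FALSE)
  }
  elements <- names(counts)
  rest <- sort(setdiff(elements, c("C", "H")))
  order <- c(intersect(c("C", "H"), elements), rest)
  paste0(order, ifelse(counts[order] == 1L, "", counts[order]), collapse = "")
}

#' Monoisotopic mass of an elemental formula
#'
#' Signed sum of count times monoisotopic atomic mass over the packaged
#' atomic-mass table ([atomic_masses]). Accepts a formula string, a signed
#' delta expression, or a named count vector; negative counts yield the
#' signed mass delta of a reaction.
#'
#' @param formula A formula/delta string or a named integer count vector.
#' @return Mass (or signed mass delta) in Da.
#' @export
#' @examples
#' monoisotopic_mass("C6H10O5")  # glucose conjugation shift, 162.05282
#' monoisotopic_mass("C3H2O3")   # malonic acid conjugation shift, 86.00039
monoisotopic_mass <- function(formula) {
  counts <- if (is.character(formula)) parse_delta(formula) else formula
  if (length(counts) == 0L) {
    return(0)
  }
  unknown <- setdiff(names(counts), names(atomic_masses))
  if (length(unknown) > 0L) {
    stop("unsupported element symbol(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  sum(counts * atomic_masses[names(counts)])
}

#' Derive an elemental formula from a SMILES string
#'
#' Delegates to OpenBabel through ChemmineR/ChemmineOB (implicit
#' hydrogens are added before counting).
#'
#' @param smiles A single SMILES string.
#' @return Hill-notation formula string.
#' @export
smiles_to_formula <- function(smiles) {
  stopifnot(is.character(smiles), length(smiles) == 1L, nzchar(smiles))
  if (!requireNamespace("ChemmineR", quietly = TRUE) ||
      !requireNamespace("ChemmineOB", quietly = TRUE)) {
    stop("SMILES-derived formulas require the ChemmineR and ChemmineOB packages",
         call. = FALSE)
  }
  sdf <- suppressWarnings(ChemmineR::smiles2sdf(smiles))
  unname(ChemmineR::MF(sdf, addH = TRUE))
}
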