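# IUPAC 2021 conventional atomic weights, g/mol. Static table: no lookups at
# run time, and molecular weights in this package are always g/mmol (g/mol /
# 1000) because flux units are mmol/gDW/h.
.ATOMIC_MASS <- c(
  H = 1.008, He = 4.0026, Li = 6.94, Be = 9.0122, B = 10.81, C = 12.011,
  N = 14.007, O = 15.999, F = 18.998, Ne = 20.180, Na = 22.990, Mg = 24.305,
  Al = 26.982, Si = 28.085, P = 30.974, S = 32.06, Cl = 35.45, Ar = 39.95,
  K = 39.098, Ca = 40.078, Mn = 54.938, Fe = 55.845, Co = 58.933,
  Ni = 58.693, Cu = 63.546, Zn = 65.38, Se = 78.971, Br = 79.904, I = 126.90
)

#' Atomic mass table
#'
#' The conventional atomic weights (IUPAC 2021) embedded in the package,
#' expressed in g/mol.
#'
#' @return Named numeric vector, element symbol to atomic mass.
#' @export
atomic_masses <- function() .ATOMIC_MASS

#' Parse a chemical formula string
#'
#' Converts a Hill-style formula string such as `"C16H32O2"` into an elemental
#' composition: a named integer vector of non-negative atom counts.
#'
#' @param x Character scalar, e.g. `"C43H81O13P"`. `""` and `NA` give an empty
#'   composition.
#' @return Named integer vector (element to count).
#' @examples
#' parse_formula("C16H32O2")
#' @export
parse_formula <- function(x) {
  if (length(x) != 1L) stop("parse_formula() expects a single string")
  if (is.na(x) || !nzchar(x)) {
    return(stats::setNames(integer(0), character(0)))
  }
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", x, perl = TRUE)[[1]]
  tokens <- regmatches(x, list(m))[[1]]
  if (sum(attr(m, "match.length")) != nchar(x)) {
    stop(sprintf("malformed chemical formula: '%s'", x))
  }
  elems <- sub("[0-9]*$", "", tokens)
  counts <- sub("^[A-Z][a-z]?", "", tokens)
  counts <- ifelse(nzchar(counts), as.integer(counts), 1L)
  out <- tapply(counts, elems, sum)
  stats::setNames(as.integer(out), names(out))
}

#' Format an elemental composition as a formula string
#'
#' Inverse of [parse_formula()]: writes the composition in Hill order (C, H,
#' then other elements alphabetically).
#'
#' @param composition Named integer vector of atom counts.
#' @return Character scalar; `""` for an empty composition.
#' @export
format_formula <- function(composition) {
  composition <- composition[composition > 0]
  if (length(composition) == 0L) return("")
  elems <- names(composition)
  ord <- c(intersect(c("C", "H"), elems), sort(setdiff(elems, c("C", "H"))))
  composition <- composition[ord]
  paste0(names(composition),
         ifelse(composition == 1L, "", composition), collapse = "")
}

#' Merge elemental compositions
#'
#' Elementwise sum of atom counts (used to combine backbone and chain
#' contributions).
#'
#' @param ... Named integer vectors as returned by [parse_formula()].
#' @return Named integer vector.
#' @export
combine_formulas <- function(...) {
  parts <- list(...)
  all_el <- unique(unlist(lapply(parts, names)))
  out <- stats::setNames(integer(length(all_el)), all_el)
  for (p in parts) out[names(p)] <- out[names(p)] + p
  out
}

#' Molecular weight of an elemental composition
#'
#' Sum of atom count times atomic mass, reported in g/mmol so that a flux in
#' mmol/gDW/h times a molecular weight gives a mass rate in g/gDW/h directly.
#'
#' @param formula Either a formula string or a named composition vector.
#' @return Numeric scalar \[g/mmol\]; 0 for an empty composition.
#' @examples
#' molecular_weight("C16H32O2") # 0.25643
#' @export
molecular_weight <- function(formula) {
  if (is.character(formula)) formula <- parse_formula(formula)
  if (length(formula) == 0L) return(0)
  unknown <- setdiff(names(formula), names(.ATOMIC_MASS))
  if (length(unknown) > 0L) {
    stop(sprintf("unknown element symbol(s): %s",
                 paste(unknown, collapse = ", ")))
  }
  sum(.ATOMIC_MASS[names(formula)] * formula) / 1000
}

#' Number of atoms of one element in a formula
#' @param formula Formula string or composition vector.
#' @param element Element symbol, default `"C"`.
#' @return Integer count (0 if absent).
#' @export
element_count <- function(formula, element = "C") {
  if (is.character(formula)) formula <- parse_formula(formula)
  if (element %in% names(formula)) unname(formula[[element]]) else 0L
}
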