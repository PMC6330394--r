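# Acyl-chain nomenclature: chains are written "C:D" (carbons:double bonds),
# e.g. "16:0" (palmitate) or "18:1" (oleate).

#' Parse an acyl-chain label
#'
#' Parses the `"C:D"` (carbons:double-bonds) notation used in lipidomics and
#' FAME reports into an `acyl_chain` object.
#'
#' @param label Character scalar such as `"16:0"`.
#' @return An object of class `acyl_chain`: a list with `carbons`,
#'   `double_bonds` and the canonical `label`.
#' @examples
#' parse_chain_label("18:1")
#' @export
parse_chain_label <- function(label) {
  if (length(label) != 1L || is.na(label)) {
    stop("parse_chain_label() expects a single chain label")
  }
  if (!grepl("^[0-9]+:[0-9]+$", label)) {
    stop(sprintf("malformed acyl-chain label: '%s' (expected 'C:D', e.g. '16:0')",
                 label))
  }
  parts <- as.integer(strsplit(label, ":", fixed = TRUE)[[1]])
  carbons <- parts[1]
  double_bonds <- parts[2]
  if (carbons < 2L) {
    stop(sprintf("acyl chain '%s': need at least 2 carbons", label))
  }
  if (double_bonds > carbons / 2) {
    stop(sprintf("acyl chain '%s': %d double bonds impossible on %d carbons",
                 label, double_bonds, carbons))
  }
  structure(
    list(carbons = carbons, double_bonds = double_bonds,
         label = paste0(carbons, ":", double_bonds)),
    class = "acyl_chain"
  )
}

#' Format an acyl chain back to its label
#' @param chain An `acyl_chain` object.
#' @return The `"C:D"` label.
#' @export
format_chain_label <- function(chain) {
  stopifnot(inherits(chain, "acyl_chain"))
  paste0(chain$carbons, ":", chain$double_bonds)
}

#' @export
print.acyl_chain <- function(x, ...) {
  cat(sprintf("<acyl chain %s: %d carbons, %d double bond(s)>\n",
              x$label, x$carbons, x$double_bonds))
  invisible(x)
}

#' Elemental composition of an acyl chain
#'
#' Returns the free-fatty-acid-equivalent composition `C_n H_(2n-2d) O2` of a
#' chain with `n` carbons and `d` double bonds. FAME measurements quantify
#' chains as fatty-acid equivalents, which makes this the natural mass basis
#' for the chain pseudo-metabolites; an alternative convention (e.g. acyl
#' residue) can be supplied via `convention`.
#'
#' @param chain An `acyl_chain` or a `"C:D"` label.
#' @param convention `"free_acid"` (default, `C_nH_(2n-2d)O2`) or
#'   `"acyl_residue"` (`C_nH_(2n-2d-2)O`, i.e. the free acid minus water).
#' @return Named integer composition vector.
#' @examples
#' chain_formula("16:0") # C16 H32 O2
#' @export
chain_formula <- function(chain, convention = c("free_acid", "acyl_residue")) {
  convention <- match.arg(convention)
  if (is.character(chain)) chain <- parse_chain_label(chain)
  stopifnot(inherits(chain, "acyl_chain"))
  n <- chain$carbons
  h <- 2L * n - 2L * chain$double_bonds
  out <- switch(convention,
    free_acid    = c(C = n, H = h, O = 2L),
    acyl_residue = c(C = n, H = h - 2L, O = 1L)
  )
  storage.mode(out) <- "integer"
  out
}

#' Molecular weight of an acyl chain \[g/mmol\]
#' @inheritParams chain_formula
#' @return Numeric scalar.
#' @export
chain_weight <- function(chain, convention = "free_acid") {
  molecular_weight(chain_formula(chain, convention))
}
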