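# Constraint-based model container. Deliberately minimal: metabolites and
# reactions as data frames, stoichiometries as a named list keyed by reaction
# id, the linear objective as a named weight vector. The stoichiometric matrix
# is assembled on demand as a sparse Matrix.

#' Create an empty constraint-based model
#'
#' @param id Model identifier.
#' @param annotations Named character vector of free-form annotations.
#' @return An object of class `gem`.
#' @export
gem <- function(id = "model", annotations = character()) {
  structure(
    list(
      id = id,
      mets = data.frame(id = character(), name = character(),
                        compartment = character(), formula = character(),
                        is_pseudo = logical(), stringsAsFactors = FALSE),
      rxns = data.frame(id = character(), lb = numeric(), ub = numeric(),
                        is_pseudo = logical(), subsystem = character(),
                        stringsAsFactors = FALSE),
      stoich = list(),
      objective = stats::setNames(numeric(0), character(0)),
      annotations = annotations
    ),
    class = "gem"
  )
}

#' Add a metabolite to a model
#'
#' @param model A `gem`.
#' @param id Unique metabolite id (SBML SId-safe: letters, digits, underscore).
#' @param name Human-readable name (lipid naming rules match on this field).
#' @param compartment Compartment id.
#' @param formula Chemical formula string (may be `""` for pseudo-metabolites).
#' @param is_pseudo Flag for backbone/chain/generic pseudo-metabolites.
#' @return The modified model.
#' @export
add_metabolite <- function(model, id, name = id, compartment = "c",
                           formula = "", is_pseudo = FALSE) {
  stopifnot(inherits(model, "gem"))
  if (id %in% model$mets$id) {
    stop(sprintf("metabolite id already present: '%s'", id))
  }
  if (!grepl("^[A-Za-z_][A-Za-z0-9_]*$", id)) {
    stop(sprintf("metabolite id '%s' is not SBML SId-safe", id))
  }
  parse_formula(formula) # validates
  model$mets <- rbind(model$mets, data.frame(
    id = id, name = name, compartment = compartment, formula = formula,
    is_pseudo = is_pseudo, stringsAsFactors = FALSE))
  model
}

#' Add a reaction to a model
#'
#' @param model A `gem`.
#' @param id Unique reaction id.
#' @param stoich Named numeric vector, metabolite id to coefficient
#'   (negative = consumed). Exchange/demand reactions carry exactly one
#'   metabolite; otherwise the stoichiometry must have at least two entries.
#' @param lb,ub Flux bounds \[mmol/gDW/h\]; `lb <= ub`.
#' @param is_pseudo Flag for pseudo-reactions (biomass components, pools,
#'   SLIME reactions).
#' @param subsystem Free-form subsystem tag.
#' @return The modified model.
#' @export
add_reaction <- function(model, id, stoich, lb = 0, ub = Inf,
                         is_pseudo = FALSE, subsystem = "") {
  stopifnot(inherits(model, "gem"))
  if (id %in% model$rxns$id) {
    stop(sprintf("reaction id already present: '%s'", id))
  }
  if (!grepl("^[A-Za-z_][A-Za-z0-9_]*$", id)) {
    stop(sprintf("reaction id '%s' is not SBML SId-safe", id))
  }
  if (length(stoich) == 0L) {
    stop(sprintf("reaction '%s': empty stoichiometry", id))
  }
  if (is.null(names(stoich)) || any(!nzchar(names(stoich)))) {
    stop(sprintf("reaction '%s': stoichiometry must be a named vector", id))
  }
  missing_mets <- setdiff(names(stoich), model$mets$id)
  if (length(missing_mets) > 0L) {
    stop(sprintf("reaction '%s' references unknown metabolite(s): %s",
                 id, paste(missing_mets, collapse = ", ")))
  }
  if (!is.finite(lb) && lb > 0 || !is.finite(ub) && ub < 0) {
    stop(sprintf("reaction '%s': non-finite bound of wrong sign", id))
  }
  if (lb > ub) {
    stop(sprintf("reaction '%s': lb (%g) > ub (%g)", id, lb, ub))
  }
  stoich <- stoich[stoich != 0]
  model$rxns <- rbind(model$rxns, data.frame(
    id = id, lb = lb, ub = ub, is_pseudo = is_pseudo,
    subsystem = subsystem, stringsAsFactors = FALSE))
  model$stoich[[id]] <- stoich
  model
}

#' Remove reactions from a model
#' @param model A `gem`.
#' @param ids Reaction ids to drop.
#' @return The modified model.
#' @export
remove_reaction <- function(model, ids) {
  stopifnot(inherits(model, "gem"))
  unknown <- setdiff(ids, model$rxns$id)
  if (length(unknown) > 0L) {
    stop(sprintf("cannot remove unknown reaction(s): %s",
                 paste(unknown, collapse = ", ")))
  }
  keep <- !(model$rxns$id %in% ids)
  model$rxns <- model$rxns[keep, , drop = FALSE]
  rownames(model$rxns) <- NULL
  model$stoich <- model$stoich[model$rxns$id]
  model$objective <- model$objective[setdiff(names(model$objective), ids)]
  model
}

#' Remove metabolites from a model
#'
#' Refuses to remove a metabolite still used by a reaction.
#' @param model A `gem`.
#' @param ids Metabolite ids to drop.
#' @return The modified model.
#' @export
remove_metabolite <- function(model, ids) {
  stopifnot(inherits(model, "gem"))
  used <- unique(unlist(lapply(model$stoich, names)))
  bad <- intersect(ids, used)
  if (length(bad) > 0L) {
    stop(sprintf("metabolite(s) still referenced by reactions: %s",
                 paste(bad, collapse = ", ")))
  }
  model$mets <- model$mets[!(model$mets$id %in% ids), , drop = FALSE]
  rownames(model$mets) <- NULL
  model
}

#' Set flux bounds on a reaction
#' @param model A `gem`.
#' @param id Reaction id.
#' @param lb,ub New bounds; `NULL` keeps the current value.
#' @return The modified model.
#' @export
set_bounds <- function(model, id, lb = NULL, ub = NULL) {
  stopifnot(inherits(model, "gem"))
  i <- match(id, model$rxns$id)
  if (is.na(i)) stop(sprintf("unknown reaction: '%s'", id))
  if (!is.null(lb)) model$rxns$lb[i] <- lb
  if (!is.null(ub)) model$rxns$ub[i] <- ub
  if (model$rxns$lb[i] > model$rxns$ub[i]) {
    stop(sprintf("reaction '%s': lb (%g) > ub (%g)",
                 id, model$rxns$lb[i], model$rxns$ub[i]))
  }
  model
}

#' Set the linear objective
#' @param model A `gem`.
#' @param objective Named numeric vector, reaction id to weight.
#' @return The modified model.
#' @export
set_objective <- function(model, objective) {
  stopifnot(inherits(model, "gem"))
  unknown <- setdiff(names(objective), model$rxns$id)
  if (length(unknown) > 0L) {
    stop(sprintf("objective references unknown reaction(s): %s",
                 paste(unknown, collapse = ", ")))
  }
  model$objective <- objective
  model
}

#' Assemble the stoichiometric matrix S
#'
#' One row per metabolite, one column per reaction, as a sparse `dgCMatrix`.
#'
#' @param model A `gem`.
#' @return A sparse matrix with dimnames (metabolite ids, reaction ids).
#' @export
stoich_matrix <- function(model) {
  stopifnot(inherits(model, "gem"))
  m <- nrow(model$mets)
  n <- nrow(model$rxns)
  met_index <- stats::setNames(seq_len(m), model$mets$id)
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  for (j in seq_len(n)) {
    s <- model$stoich[[model$rxns$id[j]]]
    ii <- c(ii, met_index[names(s)])
    jj <- c(jj, rep.int(j, length(s)))
    xx <- c(xx, unname(s))
  }
  Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(m, n),
                       dimnames = list(model$mets$id, model$rxns$id))
}

#' Is a reaction an exchange/demand reaction?
#' @param model A `gem`.
#' @param ids Reaction ids (default: all).
#' @return Logical vector: `TRUE` where the stoichiometry has exactly one
#'   metabolite.
#' @export
is_exchange <- function(model, ids = model$rxns$id) {
  vapply(model$stoich[ids], function(s) length(s) == 1L, logical(1))
}

#' Validate model invariants
#'
#' Checks id uniqueness, bound ordering, stoichiometry references and that the
#' steady-state system is well-posed. Returns the model invisibly on success,
#' stops with an informative message otherwise.
#'
#' @param model A `gem`.
#' @return The model, invisibly.
#' @export
validate_gem <- function(model) {
  stopifnot(inherits(model, "gem"))
  if (anyDuplicated(model$mets$id)) {
    stop(sprintf("duplicated metabolite id(s): %s",
         paste(unique(model$mets$id[duplicated(model$mets$id)]), collapse = ", ")))
  }
  if (anyDuplicated(model$rxns$id)) {
    stop(sprintf("duplicated reaction id(s): %s",
         paste(unique(model$rxns$id[duplicated(model$rxns$id)]), collapse = ", ")))
  }
  bad <- model$rxns$id[model$rxns$lb > model$rxns$ub]
  if (length(bad) > 0L) {
    stop(sprintf("lb > ub for reaction(s): %s", paste(bad, collapse = ", ")))
  }
  if (!setequal(names(model$stoich), model$rxns$id)) {
    stop("stoichiometry list out of step with reaction table")
  }
  used <- unique(unlist(lapply(model$stoich, names)))
  unknown <- setdiff(used, model$mets$id)
  if (length(unknown) > 0L) {
    stop(sprintf("stoichiometry references unknown metabolite(s): %s",
                 paste(unknown, collapse = ", ")))
  }
  S <- stoich_matrix(model)
  stopifnot(nrow(S) == nrow(model$mets), ncol(S) == nrow(model$rxns))
  invisible(model)
}

#' @export
print.gem <- function(x, ...) {
  cat(sprintf("<gem '%s': %d metabolites, %d reactions, %d objective term(s)>\n",
              x$id, nrow(x$mets), nrow(x$rxns), length(x$objective)))
  invisible(x)
}

met_formula <- function(model, met_id) {
  i <- match(met_id, model$mets$id)
  if (is.na(i)) stop(sprintf("unknown metabolite: '%s'", met_id))
  model$mets$formula[i]
}
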