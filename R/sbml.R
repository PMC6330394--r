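# SBML Level 3 + FBC v2 I/O. The writer emits bounds as constant parameters
# referenced through fbc:lowerFluxBound/fbc:upperFluxBound, objectives via
# fbc:listOfObjectives, metabolite formulas via fbc:chemicalFormula, and the
# package's pseudo/subsystem flags in a namespaced annotation element that
# other tools simply ignore. The reader accepts any FBC v2 file of that shape.

.xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  x <- gsub(">", "&gt;", x, fixed = TRUE)
  x <- gsub("\"", "&quot;", x, fixed = TRUE)
  x
}

.sbml_num <- function(x) {
  if (x == Inf) return("INF")
  if (x == -Inf) return("-INF")
  sprintf("%.17g", x)
}

.SLIMEKIT_NS <- "https://slimekit.invalid/annotation"

#' Write a model as SBML Level 3 + FBC v2
#'
#' @param model A `gem`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_model_sbml <- function(model, path) {
  validate_gem(model)
  out <- c(
    "<?xml version=\"1.0\" encoding=\"UTF-8\"?>",
    paste0("<sbml xmlns=\"http://www.sbml.org/sbml/level3/version1/core\" ",
           "xmlns:fbc=\"http://www.sbml.org/sbml/level3/version1/fbc/version2\" ",
           "level=\"3\" version=\"1\" fbc:required=\"false\">"),
    sprintf("  <model id=\"%s\" fbc:strict=\"false\">", .xml_escape(model$id))
  )
  comps <- unique(model$mets$compartment)
  if (length(comps) > 0L) {
    out <- c(out, "    <listOfCompartments>",
             sprintf("      <compartment id=\"%s\" constant=\"true\"/>",
                     .xml_escape(comps)),
             "    </listOfCompartments>")
  }
  if (nrow(model$mets) > 0L) {
    sp <- vapply(seq_len(nrow(model$mets)), function(i) {
      met <- model$mets[i, ]
      formula_attr <- if (nzchar(met$formula)) {
        sprintf(" fbc:chemicalFormula=\"%s\"", .xml_escape(met$formula))
      } else ""
      ann <- sprintf(paste0("<annotation><slimekit xmlns=\"%s\" ",
                            "isPseudo=\"%s\"/></annotation>"),
                     .SLIMEKIT_NS, tolower(as.character(met$is_pseudo)))
      sprintf(paste0("      <species id=\"%s\" name=\"%s\" compartment=\"%s\" ",
                     "hasOnlySubstanceUnits=\"false\" boundaryCondition=\"false\" ",
                     "constant=\"false\"%s>%s</species>"),
              .xml_escape(met$id), .xml_escape(met$name),
              .xml_escape(met$compartment), formula_attr, ann)
    }, character(1))
    out <- c(out, "    <listOfSpecies>", sp, "    </listOfSpecies>")
  }
  # One shared parameter per distinct bound value.
  bvals <- sort(unique(c(model$rxns$lb, model$rxns$ub)))
  pid <- stats::setNames(sprintf("bnd_%d", seq_along(bvals)),
                         vapply(bvals, .sbml_num, character(1)))
  if (length(bvals) > 0L) {
    out <- c(out, "    <listOfParameters>",
             sprintf("      <parameter id=\"%s\" value=\"%s\" constant=\"true\"/>",
                     pid, names(pid)),
             "    </listOfParameters>")
  }
  if (nrow(model$rxns) > 0L) {
    rx <- vapply(seq_len(nrow(model$rxns)), function(i) {
      rxn <- model$rxns[i, ]
      s <- model$stoich[[rxn$id]]
      sub <- s[s < 0]; prod <- s[s > 0]
      refs <- function(v, tag) {
        if (length(v) == 0L) return("")
        inner <- sprintf(paste0("          <speciesReference species=\"%s\" ",
                                "stoichiometry=\"%s\" constant=\"true\"/>"),
                         .xml_escape(names(v)),
                         vapply(abs(unname(v)), .sbml_num, character(1)))
        paste0("        <", tag, ">\n", paste(inner, collapse = "\n"),
               "\n        </", tag, ">\n")
      }
      ann <- sprintf(paste0("        <annotation><slimekit xmlns=\"%s\" ",
                            "isPseudo=\"%s\" subsystem=\"%s\"/></annotation>\n"),
                     .SLIMEKIT_NS, tolower(as.character(rxn$is_pseudo)),
                     .xml_escape(rxn$subsystem))
      paste0(sprintf(paste0("      <reaction id=\"%s\" reversible=\"%s\" ",
                            "fast=\"false\" fbc:lowerFluxBound=\"%s\" ",
                            "fbc:upperFluxBound=\"%s\">\n"),
                     .xml_escape(rxn$id), tolower(as.character(rxn$lb < 0)),
                     pid[[.sbml_num(rxn$lb)]], pid[[.sbml_num(rxn$ub)]]),
             ann, refs(sub, "listOfReactants"), refs(prod, "listOfProducts"),
             "      </reaction>")
    }, character(1))
    out <- c(out, "    <listOfReactions>", rx, "    </listOfReactions>")
  }
  if (length(model$objective) > 0L) {
    fo <- sprintf(paste0("          <fbc:fluxObjective fbc:reaction=\"%s\" ",
                         "fbc:coefficient=\"%s\"/>"),
                  .xml_escape(names(model$objective)),
                  vapply(unname(model$objective), .sbml_num, character(1)))
    out <- c(out,
             "    <fbc:listOfObjectives fbc:activeObjective=\"obj\">",
             "      <fbc:objective fbc:id=\"obj\" fbc:type=\"maximize\">",
             "        <fbc:listOfFluxObjectives>", fo,
             "        </fbc:listOfFluxObjectives>",
             "      </fbc:objective>",
             "    </fbc:listOfObjectives>")
  }
  out <- c(out, "  </model>", "</sbml>")
  txt <- paste(out, collapse = "\n")
  xml2::read_xml(txt) # self-check: what we wrote parses
  writeLines(txt, path)
  invisible(path)
}

.parse_sbml_value <- function(x) {
  ifelse(x == "INF", Inf, ifelse(x == "-INF", -Inf, suppressWarnings(as.numeric(x))))
}

.slimekit_ann <- function(node, attrib, default) {
  ann <- xml2::xml_find_first(node, ".//*[local-name()='slimekit']")
  if (inherits(ann, "xml_missing")) return(default)
  val <- xml2::xml_attr(ann, attrib)
  if (is.na(val)) default else val
}

#' Read an SBML Level 3 + FBC model
#'
#' Expects flux bounds through the FBC package (parameter references) and
#' reads `fbc:chemicalFormula` into the metabolite formula slot. Malformed XML
#' propagates the parser error (which names the offending line); reactions
#' without FBC bounds are reported by id.
#'
#' @param path SBML file path.
#' @return A `gem`.
#' @export
read_model_sbml <- function(path) {
  doc <- xml2::read_xml(path)
  model_node <- xml2::xml_find_first(doc, ".//*[local-name()='model']")
  if (inherits(model_node, "xml_missing")) stop("SBML file has no <model>")
  mid <- xml2::xml_attr(model_node, "id")
  model <- gem(id = if (is.na(mid)) "model" else mid)

  params <- xml2::xml_find_all(
    doc, ".//*[local-name()='listOfParameters']/*[local-name()='parameter']")
  pvals <- stats::setNames(
    .parse_sbml_value(xml2::xml_attr(params, "value")),
    xml2::xml_attr(params, "id"))

  species <- xml2::xml_find_all(
    doc, ".//*[local-name()='listOfSpecies']/*[local-name()='species']")
  for (sp in species) {
    formula <- xml2::xml_attr(sp, "chemicalFormula")
    nm <- xml2::xml_attr(sp, "name")
    model <- add_metabolite(
      model,
      id = xml2::xml_attr(sp, "id"),
      name = if (is.na(nm)) xml2::xml_attr(sp, "id") else nm,
      compartment = xml2::xml_attr(sp, "compartment"),
      formula = if (is.na(formula)) "" else formula,
      is_pseudo = identical(.slimekit_ann(sp, "isPseudo", "false"), "true"))
  }

  rxn_nodes <- xml2::xml_find_all(
    doc, ".//*[local-name()='listOfReactions']/*[local-name()='reaction']")
  no_bounds <- character(0)
  for (rx in rxn_nodes) {
    rid <- xml2::xml_attr(rx, "id")
    lb_ref <- xml2::xml_attr(rx, "lowerFluxBound")
    ub_ref <- xml2::xml_attr(rx, "upperFluxBound")
    if (is.na(lb_ref) || is.na(ub_ref) ||
        !(lb_ref %in% names(pvals)) || !(ub_ref %in% names(pvals))) {
      no_bounds <- c(no_bounds, rid)
      next
    }
    reac <- xml2::xml_find_all(rx, paste0("./*[local-name()='listOfReactants']",
                                          "/*[local-name()='speciesReference']"))
    prod <- xml2::xml_find_all(rx, paste0("./*[local-name()='listOfProducts']",
                                          "/*[local-name()='speciesReference']"))
    stoich <- c(
      stats::setNames(-as.numeric(xml2::xml_attr(reac, "stoichiometry")),
                      xml2::xml_attr(reac, "species")),
      stats::setNames(as.numeric(xml2::xml_attr(prod, "stoichiometry")),
                      xml2::xml_attr(prod, "species")))
    model <- add_reaction(
      model, id = rid, stoich = stoich,
      lb = unname(pvals[[lb_ref]]), ub = unname(pvals[[ub_ref]]),
      is_pseudo = identical(.slimekit_ann(rx, "isPseudo", "false"), "true"),
      subsystem = .slimekit_ann(rx, "subsystem", ""))
  }
  if (length(no_bounds) > 0L) {
    stop(sprintf("reaction(s) without FBC flux bounds: %s",
                 paste(no_bounds, collapse = ", ")))
  }

  fobj <- xml2::xml_find_all(doc, ".//*[local-name()='fluxObjective']")
  if (length(fobj) > 0L) {
    model <- set_objective(model, stats::setNames(
      as.numeric(xml2::xml_attr(fobj, "coefficient")),
      xml2::xml_attr(fobj, "reaction")))
  }
  validate_gem(model)
  model
}

#' Write the JSON model dialect
#'
#' A plain-text companion format to SBML so fixtures and scripts need no XML
#' tooling: `{metabolites: [...], reactions: [{id, stoich, lb, ub, ...}],
#' objective: {...}}`. Infinite bounds serialize as the strings `"Inf"` /
#' `"-Inf"`.
#'
#' @param model A `gem`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_model_json <- function(model, path) {
  validate_gem(model)
  enc_num <- function(x) if (is.finite(x)) x else as.character(x)
  obj <- list(
    id = model$id,
    metabolites = lapply(seq_len(nrow(model$mets)), function(i) {
      m <- model$mets[i, ]
      list(id = m$id, name = m$name, compartment = m$compartment,
           formula = m$formula, is_pseudo = m$is_pseudo)
    }),
    reactions = lapply(seq_len(nrow(model$rxns)), function(i) {
      r <- model$rxns[i, ]
      list(id = r$id, stoich = as.list(model$stoich[[r$id]]),
           lb = enc_num(r$lb), ub = enc_num(r$ub),
           is_pseudo = r$is_pseudo, subsystem = r$subsystem)
    }),
    objective = as.list(model$objective),
    annotations = as.list(model$annotations)
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read the JSON model dialect
#' @param path JSON file path written by [write_model_json()].
#' @return A `gem`.
#' @export
read_model_json <- function(path) {
  raw <- jsonlite::read_json(path)
  model <- gem(id = raw$id %||% "model",
               annotations = unlist(raw$annotations) %||% character())
  for (m in raw$metabolites) {
    model <- add_metabolite(model, id = m$id, name = m$name,
                            compartment = m$compartment,
                            formula = m$formula %||% "",
                            is_pseudo = isTRUE(m$is_pseudo))
  }
  for (r in raw$reactions) {
    model <- add_reaction(
      model, id = r$id,
      stoich = stats::setNames(as.numeric(unlist(r$stoich)), names(r$stoich)),
      lb = as.numeric(r$lb), ub = as.numeric(r$ub),
      is_pseudo = isTRUE(r$is_pseudo), subsystem = r$subsystem %||% "")
  }
  if (length(raw$objective) > 0L) {
    model <- set_objective(model, stats::setNames(
      as.numeric(unlist(raw$objective)), names(raw$objective)))
  }
  validate_gem(model)
  model
}

`%||%` <- function(a, b) if (is.null(a)) b else a
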