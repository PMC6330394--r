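# Mapping model metabolites to lipid species. Conventions for naming lipids
# vary a great deal between databases and models, so the extraction is driven
# by a rule config (per-class regex patterns over metabolite names), never
# hard-coded.

#' Construct a lipid species
#'
#' A specific lipid: class, acyl-chain configuration (a multiset of chain
#' labels, possibly empty as for sterols) and chemical formula.
#'
#' @param id Metabolite id of the species in the model.
#' @param lipid_class Class tag (e.g. `"PI"`, `"TAG"`, `"ERG"`).
#' @param chains Character vector of chain labels (repeats allowed; may be
#'   empty for chain-free species).
#' @param formula Chemical formula string of the full lipid.
#' @param name Display name (defaults to `id`).
#' @return An object of class `lipid_species`.
#' @export
lipid_species <- function(id, lipid_class, chains, formula, name = id) {
  chains <- vapply(chains, function(x) parse_chain_label(x)$label, character(1),
                   USE.NAMES = FALSE)
  comp <- parse_formula(formula)
  if (length(chains) > 0L) {
    if (length(comp) == 0L) {
      stop(sprintf("lipid species '%s' has chains but no formula", id))
    }
    chain_sum <- Reduce(combine_formulas, lapply(chains, chain_formula))
    common <- intersect(names(chain_sum), names(comp))
    bad <- any(chain_sum[common] > comp[common]) ||
      length(setdiff(names(chain_sum), names(comp))) > 0L
    if (bad) {
      stop(sprintf(
        "lipid species '%s': summed chain formula %s exceeds lipid formula %s",
        id, format_formula(chain_sum), format_formula(comp)))
    }
  }
  structure(list(id = id, name = name, lipid_class = lipid_class,
                 chains = chains, formula = format_formula(comp)),
            class = "lipid_species")
}

#' @export
print.lipid_species <- function(x, ...) {
  cat(sprintf("<lipid species '%s': class %s, chains [%s], %s>\n",
              x$id, x$lipid_class,
              paste(x$chains, collapse = ", "),
              if (nzchar(x$formula)) x$formula else "no formula"))
  invisible(x)
}

#' Build a lipid naming-rule config
#'
#' @param rules List of rules; each rule is a list with `class` (class tag),
#'   `pattern` (regex over metabolite *names*, with an optional capture group
#'   holding the chain block), `chain_sep` (separator inside the chain block,
#'   default `"-"`), `chains` (explicit chain labels overriding extraction —
#'   use `character(0)` for chain-free species such as free sterols), and
#'   optional `n_chains` (expected acyl positions for the class; checked when
#'   given).
#' @param candidate_pattern Regex identifying lipid-like metabolite names;
#'   candidates that no rule matches end up in the unmatched report instead of
#'   being silently dropped.
#' @return An object of class `naming_rules`.
#' @export
naming_rules <- function(rules, candidate_pattern) {
  for (r in rules) {
    stopifnot(is.character(r$class), is.character(r$pattern))
  }
  structure(list(rules = rules, candidate_pattern = candidate_pattern),
            class = "naming_rules")
}

.apply_rule <- function(rule, name) {
  m <- regexec(rule$pattern, name)
  hit <- regmatches(name, m)[[1]]
  if (length(hit) == 0L) return(NULL)
  if (!is.null(rule$chains)) {
    chains <- rule$chains
  } else if (length(hit) >= 2L) {
    sep <- rule$chain_sep %||% "-"
    chains <- strsplit(hit[2], sep, fixed = TRUE)[[1]]
  } else {
    chains <- character(0)
  }
  list(class = rule$class, chains = chains)
}

#' Map model metabolites to lipid species
#'
#' Applies the naming rules to every non-pseudo metabolite name. Matched
#' metabolites become [lipid_species()]; lipid-like metabolites (per the
#' config's `candidate_pattern`) that no rule matches, or that lack a formula
#' or a parsable chain label, are reported — never silently dropped. A matched
#' species whose chains' summed formula exceeds the lipid formula raises a
#' consistency error.
#'
#' @param model A `gem`.
#' @param rules A [naming_rules()] config.
#' @return List with `species` (list of `lipid_species`) and `unmatched`
#'   (data frame `id`, `name`, `reason`).
#' @export
map_model_lipids <- function(model, rules) {
  stopifnot(inherits(model, "gem"), inherits(rules, "naming_rules"))
  species <- list()
  unmatched <- data.frame(id = character(), name = character(),
                          reason = character(), stringsAsFactors = FALSE)
  note <- function(id, name, reason) {
    rbind(unmatched, data.frame(id = id, name = name, reason = reason,
                                stringsAsFactors = FALSE))
  }
  for (i in seq_len(nrow(model$mets))) {
    met <- model$mets[i, ]
    if (met$is_pseudo) next
    hit <- NULL
    for (r in rules$rules) {
      hit <- .apply_rule(r, met$name)
      if (!is.null(hit)) { rule <- r; break }
    }
    if (is.null(hit)) {
      if (grepl(rules$candidate_pattern, met$name)) {
        unmatched <- note(met$id, met$name, "no naming rule matched")
      }
      next
    }
    if (!nzchar(met$formula)) {
      unmatched <- note(met$id, met$name, "matched but metabolite has no formula")
      next
    }
    parsed <- tryCatch(
      lipid_species(met$id, hit$class, hit$chains, met$formula,
                    name = met$name),
      error = function(e) e)
    if (inherits(parsed, "error")) {
      if (grepl("exceeds lipid formula", conditionMessage(parsed))) {
        stop(parsed) # inconsistent chemistry is an error, not a skip
      }
      unmatched <- note(met$id, met$name, conditionMessage(parsed))
      next
    }
    if (!is.null(rule$n_chains) && length(parsed$chains) != rule$n_chains) {
      unmatched <- note(met$id, met$name,
                        sprintf("expected %d chain position(s), found %d",
                                rule$n_chains, length(parsed$chains)))
      next
    }
    species[[length(species) + 1L]] <- parsed
  }
  list(species = species, unmatched = unmatched)
}

#' Write the unmatched-lipid report as TSV
#' @param unmatched The `unmatched` data frame from [map_model_lipids()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_unmatched_report <- function(unmatched, path) {
  utils::write.table(unmatched, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
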