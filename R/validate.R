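# Consistency checks over an enhanced model: re-derives every SLIME
# coefficient from the chemical formulas and audits the pseudo-reaction
# census. Used by the command line's `validate` subcommand and handy as a
# post-enhancement sanity gate in scripts.

#' Validate a slime model's coefficients and pseudo-reaction census
#'
#' Recomputes `s_i` (lipid molecular weight) and `s_jk` (chain molecular
#' weight times repetitions) from the species formulas and compares them to
#' the installed SLIME reaction stoichiometry; checks chain-mass dominance
#' (`sum s_jk <= s_i`); verifies the expected pseudo-reaction census for the
#' variant; and confirms no replaced class pseudo-reaction survived.
#'
#' @param x A `slime_model`.
#' @param tol Coefficient tolerance (default 1e-9).
#' @return List with `ok` (logical), `problems` (character), and `census`
#'   (named counts). `ok = FALSE` never throws: callers decide.
#' @export
validate_slime <- function(x, tol = 1e-9) {
  stopifnot(inherits(x, "slime_model"))
  problems <- character(0)
  model <- x$model
  for (sp in x$species) {
    rid <- paste0("SLIME_", sp$id)
    if (!(rid %in% model$rxns$id)) {
      problems <- c(problems, sprintf("missing SLIME reaction for '%s'", sp$id))
      next
    }
    s <- model$stoich[[rid]]
    s_i_expect <- molecular_weight(sp$formula)
    bmet <- .backbone_met_id(sp$lipid_class)
    if (!(bmet %in% names(s)) || abs(s[[bmet]] - s_i_expect) > tol) {
      problems <- c(problems, sprintf(
        "'%s': backbone coefficient %.12g != lipid MW %.12g", rid,
        if (bmet %in% names(s)) s[[bmet]] else NA_real_, s_i_expect))
    }
    reps <- table(sp$chains)
    chain_sum <- 0
    for (lbl in names(reps)) {
      expect <- chain_weight(lbl) * as.integer(reps[[lbl]])
      chain_sum <- chain_sum + expect
      cid <- .chain_met_id(lbl)
      hits <- names(s)[names(s) == cid |
                         startsWith(names(s), paste0(cid, "_"))]
      got <- if (length(hits) > 0L) s[[hits[1]]] else NA_real_
      if (is.na(got) || abs(got - expect) > tol) {
        problems <- c(problems, sprintf(
          "'%s': chain %s coefficient %.12g != chain MW x reps %.12g",
          rid, lbl, got, expect))
      }
    }
    if (chain_sum > s_i_expect + tol) {
      problems <- c(problems, sprintf(
        "'%s': chain mass %.12g exceeds backbone mass %.12g",
        rid, chain_sum, s_i_expect))
    }
  }
  census <- c(
    slime_reactions = sum(startsWith(model$rxns$id, "SLIME_")),
    backbone_pool = sum(model$rxns$id == .POOL_BACKBONE),
    chain_pool = sum(model$rxns$id == .POOL_CHAIN),
    merge = sum(model$rxns$id == .POOL_MERGE),
    chain_excretions = sum(grepl("^EX_chain_", model$rxns$id)),
    backbone_mets = sum(grepl("^backbone_", model$mets$id) &
                          model$mets$id != .GENERIC_BACKBONE),
    chain_mets = sum(grepl("^chain_C", model$mets$id)))
  expected_chain_pool <- if (x$variant == "permissive") 0L else 1L
  if (census[["backbone_pool"]] != 1L || census[["merge"]] != 1L ||
      census[["chain_pool"]] != expected_chain_pool) {
    problems <- c(problems, sprintf(
      "pseudo-reaction census wrong for variant '%s': backbone=%d chain=%d merge=%d",
      x$variant, census[["backbone_pool"]], census[["chain_pool"]],
      census[["merge"]]))
  }
  if (x$variant == "permissive" && census[["chain_excretions"]] == 0L) {
    problems <- c(problems, "permissive variant has no chain excretions")
  }
  # Replacement completeness: the only pseudo-reactions consuming a mapped
  # species are its SLIME reactions.
  species_ids <- vapply(x$species, `[[`, character(1), "id")
  for (rid in model$rxns$id) {
    s <- model$stoich[[rid]]
    if (model$rxns$is_pseudo[match(rid, model$rxns$id)] &&
        !startsWith(rid, "SLIME_") &&
        length(intersect(names(s)[s < 0], species_ids)) > 0L) {
      problems <- c(problems, sprintf(
        "replaced-style pseudo-reaction still consumes a lipid species: '%s'",
        rid))
    }
  }
  list(ok = length(problems) == 0L, problems = problems, census = census)
}
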