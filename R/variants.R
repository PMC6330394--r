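# Comparator model builders. The permissive variant keeps only the
# lipid-class constraint and lets the network pick acyl chains freely (it
# will pick the cheapest); the restrictive variant forces every lipid class
# to one global acyl-chain distribution.

#' Build the permissive comparator model
#'
#' Drops the acyl-chain pseudo-reaction, opens one irreversible excretion
#' exchange per chain pseudo-metabolite (so the model may discard any chain
#' mix it likes), and rewires the merge reaction to consume only the generic
#' backbone. The feasible set of the enhanced model embeds in the permissive
#' one, so the permissive maximum ATP turnover can never be lower.
#'
#' @param enhanced A `slime_model` of variant `"enhanced"`.
#' @return A `slime_model` of variant `"permissive"`.
#' @export
make_permissive <- function(enhanced) {
  stopifnot(inherits(enhanced, "slime_model"))
  if (enhanced$variant != "enhanced") {
    stop(sprintf("make_permissive() needs an enhanced model, got variant '%s'",
                 enhanced$variant))
  }
  model <- enhanced$model
  model <- remove_reaction(model, c(.POOL_CHAIN, .POOL_MERGE))
  chain_mets <- .chain_met_id(names(enhanced$data$chain_abundance))
  chain_mets <- intersect(chain_mets, model$mets$id)
  for (cm in chain_mets) {
    model <- add_reaction(model, paste0("EX_", cm),
                          stats::setNames(-1, cm), lb = 0, ub = Inf,
                          is_pseudo = TRUE, subsystem = "chain excretion")
  }
  model <- add_reaction(model, .POOL_MERGE,
                        stats::setNames(c(-1, 1),
                                        c(.GENERIC_BACKBONE,
                                          enhanced$config$lipid_met)),
                        lb = 0, ub = Inf, is_pseudo = TRUE,
                        subsystem = "lipid pseudo-reactions")
  model <- remove_metabolite(model, .GENERIC_CHAIN)
  out <- enhanced
  out$model <- model
  out$variant <- "permissive"
  out$provenance$removed <- c(out$provenance$removed, .POOL_CHAIN)
  out$provenance$added <- c(out$provenance$added, paste0("EX_", chain_mets))
  out
}

#' Build the restrictive comparator model
#'
#' Forces every lipid class to the same global acyl-chain distribution (the
#' classical generic-acyl-pool formulation). Each class gets its own copy of
#' the chain pseudo-metabolites, pooled per class with the supplied mass
#' fractions as coefficients — the pooling flux pins the class's chain-mass
#' split to exactly those fractions — and the per-class pools feed the
#' generic chain with the total FAME mass as coefficient.
#'
#' @param enhanced A `slime_model` of variant `"enhanced"` (it contains the
#'   SLIME machinery the pooling construct rewires).
#' @param chain_fractions Named numeric, chain label to mass fraction;
#'   must sum to 1 (±1e-9). Default: fractions of the model's FAME data.
#' @return A `slime_model` of variant `"restrictive"`.
#' @export
make_restrictive <- function(enhanced, chain_fractions = NULL) {
  stopifnot(inherits(enhanced, "slime_model"))
  if (enhanced$variant != "enhanced") {
    stop(sprintf("make_restrictive() needs an enhanced model, got variant '%s'",
                 enhanced$variant))
  }
  chain_total <- sum(enhanced$data$chain_abundance)
  if (is.null(chain_fractions)) {
    chain_fractions <- enhanced$data$chain_abundance / chain_total
  }
  if (abs(sum(chain_fractions) - 1) > 1e-9) {
    stop(sprintf("chain_fractions must sum to 1 (got %.12g)",
                 sum(chain_fractions)))
  }
  model <- enhanced$model
  classes <- unique(vapply(enhanced$species, `[[`, character(1), "lipid_class"))
  model <- add_metabolite(model, "chain_pooled",
                          name = "pooled acyl chain mass [pseudo]",
                          compartment = "c", is_pseudo = TRUE)

  # Class-local chain copies: rewrite each SLIME reaction to deposit its
  # chain mass into its own class's pseudo-metabolites.
  all_lbls <- union(names(chain_fractions),
                    unique(unlist(lapply(enhanced$species, `[[`, "chains"))))
  for (cl in classes) {
    for (lbl in all_lbls) {
      model <- add_metabolite(
        model, paste0(.chain_met_id(lbl), "_", .sanitize_id(cl)),
        name = sprintf("C%s chain of %s [pseudo]", lbl, cl),
        compartment = "c", is_pseudo = TRUE)
    }
  }
  for (sp in enhanced$species) {
    rid <- paste0("SLIME_", sp$id)
    s <- model$stoich[[rid]]
    lbls <- unique(sp$chains)
    old_ids <- .chain_met_id(lbls)
    new_ids <- paste0(old_ids, "_", .sanitize_id(sp$lipid_class))
    names(s)[match(old_ids, names(s))] <- new_ids
    model$stoich[[rid]] <- s
  }
  # Per-class pooling at the global fractions: flux t consumes f_k * t of
  # each class-local chain k, so the class's chain-mass split equals the
  # fractions exactly.
  for (cl in classes) {
    stoich <- c(stats::setNames(-unname(chain_fractions),
                                paste0(.chain_met_id(names(chain_fractions)),
                                       "_", .sanitize_id(cl))),
                chain_pooled = 1)
    model <- add_reaction(model, paste0("PSEUDO_chainpool_", .sanitize_id(cl)),
                          stoich, lb = 0, ub = Inf, is_pseudo = TRUE,
                          subsystem = "lipid pseudo-reactions")
  }
  # The generic chain requirement is now expressed through the pooled mass.
  model <- remove_reaction(model, .POOL_CHAIN)
  model <- add_reaction(model, .POOL_CHAIN,
                        stats::setNames(c(-chain_total, 1),
                                        c("chain_pooled", .GENERIC_CHAIN)),
                        lb = 0, ub = Inf, is_pseudo = TRUE,
                        subsystem = "lipid pseudo-reactions")
  # Global chain pseudo-metabolites are orphaned by the rewrite.
  orphan <- setdiff(.chain_met_id(names(enhanced$data$chain_abundance)),
                    unique(unlist(lapply(model$stoich, names))))
  if (length(orphan) > 0L) model <- remove_metabolite(model, orphan)

  out <- enhanced
  out$model <- model
  out$variant <- "restrictive"
  out$chain_fractions <- chain_fractions
  out
}
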