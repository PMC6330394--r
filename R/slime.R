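# SLIME reactions ("Split Lipids Into Measurable Entities") and the three
# lipid pseudo-reactions. A SLIME reaction splits one specific lipid into its
# class backbone and its acyl chains, with molecular weights (g/mmol) as
# stoichiometric coefficients, so a molar lipid flux becomes a mass flux.
# The backbone pool then constrains the lipid-class profile, the chain pool
# the FAME acyl-chain profile, and a merge reaction feeds the generic lipid
# into the biomass pseudo-reaction.

.sanitize_id <- function(x) gsub("[^A-Za-z0-9]", "_", x)
.backbone_met_id <- function(class) paste0("backbone_", .sanitize_id(class))
.chain_met_id <- function(label) paste0("chain_C", .sanitize_id(label))
.GENERIC_BACKBONE <- "backbone_generic"
.GENERIC_CHAIN <- "chain_generic"
.POOL_BACKBONE <- "PSEUDO_backbone_pool"
.POOL_CHAIN <- "PSEUDO_chain_pool"
.POOL_MERGE <- "PSEUDO_lipid_merge"

#' Model wiring configuration
#'
#' Names the handful of reactions/metabolites the enhancement needs to find
#' in the host model.
#'
#' @param biomass_rxn Id of the biomass pseudo-reaction.
#' @param lipid_met Id of the generic lipid pseudo-metabolite consumed by the
#'   biomass pseudo-reaction.
#' @param atpm_rxn Id of the ATP maintenance reaction (the simulation
#'   objective).
#' @param carb_rxn Id of the carbohydrate pseudo-reaction (rescaled when
#'   normalizing biomass to 1 g/gDW).
#' @param ngam Non-growth-associated maintenance \[mmol/gDW/h\], a model
#'   constant (default 0.7).
#' @return A list of class `slime_config`.
#' @export
slime_config <- function(biomass_rxn, lipid_met, atpm_rxn, carb_rxn = NULL,
                         ngam = 0.7) {
  structure(list(biomass_rxn = biomass_rxn, lipid_met = lipid_met,
                 atpm_rxn = atpm_rxn, carb_rxn = carb_rxn, ngam = ngam),
            class = "slime_config")
}

#' Build a SLIME reaction for one lipid species
#'
#' The backbone coefficient `s_i` is the molecular weight \[g/mmol\] of the
#' full lipid; each chain coefficient `s_jk` is the molecular weight of chain
#' `k` times its number of repetitions in the species' configuration. The
#' split is irreversible (bounds `[0, Inf)`): SLIME reactions are accounting
#' constructs and mass must not flow backwards out of the pools.
#'
#' @param species A [lipid_species()]; must carry a formula.
#' @return An object of class `slime_reaction` with fields `lipid_id`,
#'   `lipid_class`, `backbone_coeff` and `chain_coeffs` (named by chain
#'   label).
#' @export
build_slime_reaction <- function(species) {
  stopifnot(inherits(species, "lipid_species"))
  if (!nzchar(species$formula)) {
    stop(sprintf("lipid species '%s' has no chemical formula; cannot build its SLIME reaction",
                 species$id))
  }
  s_i <- molecular_weight(species$formula)
  chain_coeffs <- numeric(0)
  if (length(species$chains) > 0L) {
    reps <- table(species$chains)
    chain_coeffs <- vapply(names(reps), function(lbl) {
      chain_weight(lbl) * as.integer(reps[[lbl]])
    }, numeric(1))
  }
  if (sum(chain_coeffs) > s_i + 1e-12) {
    stop(sprintf("species '%s': chain mass %.6g exceeds lipid mass %.6g",
                 species$id, sum(chain_coeffs), s_i))
  }
  structure(list(lipid_id = species$id, lipid_class = species$lipid_class,
                 backbone_coeff = s_i, chain_coeffs = chain_coeffs),
            class = "slime_reaction")
}

#' @export
print.slime_reaction <- function(x, ...) {
  rhs <- sprintf("%.6g %s", x$backbone_coeff, .backbone_met_id(x$lipid_class))
  if (length(x$chain_coeffs) > 0L) {
    rhs <- paste(c(rhs, sprintf("%.6g %s", x$chain_coeffs,
                                .chain_met_id(names(x$chain_coeffs)))),
                 collapse = " + ")
  }
  cat(sprintf("<SLIME: %s -> %s>\n", x$lipid_id, rhs))
  invisible(x)
}

# Adds backbone/chain/generic pseudo-metabolites and one SLIME reaction per
# species; removes the class pseudo-reactions they replace (pseudo-reactions
# consuming a mapped species). Returns list(model, removed, slime_ids).
.add_slime_reactions <- function(model, species_list) {
  slime_ids <- paste0("SLIME_", vapply(species_list, `[[`, character(1), "id"))
  if (any(slime_ids %in% model$rxns$id)) {
    stop("model already contains SLIME reactions; enhancement is not re-entrant")
  }
  classes <- unique(vapply(species_list, `[[`, character(1), "lipid_class"))
  labels <- unique(unlist(lapply(species_list, `[[`, "chains")))
  for (cl in classes) {
    model <- add_metabolite(model, .backbone_met_id(cl),
                            name = sprintf("%s backbone [pseudo]", cl),
                            compartment = "c", is_pseudo = TRUE)
  }
  for (lbl in labels) {
    model <- add_metabolite(model, .chain_met_id(lbl),
                            name = sprintf("C%s chain [pseudo]", lbl),
                            compartment = "c", is_pseudo = TRUE)
  }
  model <- add_metabolite(model, .GENERIC_BACKBONE,
                          name = "generic backbone [pseudo]",
                          compartment = "c", is_pseudo = TRUE)
  model <- add_metabolite(model, .GENERIC_CHAIN,
                          name = "generic acyl chain [pseudo]",
                          compartment = "c", is_pseudo = TRUE)

  # Replace class pseudo-reactions (specific lipid -> generic class).
  species_ids <- vapply(species_list, `[[`, character(1), "id")
  removed <- character(0)
  for (rid in model$rxns$id) {
    s <- model$stoich[[rid]]
    consumed <- names(s)[s < 0]
    if (model$rxns$is_pseudo[match(rid, model$rxns$id)] &&
        length(intersect(consumed, species_ids)) > 0L) {
      removed <- c(removed, rid)
    }
  }
  if (length(removed) > 0L) model <- remove_reaction(model, removed)

  for (sp in species_list) {
    sr <- build_slime_reaction(sp)
    stoich <- c(stats::setNames(-1, sp$id),
                stats::setNames(sr$backbone_coeff,
                                .backbone_met_id(sp$lipid_class)))
    if (length(sr$chain_coeffs) > 0L) {
      stoich <- c(stoich, stats::setNames(unname(sr$chain_coeffs),
                                          .chain_met_id(names(sr$chain_coeffs))))
    }
    model <- add_reaction(model, paste0("SLIME_", sp$id), stoich,
                          lb = 0, ub = Inf, is_pseudo = TRUE,
                          subsystem = "SLIME")
  }
  list(model = model, removed = removed, slime_ids = slime_ids)
}

# (Re)build the three lipid pseudo-reactions from the abundance data.
.update_pools <- function(model, data, config) {
  for (rid in c(.POOL_BACKBONE, .POOL_CHAIN, .POOL_MERGE)) {
    if (rid %in% model$rxns$id) model <- remove_reaction(model, rid)
  }
  back_stoich <- stats::setNames(
    -unname(data$class_abundance),
    .backbone_met_id(names(data$class_abundance)))
  chain_stoich <- stats::setNames(
    -unname(data$chain_abundance),
    .chain_met_id(names(data$chain_abundance)))
  missing_b <- setdiff(names(back_stoich), model$mets$id)
  if (length(missing_b) > 0L) {
    stop(sprintf("abundance data names lipid class(es) with no backbone pseudo-metabolite: %s",
                 paste(missing_b, collapse = ", ")))
  }
  missing_c <- setdiff(names(chain_stoich), model$mets$id)
  if (length(missing_c) > 0L) {
    stop(sprintf("abundance data names acyl chain(s) with no chain pseudo-metabolite: %s",
                 paste(missing_c, collapse = ", ")))
  }
  model <- add_reaction(model, .POOL_BACKBONE,
                        c(back_stoich, stats::setNames(1, .GENERIC_BACKBONE)),
                        lb = 0, ub = Inf, is_pseudo = TRUE,
                        subsystem = "lipid pseudo-reactions")
  model <- add_reaction(model, .POOL_CHAIN,
                        c(chain_stoich, stats::setNames(1, .GENERIC_CHAIN)),
                        lb = 0, ub = Inf, is_pseudo = TRUE,
                        subsystem = "lipid pseudo-reactions")
  model <- add_reaction(model, .POOL_MERGE,
                        stats::setNames(c(-1, -1, 1),
                                        c(.GENERIC_BACKBONE, .GENERIC_CHAIN,
                                          config$lipid_met)),
                        lb = 0, ub = Inf, is_pseudo = TRUE,
                        subsystem = "lipid pseudo-reactions")
  model
}

#' Install the lipid pseudo-reactions
#'
#' Adds the three pooling reactions — backbone pool (class abundances
#' \[g/gDW\] as coefficients), chain pool (FAME abundances \[g/gDW\]) and the
#' merge reaction (1 generic backbone + 1 generic chain -> 1 generic lipid) —
#' and removes the old lipid pseudo-reaction that only constrained classes.
#' The generic lipid is the metabolite the biomass pseudo-reaction already
#' consumes, so biomass wiring is untouched. Classes/chains present in the
#' model but absent from the data get coefficient 0 (their SLIME fluxes are
#' then forced to zero but the species stay in the model).
#'
#' @param model A `gem` that already contains SLIME reactions (see
#'   [enhance_model()] for the orchestrated pipeline).
#' @param data An [abundance_data()].
#' @param config A [slime_config()].
#' @param species_list The mapped [lipid_species()] list (recorded in
#'   provenance).
#' @param removed Reaction ids removed by the SLIME step (provenance).
#' @return An object of class `slime_model`, variant `"enhanced"`.
#' @export
install_pseudo_reactions <- function(model, data, config, species_list = list(),
                                     removed = character()) {
  stopifnot(inherits(model, "gem"), inherits(data, "abundance_data"),
            inherits(config, "slime_config"))
  if (.POOL_MERGE %in% model$rxns$id) {
    stop("lipid pseudo-reactions already installed; enhancement is not re-entrant")
  }
  if (!(config$biomass_rxn %in% model$rxns$id)) {
    stop(sprintf("biomass pseudo-reaction '%s' not found", config$biomass_rxn))
  }
  if (!(config$lipid_met %in% model$mets$id)) {
    stop(sprintf("generic lipid metabolite '%s' not found", config$lipid_met))
  }
  # Remove the old lipid pseudo-reaction(s): pseudo-reactions producing the
  # generic lipid.
  old <- character(0)
  for (rid in model$rxns$id) {
    s <- model$stoich[[rid]]
    if (model$rxns$is_pseudo[match(rid, model$rxns$id)] &&
        config$lipid_met %in% names(s) && s[[config$lipid_met]] > 0) {
      old <- c(old, rid)
    }
  }
  if (length(old) > 0L) model <- remove_reaction(model, old)
  model <- .update_pools(model, data, config)
  structure(list(
    model = model, variant = "enhanced", data = data, config = config,
    species = species_list,
    provenance = list(
      removed = c(removed, old),
      added = c(paste0("SLIME_", vapply(species_list, `[[`, character(1), "id")),
                .POOL_BACKBONE, .POOL_CHAIN, .POOL_MERGE),
      scaling_factor = NA_real_, scaling_side = "none",
      coefficients = lapply(species_list, build_slime_reaction))
  ), class = "slime_model")
}

#' @export
print.slime_model <- function(x, ...) {
  cat(sprintf("<slime model (%s): %d species, %d classes, %d chains>\n",
              x$variant, length(x$species),
              length(x$data$class_abundance), length(x$data$chain_abundance)))
  invisible(x)
}

#' Enhance a model with SLIME reactions and lipid pseudo-reactions
#'
#' The full pipeline: map lipid species from metabolite names, add
#' backbone/chain pseudo-metabolites and SLIME reactions (replacing class
#' pseudo-reactions), install the three lipid pseudo-reactions (replacing the
#' old lipid pseudo-reaction), rescale one side of the abundance data to mass
#' consistency, and normalize the biomass composition to 1 g/gDW via the
#' carbohydrate fraction.
#'
#' @param model Host `gem` (lipid species must carry chemical formulas).
#' @param data An [abundance_data()].
#' @param rules A [naming_rules()] config.
#' @param config A [slime_config()].
#' @param rescale `"classes"` (rescale the lipid-class profile toward the
#'   FAME totals — the chemostat reference treatment), `"chains"` (rescale the
#'   FAME profile toward an assumed total lipid fraction), or `"none"`.
#' @param normalize Normalize total biomass to 1 g/gDW (default `TRUE`;
#'   requires `config$carb_rxn`).
#' @return A `slime_model` (variant `"enhanced"`) whose `provenance` records
#'   removed/added reactions, the scaling factor and the per-species SLIME
#'   coefficients; `unmatched` carries the unmatched-lipid report.
#' @export
enhance_model <- function(model, data, rules, config,
                          rescale = c("classes", "chains", "none"),
                          normalize = TRUE) {
  rescale <- match.arg(rescale)
  mapping <- map_model_lipids(model, rules)
  if (length(mapping$species) == 0L) {
    stop("no lipid species matched the naming rules")
  }
  step <- .add_slime_reactions(model, mapping$species)
  enhanced <- install_pseudo_reactions(step$model, data, config,
                                       species_list = mapping$species,
                                       removed = step$removed)
  enhanced$unmatched <- mapping$unmatched
  if (rescale != "none") {
    scaled <- rescale_abundances(enhanced,
                                 side = paste0("scale_", rescale))
    enhanced$data <- scaled
    enhanced$model <- .update_pools(enhanced$model, scaled, config)
    enhanced$provenance$scaling_factor <- attr(scaled, "scaling_factor")
    enhanced$provenance$scaling_side <- paste0("scale_", rescale)
  }
  if (normalize) {
    enhanced$model <- normalize_biomass(enhanced$model, enhanced$data, config)
  }
  enhanced
}
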