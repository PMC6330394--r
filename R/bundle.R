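# A "bundle" persists an enhanced/permissive/restrictive model together with
# the metadata needed to keep working with it from disk: the SBML model plus
# a JSON sidecar holding variant, wiring config, abundance data, mapped
# species and provenance. This is what the command-line interface passes
# between its subcommands.

#' Write a slime model bundle
#'
#' @param x A `slime_model`.
#' @param prefix Path prefix; writes `<prefix>.xml` and `<prefix>.meta.json`.
#' @return The prefix, invisibly.
#' @export
write_slime_bundle <- function(x, prefix) {
  stopifnot(inherits(x, "slime_model"))
  write_model_sbml(x$model, paste0(prefix, ".xml"))
  meta <- list(
    variant = x$variant,
    config = unclass(x$config),
    data = list(class_abundance = as.list(x$data$class_abundance),
                chain_abundance = as.list(x$data$chain_abundance),
                other_biomass = as.list(x$data$other_biomass),
                measured_exchanges = as.list(x$data$measured_exchanges),
                growth_rate = x$data$growth_rate),
    species = lapply(x$species, function(sp) {
      list(id = sp$id, name = sp$name, lipid_class = sp$lipid_class,
           chains = as.list(sp$chains), formula = sp$formula)
    }),
    provenance = list(removed = as.list(x$provenance$removed),
                      added = as.list(x$provenance$added),
                      scaling_factor = x$provenance$scaling_factor,
                      scaling_side = x$provenance$scaling_side)
  )
  jsonlite::write_json(meta, paste0(prefix, ".meta.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  invisible(prefix)
}

#' Read a slime model bundle
#'
#' @param prefix Path prefix used by [write_slime_bundle()].
#' @return A `slime_model`.
#' @export
read_slime_bundle <- function(prefix) {
  model <- read_model_sbml(paste0(prefix, ".xml"))
  meta <- jsonlite::read_json(paste0(prefix, ".meta.json"))
  num <- function(x) stats::setNames(as.numeric(unlist(x)), names(x))
  data <- abundance_data(
    class_abundance = num(meta$data$class_abundance),
    chain_abundance = num(meta$data$chain_abundance),
    other_biomass = num(meta$data$other_biomass),
    measured_exchanges = num(meta$data$measured_exchanges),
    growth_rate = as.numeric(meta$data$growth_rate))
  species <- lapply(meta$species, function(sp) {
    lipid_species(sp$id, sp$lipid_class, unlist(sp$chains) %||% character(0),
                  sp$formula, name = sp$name)
  })
  cfg <- slime_config(meta$config$biomass_rxn, meta$config$lipid_met,
                      meta$config$atpm_rxn,
                      carb_rxn = meta$config$carb_rxn,
                      ngam = as.numeric(meta$config$ngam))
  structure(list(
    model = model, variant = meta$variant, data = data, config = cfg,
    species = species,
    provenance = list(removed = unlist(meta$provenance$removed) %||% character(),
                      added = unlist(meta$provenance$added) %||% character(),
                      scaling_factor = meta$provenance$scaling_factor %||% NA_real_,
                      scaling_side = meta$provenance$scaling_side %||% "none")
  ), class = "slime_model")
}
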