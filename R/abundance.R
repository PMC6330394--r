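# Abundance data container: lipid-class profile and FAME acyl-chain profile
# in g/gDW, other biomass components in g/gDW, measured exchange fluxes in
# mmol/gDW/h, and the growth rate (a chemostat dilution rate at steady
# state).

#' Construct an abundance dataset
#'
#' @param class_abundance Named numeric, lipid class to abundance \[g/gDW\].
#' @param chain_abundance Named numeric, chain label (`"C:D"`) to abundance
#'   \[g/gDW\] from FAME analysis.
#' @param other_biomass Named numeric, non-lipid biomass components
#'   (`protein`, `carbohydrate`, `RNA`, ...) \[g/gDW\].
#' @param measured_exchanges Named numeric, exchange reaction id to measured
#'   flux \[mmol/gDW/h\] (uptake negative).
#' @param growth_rate Specific growth rate \[1/h\].
#' @return An object of class `abundance_data`.
#' @export
abundance_data <- function(class_abundance, chain_abundance,
                           other_biomass = numeric(),
                           measured_exchanges = numeric(),
                           growth_rate = 0.1) {
  stopifnot(all(class_abundance >= 0), all(chain_abundance >= 0),
            growth_rate > 0)
  for (lbl in names(chain_abundance)) parse_chain_label(lbl)
  structure(list(class_abundance = class_abundance,
                 chain_abundance = chain_abundance,
                 other_biomass = other_biomass,
                 measured_exchanges = measured_exchanges,
                 growth_rate = growth_rate),
            class = "abundance_data")
}

#' @export
print.abundance_data <- function(x, ...) {
  cat(sprintf(paste0("<abundance data: %d lipid classes (%.4g g/gDW), ",
                     "%d chains (%.4g g/gDW), mu = %.3g 1/h>\n"),
              length(x$class_abundance), sum(x$class_abundance),
              length(x$chain_abundance), sum(x$chain_abundance),
              x$growth_rate))
  invisible(x)
}

#' Read abundance tables from TSV files
#'
#' Expected shapes: class table (`class`, `g_per_gDW`), chain table (`chain`,
#' `g_per_gDW`), optional biomass table (`component`, `g_per_gDW`) and
#' exchange table (`reaction_id`, `mmol_per_gDWh`).
#'
#' @param classes,chains,biomass,exchanges TSV paths (`biomass`/`exchanges`
#'   optional).
#' @param growth_rate Growth rate \[1/h\].
#' @return An [abundance_data()] object.
#' @export
read_abundance_tables <- function(classes, chains, biomass = NULL,
                                  exchanges = NULL, growth_rate = 0.1) {
  cls <- utils::read.delim(classes, stringsAsFactors = FALSE)
  chn <- utils::read.delim(chains, stringsAsFactors = FALSE)
  other <- numeric()
  exch <- numeric()
  if (!is.null(biomass)) {
    bm <- utils::read.delim(biomass, stringsAsFactors = FALSE)
    other <- stats::setNames(bm$g_per_gDW, bm$component)
  }
  if (!is.null(exchanges)) {
    ex <- utils::read.delim(exchanges, stringsAsFactors = FALSE)
    exch <- stats::setNames(ex$mmol_per_gDWh, ex$reaction_id)
  }
  abundance_data(stats::setNames(cls$g_per_gDW, cls$class),
                 stats::setNames(chn$g_per_gDW, chn$chain),
                 other_biomass = other, measured_exchanges = exch,
                 growth_rate = growth_rate)
}

#' Write abundance tables as TSV files
#'
#' @param data An [abundance_data()] object.
#' @param dir Output directory (created if missing). Writes `classes.tsv`,
#'   `chains.tsv`, `biomass.tsv`, `exchanges.tsv`.
#' @return The directory, invisibly.
#' @export
write_abundance_tables <- function(data, dir) {
  stopifnot(inherits(data, "abundance_data"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  w <- function(df, file) {
    utils::write.table(df, file.path(dir, file), sep = "\t",
                       row.names = FALSE, quote = FALSE)
  }
  w(data.frame(class = names(data$class_abundance),
               g_per_gDW = unname(data$class_abundance)), "classes.tsv")
  w(data.frame(chain = names(data$chain_abundance),
               g_per_gDW = unname(data$chain_abundance)), "chains.tsv")
  w(data.frame(component = names(data$other_biomass),
               g_per_gDW = unname(data$other_biomass)), "biomass.tsv")
  w(data.frame(reaction_id = names(data$measured_exchanges),
               mmol_per_gDWh = unname(data$measured_exchanges)),
    "exchanges.tsv")
  invisible(dir)
}
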