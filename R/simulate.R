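# Analysis suite: exchange constraining, ATP-turnover maximization with
# pFBA, grouped lipid FVA, flux sampling with abundance back-calculation,
# and energy/carbon cost deltas between model variants.

#' Exchange-flux constraints
#'
#' @param measured Named numeric, exchange reaction id to measured flux
#'   \[mmol/gDW/h\], uptake negative.
#' @param tolerance Allowed relative deviation from the measurement
#'   (default 0.05, i.e. ±5% on the magnitude, sign preserved).
#' @return An object of class `exchange_constraints`.
#' @export
exchange_constraints <- function(measured, tolerance = 0.05) {
  stopifnot(is.numeric(measured), tolerance >= 0)
  structure(list(measured = measured, tolerance = tolerance),
            class = "exchange_constraints")
}

.as_gem <- function(x) if (inherits(x, "slime_model")) x$model else x

#' Constrain measured exchange fluxes
#'
#' Tightens each measured exchange to `[v (1 - tol), v (1 + tol)]` on the
#' flux magnitude with the sign preserved (a measured 0 pins the flux to 0).
#' Unmeasured exchanges are untouched.
#'
#' @param x A `gem` or `slime_model`.
#' @param constraints An [exchange_constraints()] object.
#' @return Same type as `x`, with tightened bounds.
#' @export
constrain_exchanges <- function(x, constraints) {
  stopifnot(inherits(constraints, "exchange_constraints"))
  model <- .as_gem(x)
  unknown <- setdiff(names(constraints$measured), model$rxns$id)
  if (length(unknown) > 0L) {
    stop(sprintf("constrain_exchanges(): unknown reaction(s): %s",
                 paste(unknown, collapse = ", ")))
  }
  not_exch <- names(constraints$measured)[
    !is_exchange(model, names(constraints$measured))]
  if (length(not_exch) > 0L) {
    stop(sprintf("constrain_exchanges(): not exchange reaction(s): %s",
                 paste(not_exch, collapse = ", ")))
  }
  tol <- constraints$tolerance
  for (rid in names(constraints$measured)) {
    v <- constraints$measured[[rid]]
    bounds <- sort(c(v * (1 - tol), v * (1 + tol)))
    model <- set_bounds(model, rid, lb = bounds[1], ub = bounds[2])
  }
  if (inherits(x, "slime_model")) { x$model <- model; x } else model
}

#' Maximize ATP turnover (pFBA) with maintenance accounting
#'
#' Sets the objective to the ATP maintenance reaction, runs [pfba()], and
#' decomposes the turnover into the non-growth maintenance (NGAM, a model
#' constant) and the growth-associated part per gram biomass,
#' `GAM = (total - NGAM) / mu`.
#'
#' @param x A `slime_model` (uses its config and growth rate) or a `gem`
#'   (then `atpm_rxn` and `growth_rate` are required).
#' @param atpm_rxn ATP maintenance reaction id.
#' @param ngam NGAM \[mmol/gDW/h\].
#' @param growth_rate Growth rate \[1/h\].
#' @return List with `accounting` (`total_turnover`, `ngam`, `gam_per_gDW`,
#'   `growth_rate`) and `solution` (a `flux_solution`).
#' @export
max_atp_turnover <- function(x, atpm_rxn = NULL, ngam = NULL,
                             growth_rate = NULL) {
  if (inherits(x, "slime_model")) {
    atpm_rxn <- atpm_rxn %||% x$config$atpm_rxn
    ngam <- ngam %||% x$config$ngam
    growth_rate <- growth_rate %||% x$data$growth_rate
  }
  model <- .as_gem(x)
  if (is.null(atpm_rxn) || !(atpm_rxn %in% model$rxns$id)) {
    candidates <- model$rxns$id[grepl("atp|maint", model$rxns$id,
                                      ignore.case = TRUE)]
    stop(sprintf("ATP maintenance reaction '%s' not found; candidates: %s",
                 atpm_rxn %||% "<unset>",
                 if (length(candidates)) paste(candidates, collapse = ", ")
                 else "<none>"))
  }
  stopifnot(!is.null(ngam), !is.null(growth_rate), growth_rate > 0)
  model <- set_objective(model, stats::setNames(1, atpm_rxn))
  sol <- pfba(model, "max")
  if (sol$status != "optimal") {
    return(list(accounting = NULL, solution = sol))
  }
  total <- sol$objective_value
  list(accounting = list(total_turnover = total, ngam = ngam,
                         gam_per_gDW = (total - ngam) / growth_rate,
                         growth_rate = growth_rate),
       solution = sol)
}

#' Pin the ATP maintenance flux at its maximum
#'
#' Returns the underlying model with the maintenance lower bound raised to
#' `(1 - rel_tol)` of `atp_value` (default: the recomputed maximum), the
#' setting under which variability and sampling answer "in how many ways can
#' the lipid requirement be met at equal energy expenditure".
#'
#' @param x A `slime_model`.
#' @param atp_value ATP turnover to pin (default recomputed).
#' @param rel_tol Relative slack.
#' @return A `gem`.
#' @export
fix_atp_model <- function(x, atp_value = NULL, rel_tol = 1e-6) {
  stopifnot(inherits(x, "slime_model"))
  model <- set_objective(x$model, stats::setNames(1, x$config$atpm_rxn))
  if (is.null(atp_value)) {
    sol <- fba(model, "max")
    if (sol$status != "optimal") {
      stop(sprintf("fix_atp_model(): model is %s", sol$status))
    }
    atp_value <- sol$objective_value
  }
  set_bounds(model, x$config$atpm_rxn,
             lb = atp_value * (1 - rel_tol))
}

.class_chain_weights <- function(x, lipid_class, chain) {
  classes <- vapply(x$species, `[[`, character(1), "lipid_class")
  if (!(lipid_class %in% classes)) {
    stop(sprintf("unknown lipid class '%s'", lipid_class))
  }
  chain <- parse_chain_label(chain)$label
  w <- numeric(0)
  for (sp in x$species[classes == lipid_class]) {
    sr <- build_slime_reaction(sp)
    if (chain %in% names(sr$chain_coeffs)) {
      w[paste0("SLIME_", sp$id)] <- sr$chain_coeffs[[chain]]
    }
  }
  if (length(w) == 0L) {
    stop(sprintf("no species of class '%s' carries chain %s",
                 lipid_class, chain))
  }
  w
}

#' Variability of one acyl chain within one lipid class
#'
#' Grouped FVA: the objective is the summed chain-mass rate over all SLIME
#' reactions of the class that produce the chain (weights = the chain-mass
#' coefficients), evaluated with the ATP turnover pinned at its maximum by
#' default.
#'
#' @param x A `slime_model`.
#' @param lipid_class Class tag.
#' @param chain Chain label `"C:D"`.
#' @param fix_atp Pin ATP turnover at its maximum first (default `TRUE`).
#' @param atp_value ATP turnover to pin (default: the model's own maximum).
#' @param solution Optional `flux_solution` for the pFBA point; computed if
#'   missing.
#' @return List (`variability_range`): `lipid_class`, `chain`,
#'   `min_mass_rate`, `max_mass_rate`, `pfba_value` \[g/gDW/h\].
#' @export
lipid_variability <- function(x, lipid_class, chain, fix_atp = TRUE,
                              atp_value = NULL, solution = NULL) {
  stopifnot(inherits(x, "slime_model"))
  w <- .class_chain_weights(x, lipid_class, chain)
  model <- if (fix_atp) fix_atp_model(x, atp_value) else x$model
  rng <- fva_linear(model, w)
  if (is.null(solution)) {
    model_obj <- set_objective(model, stats::setNames(1, x$config$atpm_rxn))
    solution <- pfba(model_obj, "max")
  }
  pf <- sum(w * solution$fluxes[names(w)])
  structure(list(lipid_class = lipid_class, chain = parse_chain_label(chain)$label,
                 min_mass_rate = unname(rng[["min"]]),
                 max_mass_rate = unname(rng[["max"]]),
                 pfba_value = pf),
            class = "variability_range")
}

#' Realized chain-mass profile of a flux solution
#'
#' Chain mass rates \[g/gDW/h\] recovered from the SLIME reaction fluxes:
#' `flux * chain MW * repetitions`, per lipid class and chain.
#'
#' @param x A `slime_model`.
#' @param solution A `flux_solution` for `x$model` (or a compatible variant).
#' @param fractions Return rows normalized to fractions (default `FALSE`).
#' @return Matrix classes x chains.
#' @export
chain_profile <- function(x, solution, fractions = FALSE) {
  stopifnot(inherits(x, "slime_model"), inherits(solution, "flux_solution"))
  classes <- sort(unique(vapply(x$species, `[[`, character(1), "lipid_class")))
  chains <- sort(unique(unlist(lapply(x$species, `[[`, "chains"))))
  out <- matrix(0, length(classes), length(chains),
                dimnames = list(classes, chains))
  for (sp in x$species) {
    sr <- build_slime_reaction(sp)
    v <- solution$fluxes[[paste0("SLIME_", sp$id)]]
    for (lbl in names(sr$chain_coeffs)) {
      out[sp$lipid_class, lbl] <- out[sp$lipid_class, lbl] +
        v * sr$chain_coeffs[[lbl]]
    }
  }
  if (fractions) {
    rs <- rowSums(out)
    rs[rs == 0] <- 1
    out <- out / rs
  }
  out
}

#' Sample specific lipid distributions
#'
#' Hit-and-run sampling of the flux polytope followed by abundance
#' back-calculation: each species' abundance \[mg/gDW\] is its SLIME reaction
#' flux times the species molecular weight, divided by the growth rate.
#'
#' @param x A `slime_model`.
#' @param n Number of samples.
#' @param seed Integer seed.
#' @param growth_rate Growth rate \[1/h\] (default: the dataset's); must be
#'   positive.
#' @param fix_atp Sample at maximal ATP turnover (default `TRUE`).
#' @param thin Chord steps per sample.
#' @return Matrix `n x n_species` of abundances \[mg/gDW\], columns named by
#'   species id, with attributes `species_class` (named class map) and
#'   `fluxes` (the raw sampled flux matrix).
#' @export
sample_lipid_distributions <- function(x, n, seed, growth_rate = NULL,
                                       fix_atp = TRUE, thin = 100L) {
  stopifnot(inherits(x, "slime_model"))
  growth_rate <- growth_rate %||% x$data$growth_rate
  if (is.null(growth_rate) || growth_rate <= 0) {
    stop("sample_lipid_distributions(): growth_rate must be positive")
  }
  model <- if (fix_atp) fix_atp_model(x) else x$model
  fluxes <- sample_fluxes(model, n, seed, thin = thin)
  ids <- vapply(x$species, `[[`, character(1), "id")
  mw <- vapply(x$species, function(sp) molecular_weight(sp$formula), numeric(1))
  ab <- fluxes[, paste0("SLIME_", ids), drop = FALSE]
  ab <- sweep(ab, 2L, mw, `*`) / growth_rate * 1000
  colnames(ab) <- ids
  attr(ab, "species_class") <- stats::setNames(
    vapply(x$species, `[[`, character(1), "lipid_class"), ids)
  attr(ab, "fluxes") <- fluxes
  ab
}

.net_carbon_consumption <- function(model, solution) {
  exch <- model$rxns$id[is_exchange(model)]
  total <- 0
  for (rid in exch) {
    s <- model$stoich[[rid]]
    met <- names(s)
    i <- match(met, model$mets$id)
    if (model$mets$is_pseudo[i]) next
    nc <- element_count(model$mets$formula[i], "C")
    if (nc == 0L) next
    # stoich -1, flux < 0 means uptake: consumption is -v * nC.
    total <- total + (-solution$fluxes[[rid]]) * nc * abs(unname(s))
  }
  total
}

#' Energy and carbon cost of enforcing the acyl-chain distribution
#'
#' Compares the permissive and enhanced models under the same exchange
#' constraints: the ATP cost is the drop in maximal ATP turnover divided by
#' the growth rate \[mmol ATP/gDW\], and the carbon cost is the difference in
#' net substrate carbon consumption of the two pFBA solutions
#' (`sum(uptake flux x C atoms) - sum(secretion flux x C atoms)`, real
#' exchanges only), also per gram biomass \[mmol C/gDW\].
#'
#' @param permissive A `slime_model`, variant `"permissive"` (or the same
#'   object as `enhanced` for a self-comparison, which returns zero costs).
#' @param enhanced A `slime_model`, variant `"enhanced"` or `"restrictive"`.
#' @param constraints Optional [exchange_constraints()] applied to both.
#' @return List: `atp_cost`, `carbon_cost`, `max_atp_permissive`,
#'   `max_atp_enhanced`, `gam_per_gDW`, `ngam`, `growth_rate`, and
#'   `carbon_cost_definition` documenting the formula used.
#' @export
cost_delta <- function(permissive, enhanced, constraints = NULL) {
  stopifnot(inherits(permissive, "slime_model"),
            inherits(enhanced, "slime_model"))
  self_cmp <- identical(permissive$variant, enhanced$variant)
  if (!self_cmp &&
      (permissive$variant != "permissive" ||
       !(enhanced$variant %in% c("enhanced", "restrictive")))) {
    stop(sprintf("cost_delta(): variant mismatch (got '%s' vs '%s')",
                 permissive$variant, enhanced$variant))
  }
  if (!is.null(constraints)) {
    permissive <- constrain_exchanges(permissive, constraints)
    enhanced <- constrain_exchanges(enhanced, constraints)
  }
  mu <- enhanced$data$growth_rate
  rp <- max_atp_turnover(permissive)
  re <- max_atp_turnover(enhanced)
  if (is.null(rp$accounting) || is.null(re$accounting)) {
    stop("cost_delta(): one of the models has no optimal solution")
  }
  atp_p <- rp$accounting$total_turnover
  atp_e <- re$accounting$total_turnover
  cp <- .net_carbon_consumption(permissive$model, rp$solution)
  ce <- .net_carbon_consumption(enhanced$model, re$solution)
  list(atp_cost = (atp_p - atp_e) / mu,
       carbon_cost = (ce - cp) / mu,
       max_atp_permissive = atp_p,
       max_atp_enhanced = atp_e,
       gam_per_gDW = re$accounting$gam_per_gDW,
       ngam = re$accounting$ngam,
       growth_rate = mu,
       carbon_cost_definition = paste(
         "(net substrate carbon consumption of enhanced pFBA -",
         "that of permissive pFBA) / growth rate; net consumption =",
         "sum over real exchanges of -flux * carbon atoms"))
}
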