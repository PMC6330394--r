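# Mass-consistency rescaling (one scalar factor on either the class or the
# chain profile) and biomass normalization to 1 g/gDW.

.add_temp_excretions <- function(model) {
  pseudo_mets <- model$mets$id[grepl("^(backbone_|chain_C)", model$mets$id) &
                                 model$mets$is_pseudo]
  pseudo_mets <- setdiff(pseudo_mets, c(.GENERIC_BACKBONE, .GENERIC_CHAIN))
  exc_ids <- paste0("EXC_tmp_", pseudo_mets)
  for (i in seq_along(pseudo_mets)) {
    model <- add_reaction(model, exc_ids[i],
                          stats::setNames(-1, pseudo_mets[i]),
                          lb = 0, ub = Inf, is_pseudo = TRUE,
                          subsystem = "temporary excretion")
  }
  list(model = model, exc_ids = exc_ids, mets = pseudo_mets)
}

# Minimum total excretion of unused backbones and chains, given data scaled
# by f on one side. Excretion fluxes are already mass rates [g/gDW/h] because
# the pseudo-metabolites carry g units.
.excretion_at <- function(enhanced, data_scaled) {
  tmp <- .update_pools(enhanced$model, data_scaled, enhanced$config)
  tmp <- .add_temp_excretions(tmp)
  w <- stats::setNames(rep(1, length(tmp$exc_ids)), tmp$exc_ids)
  obj <- .objective_vector(tmp$model, w)
  res <- .model_lp(tmp$model, obj, "min")
  if (res$status != "optimal") {
    return(list(status = res$status, e_back = NA_real_, e_chain = NA_real_,
                per_met = NULL))
  }
  flux <- stats::setNames(res$x, tmp$model$rxns$id)[tmp$exc_ids]
  names(flux) <- tmp$mets
  back <- grepl("^backbone_", tmp$mets)
  list(status = "optimal",
       e_back = sum(flux[back]), e_chain = sum(flux[!back]),
       per_met = flux)
}

.scale_data <- function(data, side, f) {
  if (side == "scale_chains") {
    data$chain_abundance <- data$chain_abundance * f
  } else {
    data$class_abundance <- data$class_abundance * f
  }
  data
}

#' Rescale abundance data to exact mass consistency
#'
#' SLIME constraints are exact mass balances, so the lipid-class profile and
#' the FAME chain profile must be mutually proportional. One side of the data
#' is multiplied by a single scalar `f`, chosen so that the minimum total
#' excretion of unused backbone and chain pseudo-metabolites (through
#' temporary excretion reactions, removed afterwards) drops to the mass
#' tolerance. `f` is located by bisection on a log-spaced bracket
#' `[1e-3, 1e3]`: the side of the residual (chain surplus vs backbone
#' surplus) tells the search direction, and the minimum-excretion LP at each
#' trial factor is exact and deterministic.
#'
#' @param enhanced A `slime_model` built with the unscaled data.
#' @param side `"scale_classes"` (default for FAME-anchored chemostat data)
#'   or `"scale_chains"` (when the total lipid fraction is assumed).
#' @param mass_tol Acceptable residual excretion \[g/gDW/h\], default 1e-9.
#' @param bracket Search bracket for `f`.
#' @param max_iter Bisection iterations (default 60).
#' @return The rescaled [abundance_data()], with attributes
#'   `scaling_factor` (`f`) and `residual_excretion`.
#' @export
rescale_abundances <- function(enhanced,
                               side = c("scale_classes", "scale_chains"),
                               mass_tol = 1e-9, bracket = c(1e-3, 1e3),
                               max_iter = 60L) {
  side <- match.arg(side)
  stopifnot(inherits(enhanced, "slime_model"))
  data <- enhanced$data

  consistent <- function(ev) {
    ev$status == "optimal" && ev$e_back <= mass_tol && ev$e_chain <= mass_tol
  }
  # Fixed point first: already-proportional data must return exactly f = 1.
  ev1 <- .excretion_at(enhanced, data)
  if (consistent(ev1)) {
    out <- data
    attr(out, "scaling_factor") <- 1
    attr(out, "residual_excretion") <- ev1$e_back + ev1$e_chain
    return(out)
  }

  lo <- log(bracket[1]); hi <- log(bracket[2])
  best <- NULL
  last_ev <- ev1
  for (i in seq_len(max_iter)) {
    f <- exp((lo + hi) / 2)
    ev <- .excretion_at(enhanced, .scale_data(data, side, f))
    last_ev <- ev
    if (consistent(ev)) { best <- f; break }
    # Direction: which side of the mass balance is in surplus?
    scaled_too_high <-
      if (ev$status != "optimal") {
        side == "scale_chains" # requirement on the scaled side unmeetable
      } else if (side == "scale_chains") {
        ev$e_back > ev$e_chain
      } else {
        ev$e_chain > ev$e_back
      }
    if (scaled_too_high) hi <- log(f) else lo <- log(f)
  }
  if (is.null(best)) {
    f <- exp((lo + hi) / 2)
    ev <- .excretion_at(enhanced, .scale_data(data, side, f))
    if (consistent(ev)) {
      best <- f
    } else {
      resid <- if (!is.null(ev$per_met)) ev$per_met else last_ev$per_met
      msg <- if (is.null(resid)) "model infeasible at the final factor"
      else paste(sprintf("%s: %.3g", names(resid)[resid > mass_tol],
                         resid[resid > mass_tol]), collapse = "; ")
      stop(sprintf(paste0("rescale_abundances(): no factor in [%g, %g] gives ",
                          "mass-consistent data; residual imbalance — %s"),
                   bracket[1], bracket[2], msg))
    }
  }
  ev <- .excretion_at(enhanced, .scale_data(data, side, best))
  out <- .scale_data(data, side, best)
  attr(out, "scaling_factor") <- best
  attr(out, "residual_excretion") <- ev$e_back + ev$e_chain
  out
}

#' Normalize the biomass composition to 1 g/gDW
#'
#' Scales the carbohydrate pseudo-reaction (the component that is typically
#' not measured) by a single factor so that the summed component masses —
#' measured non-lipid components from the data, plus the lipid mass counted
#' from the backbone pool coefficients — add up to 1 g/gDW. Chain-pool
#' coefficients are a parallel constraint on the same lipid mass, not
#' additional mass, so they do not enter the sum.
#'
#' @param model A `gem` with lipid pseudo-reactions installed.
#' @param data The (rescaled) [abundance_data()].
#' @param config A [slime_config()] naming `carb_rxn`.
#' @param tol Acceptable deviation from 1 g/gDW.
#' @return The model with the carbohydrate pseudo-reaction rescaled; the
#'   factor is stored in attribute `carb_scale`.
#' @export
normalize_biomass <- function(model, data, config, tol = 1e-9) {
  stopifnot(inherits(model, "gem"), inherits(data, "abundance_data"))
  if (is.null(config$carb_rxn) || !(config$carb_rxn %in% model$rxns$id)) {
    stop("normalize_biomass(): config$carb_rxn must name a reaction in the model")
  }
  other <- data$other_biomass
  other <- other[setdiff(names(other), "carbohydrate")]
  lipid_mass <- sum(data$class_abundance)
  m_other <- sum(other) + lipid_mass
  if (m_other > 1 + tol) {
    stop(sprintf(paste0("normalize_biomass(): non-carbohydrate biomass already ",
                        "%.4f g/gDW > 1; negative carbohydrate impossible"),
                 m_other))
  }
  s <- model$stoich[[config$carb_rxn]]
  subs <- s[s < 0]
  if (length(subs) == 0L) stop("carbohydrate pseudo-reaction has no substrates")
  mws <- vapply(names(subs), function(m) molecular_weight(met_formula(model, m)),
                numeric(1))
  if (all(mws == 0)) {
    stop("normalize_biomass(): carbohydrate substrates carry no formulas")
  }
  m_carb <- sum(abs(subs) * mws)
  factor <- (1 - m_other) / m_carb
  s[s < 0] <- s[s < 0] * factor
  model$stoich[[config$carb_rxn]] <- s
  stopifnot(abs(m_other + m_carb * factor - 1) <= tol)
  attr(model, "carb_scale") <- factor
  model
}

#' Biomass composition implied by model and data
#'
#' @param model A `gem` with lipid pseudo-reactions installed.
#' @param data The [abundance_data()].
#' @param config A [slime_config()].
#' @return Named numeric vector of component masses \[g/gDW\] including
#'   `lipid` and `carbohydrate`.
#' @export
biomass_composition <- function(model, data, config) {
  other <- data$other_biomass
  other <- other[setdiff(names(other), "carbohydrate")]
  out <- c(other, lipid = sum(data$class_abundance))
  if (!is.null(config$carb_rxn) && config$carb_rxn %in% model$rxns$id) {
    s <- model$stoich[[config$carb_rxn]]
    subs <- s[s < 0]
    mws <- vapply(names(subs),
                  function(m) molecular_weight(met_formula(model, m)),
                  numeric(1))
    out <- c(out, carbohydrate = sum(abs(subs) * mws))
  }
  out
}
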