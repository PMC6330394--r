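# Deterministic synthetic fixtures with known ground truth. These do not try
# to reproduce yeast biochemistry; they reproduce the mathematical structure
# the formalism operates on — lipid classes x acyl chains x synthesis costs —
# on a small carbon/ATP core network, with abundance data generated from a
# known species distribution so it is exactly mass-consistent by
# construction.
#
# Formula convention: a species of class i with chain k carries the formula
# of m_i copies of the chain (m_i in {2,3,4}), i.e. a constant chain-mass
# fraction 1/m_i across the class. That makes the total deliverable chain
# mass an invariant of the class masses, so the mass-consistency rescaling
# factor is unique — see the methods vignette for why this matters.

.chain_synthesis_cost <- function(chain) {
  ch <- parse_chain_label(chain)
  # acetyl units and ATP per mmol chain; elongation past C16 and
  # desaturation are deliberately wasteful so that shorter, more saturated
  # chains are strictly cheaper per gram of lipid mass.
  ch$carbons / 2 + max(0, ch$carbons - 16) + 2 * ch$double_bonds
}

.assemble_lipid_fixture <- function(class_names, m, chain_labels, w, a,
                                    mu = 0.1, ngam = 0.7, glc_lb = -10,
                                    pen = NULL, protein = 0.5, rna = 0.06,
                                    carb_prior = 0.30, measured_glc = -9.5) {
  K <- length(class_names); C <- length(chain_labels)
  stopifnot(length(m) == K, nrow(w) == K, ncol(w) == C, length(a) == K)
  if (is.null(pen)) pen <- matrix(0, K, C)
  chain_mw <- vapply(chain_labels, chain_weight, numeric(1))
  chain_comp <- lapply(chain_labels, chain_formula)

  # Ground-truth species distribution [mmol/gDW] and the implied marginals.
  x <- matrix(0, K, C, dimnames = list(class_names, chain_labels))
  for (i in seq_len(K)) {
    denom <- m[i] * sum(w[i, ] * chain_mw)
    x[i, ] <- a[i] * w[i, ] / denom
  }
  class_chain_mass <- sweep(x, 2L, chain_mw, `*`)
  b <- colSums(class_chain_mass)

  mdl <- gem(id = "lipid_toy")
  addm <- function(mdl, id, name, comp, formula = "", pseudo = FALSE) {
    add_metabolite(mdl, id, name, comp, formula, pseudo)
  }
  mdl <- addm(mdl, "glc_e", "glucose [extracellular]", "e", "C6H12O6")
  mdl <- addm(mdl, "co2_e", "carbon dioxide [extracellular]", "e", "CO2")
  mdl <- addm(mdl, "glc_c", "glucose", "c", "C6H12O6")
  mdl <- addm(mdl, "ac", "acetyl unit", "c", "C2H4O2")
  mdl <- addm(mdl, "atp", "ATP equivalent", "c")
  mdl <- addm(mdl, "aa", "amino acid", "c", "C2H5NO2")
  mdl <- addm(mdl, "carbU", "glycan unit", "c", "C6H10O5")
  mdl <- addm(mdl, "ntp", "NTP", "c", "C10H14N5O7P")
  for (k in seq_len(C)) {
    mdl <- addm(mdl, paste0("fa_", .sanitize_id(chain_labels[k])),
                sprintf("fatty acid (%s)", chain_labels[k]), "c",
                format_formula(chain_comp[[k]]))
  }
  for (i in seq_len(K)) {
    mdl <- addm(mdl, paste0("head_", .sanitize_id(class_names[i])),
                sprintf("head group of %s", class_names[i]), "c", "C3H8O3")
  }
  sp_id <- matrix("", K, C)
  for (i in seq_len(K)) for (k in seq_len(C)) {
    comp <- Reduce(combine_formulas, rep(list(chain_comp[[k]]), m[i]))
    sp_id[i, k] <- paste0("sp_", .sanitize_id(class_names[i]), "_",
                          .sanitize_id(chain_labels[k]))
    mdl <- addm(mdl, sp_id[i, k],
                sprintf("%s (%s)", class_names[i], chain_labels[k]), "c",
                format_formula(comp))
  }
  for (i in seq_len(K)) {
    mdl <- addm(mdl, paste0("class_", .sanitize_id(class_names[i])),
                sprintf("%s [generic class]", class_names[i]), "c",
                pseudo = TRUE)
  }
  for (nm in c("prot", "carb", "rna", "lipid", "biomass")) {
    mdl <- addm(mdl, nm, paste0(nm, " [pseudo]"), "c", pseudo = TRUE)
  }

  addr <- function(mdl, id, stoich, lb = 0, ub = Inf, pseudo = FALSE,
                   subsystem = "") {
    add_reaction(mdl, id, stoich, lb, ub, pseudo, subsystem)
  }
  mdl <- addr(mdl, "EX_glc", c(glc_e = -1), lb = glc_lb, ub = 0,
              subsystem = "exchange")
  mdl <- addr(mdl, "EX_co2", c(co2_e = -1), lb = 0, ub = Inf,
              subsystem = "exchange")
  mdl <- addr(mdl, "T_glc", c(glc_e = -1, glc_c = 1))
  mdl <- addr(mdl, "R_glycolysis", c(glc_c = -1, ac = 3, atp = 2))
  mdl <- addr(mdl, "R_respiration", c(ac = -1, atp = 4, co2_e = 2))
  mdl <- addr(mdl, "R_aa_syn", c(ac = -1, atp = -2, aa = 1))
  mdl <- addr(mdl, "R_carbU_syn", c(glc_c = -1, atp = -1, carbU = 1))
  mdl <- addr(mdl, "R_ntp_syn", c(ac = -2, atp = -3, ntp = 1))
  for (k in seq_len(C)) {
    n_k <- .chain_synthesis_cost(chain_labels[k])
    mdl <- addr(mdl, paste0("R_fa_", .sanitize_id(chain_labels[k])),
                stats::setNames(c(-n_k, -n_k, 1),
                                c("ac", "atp",
                                  paste0("fa_", .sanitize_id(chain_labels[k])))),
                subsystem = "fatty acid synthesis")
  }
  for (i in seq_len(K)) {
    mdl <- addr(mdl, paste0("R_head_", .sanitize_id(class_names[i])),
                stats::setNames(c(-2, -1, 1),
                                c("ac", "atp",
                                  paste0("head_", .sanitize_id(class_names[i])))))
  }
  for (i in seq_len(K)) for (k in seq_len(C)) {
    mdl <- addr(mdl, paste0("R_syn_", .sanitize_id(class_names[i]), "_",
                            .sanitize_id(chain_labels[k])),
                stats::setNames(
                  c(-1, -1, -(1 + pen[i, k]), 1),
                  c(paste0("head_", .sanitize_id(class_names[i])),
                    paste0("fa_", .sanitize_id(chain_labels[k])),
                    "atp", sp_id[i, k])),
                subsystem = "lipid synthesis")
  }
  # Permissive-approach baseline: class pseudo-reactions (specific lipid ->
  # generic class, unit coefficients) plus one old-style lipid
  # pseudo-reaction over classes. Both get replaced by the enhancement.
  for (i in seq_len(K)) for (k in seq_len(C)) {
    mdl <- addr(mdl, paste0("R_class_", .sanitize_id(class_names[i]), "_",
                            .sanitize_id(chain_labels[k])),
                stats::setNames(c(-1, 1),
                                c(sp_id[i, k],
                                  paste0("class_", .sanitize_id(class_names[i])))),
                pseudo = TRUE, subsystem = "class pseudo-reactions")
  }
  mdl <- addr(mdl, "R_lipid_old",
              c(stats::setNames(-a, paste0("class_", .sanitize_id(class_names))),
                lipid = 1), pseudo = TRUE, subsystem = "lipid pseudo-reactions")
  mdl <- addr(mdl, "R_prot",
              c(aa = -protein / molecular_weight("C2H5NO2"), prot = 1),
              pseudo = TRUE, subsystem = "biomass components")
  mdl <- addr(mdl, "R_carb",
              c(carbU = -carb_prior / molecular_weight("C6H10O5"), carb = 1),
              pseudo = TRUE, subsystem = "biomass components")
  mdl <- addr(mdl, "R_rna",
              c(ntp = -rna / molecular_weight("C10H14N5O7P"), rna = 1),
              pseudo = TRUE, subsystem = "biomass components")
  mdl <- addr(mdl, "R_biomass",
              c(prot = -1, carb = -1, rna = -1, lipid = -1, biomass = 1),
              pseudo = TRUE, subsystem = "biomass")
  mdl <- addr(mdl, "EX_biomass", c(biomass = -1), lb = mu, ub = mu,
              pseudo = TRUE, subsystem = "exchange")
  mdl <- addr(mdl, "R_atpm", c(atp = -1), lb = ngam, ub = Inf,
              subsystem = "maintenance")
  mdl <- set_objective(mdl, c(R_atpm = 1))

  rules <- naming_rules(
    rules = lapply(class_names, function(cl) {
      list(class = cl,
           pattern = paste0("^", cl, " \\((.+)\\)$"), chain_sep = "-")
    }),
    candidate_pattern = paste0("^(", paste(class_names, collapse = "|"), ") "))

  data <- abundance_data(
    class_abundance = stats::setNames(a, class_names),
    chain_abundance = stats::setNames(b, chain_labels),
    other_biomass = c(protein = protein, RNA = rna),
    measured_exchanges = c(EX_glc = measured_glc),
    growth_rate = mu)

  structure(list(
    model = mdl, data = data,
    config = slime_config("R_biomass", "lipid", "R_atpm", "R_carb", ngam),
    rules = rules,
    truth = list(species_mmol = x, class_chain_mass = class_chain_mass,
                 molar_pref = w, m = stats::setNames(m, class_names),
                 chain_mw = stats::setNames(chain_mw, chain_labels),
                 class_abundance = stats::setNames(a, class_names))
  ), class = "lipid_fixture")
}

#' @export
print.lipid_fixture <- function(x, ...) {
  cat(sprintf("<lipid fixture: %d classes x %d chains, mu = %.3g 1/h>\n",
              nrow(x$truth$species_mmol), ncol(x$truth$species_mmol),
              x$data$growth_rate))
  invisible(x)
}

#' The three-class / two-chain toy model
#'
#' A fixed (seedless) hypothetical network of three lipid classes and two
#' acyl chains (16:0 and 18:0, six species), with a substrate-to-chain
#' synthesis pathway in which the shorter chain costs strictly less carbon
#' and ATP per gram of lipid, an ATP maintenance reaction, a biomass
#' pseudo-reaction, chemostat-style growth pinned at 0.1 1/h, and exactly
#' mass-consistent abundance tables generated from a known heterogeneous
#' species distribution (the classes prefer 16:0 at molar shares 0.7, 0.3
#' and 0.5). The baseline model uses the permissive class-pseudo-reaction
#' formulation; [enhance_model()] turns it into the SLIME formulation.
#'
#' @return A `lipid_fixture`: list with `model`, `data`, `config`, `rules`
#'   and ground `truth`.
#' @export
toy_fig1_model <- function() {
  .assemble_lipid_fixture(
    class_names = c("L1", "L2", "L3"),
    m = c(2L, 3L, 4L),
    chain_labels = c("16:0", "18:0"),
    w = rbind(c(0.7, 0.3), c(0.3, 0.7), c(0.5, 0.5)),
    a = c(0.030, 0.028, 0.022))
}

#' Seeded random lipid network
#'
#' Scaled-up analog of the toy: `n_classes` lipid classes over the given
#' chain labels, per-class chain preferences drawn from a seeded generator
#' (classes prefer different chains), class masses summing to 0.08 g/gDW,
#' and abundance data generated from the drawn ground truth (hence exactly
#' mass-consistent). With `corner_preferences = TRUE` each class's true
#' distribution sits entirely on one preferred chain and using any other
#' chain carries an ATP assembly penalty, which makes the cost-optimal
#' species assignment unique and equal to the truth — the setting for
#' contrasting enhanced and restrictive predictions.
#'
#' @param n_classes Number of lipid classes (>= 1).
#' @param chain_labels Character vector of chain labels (>= 1).
#' @param seed Integer seed; identical seeds give identical fixtures.
#' @param corner_preferences Draw one-chain-per-class ground truth with
#'   penalized off-preference assembly (default `FALSE`).
#' @return A `lipid_fixture`.
#' @export
random_lipid_network <- function(n_classes, chain_labels, seed,
                                 corner_preferences = FALSE) {
  stopifnot(n_classes >= 1L, length(chain_labels) >= 1L)
  for (attempt in 0:4) {
    fix <- withr::with_seed(seed + attempt * 1000003L, {
      K <- n_classes; C <- length(chain_labels)
      m <- sample(2:4, K, replace = TRUE)
      a <- stats::runif(K, 0.5, 1.5)
      a <- a / sum(a) * 0.08
      if (corner_preferences) {
        pref <- sample(rep_len(seq_len(C), K))
        w <- matrix(0, K, C)
        w[cbind(seq_len(K), pref)] <- 1
        pen <- matrix(2, K, C)
        pen[cbind(seq_len(K), pref)] <- 0
      } else {
        w <- matrix(stats::rgamma(K * C, shape = 1) + 0.05, K, C)
        w <- w / rowSums(w)
        pen <- matrix(0, K, C)
      }
      .assemble_lipid_fixture(
        class_names = paste0("LC", seq_len(K)), m = m,
        chain_labels = chain_labels, w = w, a = a, pen = pen)
    })
    sol <- fba(fix$model, "max")
    if (sol$status == "optimal") return(fix)
    message(sprintf("random_lipid_network: infeasible draw, retrying (attempt %d)",
                    attempt + 2L))
  }
  stop("random_lipid_network: no feasible draw in 5 attempts")
}

#' Stress-level series of abundance datasets
#'
#' Emulates growth under increasing stress: the acyl-chain distribution
#' shifts monotonically from the all-shortest-chain composition (level 0 —
#' exactly what an unconstrained, permissive model would choose) toward the
#' base fixture's heterogeneous composition, while the non-growth ATP
#' maintenance rises linearly. Class masses stay constant, so every level's
#' data remains exactly mass-consistent.
#'
#' @param n_levels Number of levels (>= 2).
#' @param base A `lipid_fixture` (default [toy_fig1_model()]).
#' @param ngam_rise Total NGAM increase across the series \[mmol/gDW/h\].
#' @return List of levels, each a list with `level`, `lambda`, `data`
#'   (an [abundance_data()]) and `ngam`.
#' @export
stress_series <- function(n_levels, base = toy_fig1_model(), ngam_rise = 0.8) {
  stopifnot(n_levels >= 2L, inherits(base, "lipid_fixture"))
  tr <- base$truth
  chain_labels <- colnames(tr$species_mmol)
  ord <- order(vapply(chain_labels, function(l) parse_chain_label(l)$carbons,
                      numeric(1)),
               vapply(chain_labels, function(l) parse_chain_label(l)$double_bonds,
                      numeric(1)))
  shortest <- ord[1]
  K <- nrow(tr$species_mmol); C <- length(chain_labels)
  lapply(seq_len(n_levels) - 1L, function(lev) {
    lambda <- lev / (n_levels - 1L)
    w0 <- matrix(0, K, C); w0[, shortest] <- 1
    w <- (1 - lambda) * w0 + lambda * tr$molar_pref
    x <- matrix(0, K, C, dimnames = dimnames(tr$species_mmol))
    for (i in seq_len(K)) {
      x[i, ] <- tr$class_abundance[i] * w[i, ] /
        (tr$m[i] * sum(w[i, ] * tr$chain_mw))
    }
    b <- colSums(sweep(x, 2L, tr$chain_mw, `*`))
    data <- base$data
    data$chain_abundance <- stats::setNames(b, chain_labels)
    list(level = lev, lambda = lambda, data = data,
         ngam = base$config$ngam + ngam_rise * lambda)
  })
}

#' ATP/carbon cost curve over a stress series
#'
#' For each level, builds the enhanced and permissive variants from the base
#' fixture with the level's data and maintenance setting, applies the
#' measured exchange constraints, and computes [cost_delta()].
#'
#' @param base A `lipid_fixture`.
#' @param series Output of [stress_series()] (default: 4 levels).
#' @param rescale Rescaling side passed to [enhance_model()] (fixture data
#'   is consistent by construction, so `"none"` is exact and fastest).
#' @return Data frame: `level`, `lambda`, `ngam`, `atp_cost`, `carbon_cost`,
#'   `max_atp_permissive`, `max_atp_enhanced`.
#' @export
stress_cost_curve <- function(base, series = stress_series(4L, base),
                              rescale = "none") {
  stopifnot(inherits(base, "lipid_fixture"))
  rows <- lapply(series, function(lv) {
    mdl <- set_bounds(base$model, base$config$atpm_rxn, lb = lv$ngam)
    cfg <- base$config
    cfg$ngam <- lv$ngam
    enh <- enhance_model(mdl, lv$data, base$rules, cfg, rescale = rescale)
    perm <- make_permissive(enh)
    cd <- cost_delta(perm, enh,
                     exchange_constraints(lv$data$measured_exchanges))
    data.frame(level = lv$level, lambda = lv$lambda, ngam = lv$ngam,
               atp_cost = cd$atp_cost, carbon_cost = cd$carbon_cost,
               max_atp_permissive = cd$max_atp_permissive,
               max_atp_enhanced = cd$max_atp_enhanced)
  })
  do.call(rbind, rows)
}
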