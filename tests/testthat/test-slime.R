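test_that("SLIME coefficients are the molecular weights, with chain multiplicity", {
  pi_sp <- lipid_species("pi_1", "PI", c("16:0", "18:1"), "C43H81O13P")
  sr <- build_slime_reaction(pi_sp)
  # backbone carries the full lipid MW; hand sums with IUPAC 2021 masses
  expect_equal(sr$backbone_coeff, 0.837082, tolerance = 1e-9)
  expect_equal(sr$chain_coeffs[["16:0"]], 0.25643, tolerance = 1e-9)
  expect_equal(sr$chain_coeffs[["18:1"]], 0.282468, tolerance = 1e-9)

  tag <- lipid_species("tag_1", "TAG", c("16:0", "16:0", "18:1"), "C53H100O6")
  sr_tag <- build_slime_reaction(tag)
  expect_equal(sr_tag$chain_coeffs[["16:0"]], 2 * 0.25643, tolerance = 1e-9)
  expect_equal(sr_tag$chain_coeffs[["18:1"]], 0.282468, tolerance = 1e-9)

  erg <- lipid_species("erg", "ERG", character(0), "C28H44O")
  sr_erg <- build_slime_reaction(erg)
  expect_length(sr_erg$chain_coeffs, 0)
  expect_equal(sr_erg$backbone_coeff, molecular_weight("C28H44O"))

  nf <- lipid_species("nf", "PI", character(0), "")
  expect_error(build_slime_reaction(nf), "'nf'")
})

test_that("chain mass never exceeds the backbone mass in any fixture SLIME reaction", {
  for (x in list(toy_enhanced(),
                 {
                   rn <- random_lipid_network(5, c("16:0", "18:0", "18:1"), 3)
                   enhance_model(rn$model, rn$data, rn$rules, rn$config,
                                 rescale = "none")
                 })) {
    for (sp in x$species) {
      sr <- build_slime_reaction(sp)
      expect_lte(sum(sr$chain_coeffs), sr$backbone_coeff + 1e-12)
    }
  }
})

test_that("the three lipid pseudo-reactions have the expected census on the toy", {
  enh <- toy_enhanced()
  m <- enh$model
  bp <- m$stoich[["PSEUDO_backbone_pool"]]
  cp <- m$stoich[["PSEUDO_chain_pool"]]
  mg <- m$stoich[["PSEUDO_lipid_merge"]]
  expect_equal(sum(bp < 0), 3) # 3 class backbones in
  expect_equal(sum(bp > 0), 1)
  expect_equal(sum(cp < 0), 2) # 2 chains in
  expect_equal(sum(cp > 0), 1)
  expect_equal(sum(mg < 0), 2) # generic backbone + generic chain
  expect_equal(sum(mg > 0), 1) # generic lipid
  # backbone pool coefficients are the (rescaled) class abundances
  expect_equal(unname(-bp[paste0("backbone_", names(enh$data$class_abundance))]),
               unname(enh$data$class_abundance), tolerance = 1e-12)
  v <- validate_slime(enh)
  expect_true(v$ok)
})

test_that("replaced class pseudo-reactions are gone and logged in provenance", {
  enh <- toy_enhanced()
  expect_false(any(grepl("^R_class_", enh$model$rxns$id)))
  expect_false("R_lipid_old" %in% enh$model$rxns$id)
  expect_equal(sum(grepl("^R_class_", enh$provenance$removed)), 6)
  expect_true("R_lipid_old" %in% enh$provenance$removed)
})

test_that("enhancement is guarded against re-entry", {
  fix <- toy_fixture()
  enh <- toy_enhanced()
  expect_error(
    install_pseudo_reactions(enh$model, enh$data, enh$config),
    "not re-entrant")
  expect_error(
    enhance_model(enh$model, fix$data, fix$rules, fix$config),
    "not re-entrant|no lipid species")
})

test_that("a class absent from the data leaves its species with zero flux", {
  fix <- toy_fixture()
  data <- fix$data
  # drop L3 consistently: remove its class mass and its chain contribution
  mass <- fix$truth$class_chain_mass
  data$class_abundance <- data$class_abundance[c("L1", "L2")]
  data$chain_abundance <- colSums(mass[c("L1", "L2"), ])
  enh <- enhance_model(fix$model, data, fix$rules, fix$config, rescale = "none")
  r <- max_atp_turnover(enh)
  expect_equal(r$solution$status, "optimal")
  l3_flux <- r$solution$fluxes[grep("^SLIME_sp_L3", names(r$solution$fluxes))]
  expect_equal(max(abs(l3_flux)), 0, tolerance = 1e-9)
})

test_that("rescaling already-consistent data is the identity (f = 1)", {
  enh <- toy_enhanced()
  out <- rescale_abundances(enh, side = "scale_chains")
  expect_equal(attr(out, "scaling_factor"), 1, tolerance = 1e-6)
  expect_lte(attr(out, "residual_excretion"), 1e-9)
})

test_that("rescaling recovers a known distortion of the chain totals", {
  fix <- toy_fixture()
  enh <- enhance_model(fix$model, fix$data, fix$rules, fix$config,
                       rescale = "none")
  d2 <- fix$data
  d2$chain_abundance <- d2$chain_abundance * 2
  enh2 <- enh
  enh2$data <- d2
  enh2$model <- slimekit:::.update_pools(enh$model, d2, fix$config)
  out <- rescale_abundances(enh2, side = "scale_chains")
  expect_equal(attr(out, "scaling_factor"), 0.5, tolerance = 1e-4)
  expect_lte(attr(out, "residual_excretion"), 1e-9)
  # scaling the class side of the same distortion instead
  out2 <- rescale_abundances(enh2, side = "scale_classes")
  expect_equal(attr(out2, "scaling_factor"), 2, tolerance = 1e-4)
})

test_that("biomass normalization fills the composition to 1 g/gDW via carbohydrate", {
  enh <- toy_enhanced()
  comp <- biomass_composition(enh$model, enh$data, enh$config)
  expect_equal(sum(comp), 1, tolerance = 1e-9)
  # protein 0.5 + RNA 0.06 + lipid 0.08 leaves 0.36 for carbohydrate
  expect_equal(unname(comp[["carbohydrate"]]),
               1 - 0.5 - 0.06 - sum(enh$data$class_abundance),
               tolerance = 1e-9)
  # applying again is the identity
  m2 <- normalize_biomass(enh$model, enh$data, enh$config)
  expect_equal(attr(m2, "carb_scale"), 1, tolerance = 1e-9)
})

test_that("an over-full composition (protein alone > 1 g/gDW) is rejected", {
  fix <- toy_fixture()
  data <- fix$data
  data$other_biomass["protein"] <- 1.05
  expect_error(
    enhance_model(fix$model, data, fix$rules, fix$config, rescale = "none"),
    "negative carbohydrate")
})
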