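test_that("exchange constraints apply ±5% on the magnitude, sign preserved", {
  m <- gem("exch")
  m <- add_metabolite(m, "glc", formula = "C6H12O6")
  m <- add_reaction(m, "EX_glc", c(glc = -1), lb = -1000, ub = 1000)
  m <- add_reaction(m, "EX_zero", c(glc = 1), lb = -10, ub = 10)
  out <- constrain_exchanges(m, exchange_constraints(c(EX_glc = -20.4)))
  i <- match("EX_glc", out$rxns$id)
  expect_equal(out$rxns$lb[i], -21.42, tolerance = 1e-12)
  expect_equal(out$rxns$ub[i], -19.38, tolerance = 1e-12)
  # zero tolerance pins equality; measured zero pins to zero
  out <- constrain_exchanges(m, exchange_constraints(c(EX_glc = -5), tolerance = 0))
  i <- match("EX_glc", out$rxns$id)
  expect_equal(c(out$rxns$lb[i], out$rxns$ub[i]), c(-5, -5))
  out <- constrain_exchanges(m, exchange_constraints(c(EX_zero = 0)))
  i <- match("EX_zero", out$rxns$id)
  expect_equal(c(out$rxns$lb[i], out$rxns$ub[i]), c(0, 0))
})

test_that("exchange constraints reject unknown or non-exchange reactions", {
  fix <- toy_fixture()
  expect_error(constrain_exchanges(fix$model,
                                   exchange_constraints(c(EX_nope = -1))),
               "unknown")
  expect_error(constrain_exchanges(fix$model,
                                   exchange_constraints(c(R_glycolysis = -1))),
               "not exchange")
})

test_that("ATP accounting decomposes turnover into NGAM and GAM", {
  enh <- toy_enhanced()
  r <- max_atp_turnover(enh)
  acc <- r$accounting
  expect_gte(acc$total_turnover, acc$ngam)
  expect_equal(acc$gam_per_gDW,
               (acc$total_turnover - acc$ngam) / acc$growth_rate)
  expect_equal(acc$ngam, 0.7)
})

test_that("a missing maintenance reaction lists candidate ids", {
  fix <- toy_fixture()
  expect_error(max_atp_turnover(fix$model, atpm_rxn = "nope",
                                ngam = 0.7, growth_rate = 0.1),
               "R_atpm")
})

test_that("starvation (all exchanges closed) is infeasible under growth demand", {
  enh <- toy_enhanced()
  m <- set_bounds(enh$model, "EX_glc", lb = 0, ub = 0)
  x <- enh
  x$model <- m
  r <- max_atp_turnover(x)
  expect_null(r$accounting)
  expect_equal(r$solution$status, "infeasible")
})

test_that("grouped lipid FVA brackets the pFBA point at fixed maximal ATP", {
  enh <- toy_enhanced()
  for (cl in c("L1", "L2")) {
    for (ch in c("16:0", "18:0")) {
      vr <- lipid_variability(enh, cl, ch)
      expect_lte(vr$min_mass_rate, vr$pfba_value + 1e-8)
      expect_gte(vr$max_mass_rate, vr$pfba_value - 1e-8)
    }
  }
  expect_error(lipid_variability(enh, "L9", "16:0"), "unknown lipid class")
  expect_error(lipid_variability(enh, "L1", "20:0"), "no species")
})

test_that("a class with no degrees of freedom collapses its FVA to a point", {
  # one class, one chain: the SLIME flux is pinned by the class requirement
  rn <- random_lipid_network(1, "16:0", seed = 2)
  enh <- enhance_model(rn$model, rn$data, rn$rules, rn$config, rescale = "none")
  vr <- lipid_variability(enh, "LC1", "16:0")
  expect_equal(vr$min_mass_rate, vr$max_mass_rate, tolerance = 1e-8)
  expect_equal(vr$pfba_value, vr$max_mass_rate, tolerance = 1e-8)
})

test_that("sampled abundances scale inversely with the growth rate", {
  enh <- toy_enhanced()
  a1 <- sample_lipid_distributions(enh, 10, seed = 3, thin = 10)
  a2 <- sample_lipid_distributions(enh, 10, seed = 3, thin = 10,
                                   growth_rate = 0.2)
  expect_equal(a1[, colnames(a1)] / 2, a2[, colnames(a1)], tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_error(sample_lipid_distributions(enh, 5, seed = 1, growth_rate = 0),
               "positive")
})

test_that("cost_delta is zero for a self-comparison and guards variants", {
  enh <- toy_enhanced()
  perm <- toy_permissive()
  cd <- cost_delta(enh, enh)
  expect_equal(cd$atp_cost, 0, tolerance = 1e-8)
  expect_equal(cd$carbon_cost, 0, tolerance = 1e-8)
  expect_error(cost_delta(enh, perm), "variant mismatch")
})

test_that("forcing the longer chain costs ATP, matching independent LPs", {
  enh <- toy_enhanced()
  perm <- toy_permissive()
  constraints <- exchange_constraints(enh$data$measured_exchanges)
  cd <- cost_delta(perm, enh, constraints)
  expect_gt(cd$atp_cost, 0)
  expect_gt(cd$carbon_cost, 0)
  # oracle: two independent plain FBA solves
  brute <- function(x) {
    m <- constrain_exchanges(x$model, constraints)
    m <- set_objective(m, setNames(1, x$config$atpm_rxn))
    fba(m, "max")$objective_value
  }
  expect_equal(cd$atp_cost,
               (brute(perm) - brute(enh)) / enh$data$growth_rate,
               tolerance = 1e-6)
})
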