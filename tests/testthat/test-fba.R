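test_that("fba reports the optimum forced by bounds on a one-path model", {
  m <- micro_chain_model()
  sol <- fba(m, "max")
  expect_equal(sol$status, "optimal")
  expect_equal(sol$objective_value, 1)
  expect_equal(unname(sol$fluxes), c(1, 1, 1))
})

test_that("fba on the toy model gives a finite optimum at steady state", {
  fix <- toy_fixture()
  sol <- fba(fix$model, "max")
  expect_equal(sol$status, "optimal")
  expect_true(is.finite(sol$objective_value) && sol$objective_value > 0)
  S <- as.matrix(stoich_matrix(fix$model))
  expect_lt(max(abs(S %*% sol$fluxes)), 1e-6)
  expect_true(all(sol$fluxes >= fix$model$rxns$lb - 1e-6))
  expect_true(all(sol$fluxes <= fix$model$rxns$ub + 1e-6))
})

test_that("closing all exchanges leaves the null flux as the only solution", {
  fix <- toy_fixture()
  m <- fix$model
  m <- set_bounds(m, "EX_glc", lb = 0, ub = 0)
  m <- set_bounds(m, "EX_co2", lb = 0, ub = 0)
  m <- set_bounds(m, "EX_biomass", lb = 0, ub = 0)
  m <- set_bounds(m, "R_atpm", lb = 0)
  sol <- fba(m, "max")
  expect_equal(sol$status, "optimal")
  expect_equal(max(abs(sol$fluxes)), 0, tolerance = 1e-9)
})

test_that("fba errors on an empty objective and reports infeasibility", {
  m <- micro_chain_model()
  m$objective <- setNames(numeric(0), character(0))
  expect_error(fba(m), "empty objective")
  m <- micro_chain_model()
  m <- set_bounds(m, "demand", lb = 2, ub = 5) # demand above supply cap
  expect_equal(fba(m, "max")$status, "infeasible")
})

test_that("pfba keeps the stage-1 optimum and never increases total flux", {
  fix <- toy_fixture()
  f <- fba(fix$model, "max")
  p <- pfba(fix$model, "max")
  expect_equal(p$objective_value, f$objective_value,
               tolerance = 1e-6)
  expect_lte(total_flux(p), total_flux(f) + 1e-6)
})

test_that("pfba carries zero flux on a futile cycle parallel to the optimum", {
  m <- micro_chain_model()
  # add a futile cycle B <-> A that FBA could spin freely (capped)
  m <- add_reaction(m, "cycle_fwd", c(A = -1, B = 1), lb = 0, ub = 50)
  m <- add_reaction(m, "cycle_rev", c(B = -1, A = 1), lb = 0, ub = 50)
  p <- pfba(m, "max")
  expect_equal(p$objective_value, 1, tolerance = 1e-7)
  expect_equal(unname(p$fluxes[c("cycle_fwd", "cycle_rev")]), c(0, 0),
               tolerance = 1e-7)
})

test_that("pfba equals fba on a single linear pathway (unique solution)", {
  m <- micro_chain_model()
  expect_equal(pfba(m, "max")$fluxes, fba(m, "max")$fluxes, tolerance = 1e-7)
})

test_that("fva_linear brackets any feasible point and handles edge cases", {
  fix <- toy_fixture()
  # fixed-flux exchange: interval collapses to the pinned bound
  rng <- fva_linear(fix$model, c(EX_biomass = 1))
  expect_equal(unname(rng), c(0.1, 0.1), tolerance = 1e-9)
  # empty combination is the zero functional
  expect_equal(unname(fva_linear(fix$model, setNames(numeric(0), character(0)))),
               c(0, 0))
  # a pFBA solution lies inside the FVA interval of any weighting
  p <- pfba(fix$model, "max")
  w <- c(R_respiration = 2, R_glycolysis = 1)
  rng <- fva_linear(fix$model, w)
  val <- sum(w * p$fluxes[names(w)])
  expect_gte(val, rng[["min"]] - 1e-8)
  expect_lte(val, rng[["max"]] + 1e-8)
})

test_that("fva_linear distinguishes infeasible from unbounded", {
  m <- micro_chain_model()
  m2 <- set_bounds(m, "demand", lb = 2)
  expect_error(fva_linear(m2, c(demand = 1)), "infeasible")
  m3 <- micro_chain_model()
  m3 <- add_reaction(m3, "vent", c(A = 1)) # uncapped inflow
  expect_error(fva_linear(m3, c(vent = 1)), "unbounded")
})
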