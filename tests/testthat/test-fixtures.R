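test_that("the toy fixture is deterministic and exactly mass-consistent", {
  f1 <- toy_fig1_model()
  f2 <- toy_fig1_model()
  expect_identical(f1$model, f2$model)
  expect_identical(f1$data, f2$data)
  # chain totals equal the class-mass-weighted chain fractions sum(a_i / m_i)
  expect_equal(sum(f1$data$chain_abundance),
               sum(f1$data$class_abundance / f1$truth$m), tolerance = 1e-12)
  # marginals of the ground-truth species distribution reproduce the tables
  mass <- f1$truth$class_chain_mass
  expect_equal(unname(rowSums(mass)),
               unname(f1$data$class_abundance / f1$truth$m),
               tolerance = 1e-12)
  expect_equal(unname(colSums(mass)), unname(f1$data$chain_abundance),
               tolerance = 1e-12)
})

test_that("random networks are reproducible and reach the target census", {
  r1 <- random_lipid_network(19, c("16:0", "16:1", "18:0", "18:1", "18:2", "14:0"),
                             seed = 42)
  r2 <- random_lipid_network(19, c("16:0", "16:1", "18:0", "18:1", "18:2", "14:0"),
                             seed = 42)
  expect_identical(r1$model, r2$model)
  expect_identical(r1$data, r2$data)
  enh <- enhance_model(r1$model, r1$data, r1$rules, r1$config, rescale = "none")
  v <- validate_slime(enh)
  expect_true(v$ok)
  expect_equal(unname(v$census[["backbone_mets"]]), 19)
  expect_equal(unname(v$census[["chain_mets"]]), 6)
  expect_equal(unname(v$census[["slime_reactions"]]), 19 * 6)
})

test_that("fixtures round-trip through SBML unchanged", {
  rn <- random_lipid_network(3, c("16:0", "18:1"), seed = 8)
  path <- withr::local_tempfile(fileext = ".xml")
  write_model_sbml(rn$model, path)
  back <- read_model_sbml(path)
  expect_identical(rn$model$mets, back$mets)
  expect_identical(rn$model$rxns, back$rxns)
  expect_equal(rn$model$stoich, back$stoich, tolerance = 1e-12)
})

test_that("feeding the ground truth back recovers the marginals under pFBA", {
  rn <- random_lipid_network(4, c("16:0", "18:0"), seed = 5)
  enh <- enhance_model(rn$model, rn$data, rn$rules, rn$config, rescale = "none")
  r <- max_atp_turnover(enh)
  prof <- chain_profile(enh, r$solution)
  mu <- rn$data$growth_rate
  # chain marginals are constraints: recovered to 1e-6 relative
  expect_equal(unname(colSums(prof)) / mu,
               unname(rn$data$chain_abundance[colnames(prof)]),
               tolerance = 1e-6)
  expect_equal(unname(rowSums(prof)) / mu,
               unname(rn$data$class_abundance[rownames(prof)] /
                        rn$truth$m[rownames(prof)]),
               tolerance = 1e-6)
})

test_that("the stress series shifts mass toward longer chains with rising NGAM", {
  fix <- toy_fixture()
  series <- stress_series(4, fix)
  share18 <- vapply(series, function(lv) {
    unname(lv$data$chain_abundance[["18:0"]] / sum(lv$data$chain_abundance))
  }, numeric(1))
  expect_equal(share18[1], 0)
  expect_true(all(diff(share18) > 0))
  ngams <- vapply(series, `[[`, numeric(1), "ngam")
  expect_true(all(diff(ngams) > 0))
  # class masses stay fixed, so every level remains mass-consistent
  for (lv in series) {
    expect_equal(sum(lv$data$chain_abundance),
                 sum(fix$data$class_abundance / fix$truth$m),
                 tolerance = 1e-12)
  }
})

test_that("two identical stress levels give equal costs", {
  fix <- toy_fixture()
  series <- stress_series(2, fix)
  series[[2]] <- series[[1]]
  cc <- stress_cost_curve(fix, series)
  expect_equal(cc$atp_cost[1], cc$atp_cost[2], tolerance = 1e-8)
  expect_equal(cc$carbon_cost[1], cc$carbon_cost[2], tolerance = 1e-8)
})
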