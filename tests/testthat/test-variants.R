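test_that("the permissive model routes all chain mass through the cheapest chain", {
  perm <- toy_permissive()
  r <- max_atp_turnover(perm)
  prof <- chain_profile(perm, r$solution)
  expect_gt(sum(prof[, "16:0"]), 0)
  expect_equal(sum(prof[, "18:0"]), 0, tolerance = 1e-9)
  # species-level: every 18:0 species is unused
  sl <- r$solution$fluxes[grep("^SLIME_sp_.*_18_0$", names(r$solution$fluxes))]
  expect_equal(max(abs(sl)), 0, tolerance = 1e-9)
})

test_that("variant builders guard against wrong input variants", {
  perm <- toy_permissive()
  expect_error(make_permissive(perm), "variant")
  expect_error(make_restrictive(perm), "variant")
})

test_that("the enhanced feasible set nests inside the permissive one (max ATP)", {
  enh <- toy_enhanced()
  perm <- toy_permissive()
  atp_e <- max_atp_turnover(enh)$accounting$total_turnover
  atp_p <- max_atp_turnover(perm)$accounting$total_turnover
  expect_gte(atp_p, atp_e * (1 - 1e-6))
})

test_that("restrictive chain fractions must sum to one", {
  enh <- toy_enhanced()
  expect_error(make_restrictive(enh, c("16:0" = 0.6, "18:0" = 0.6)),
               "sum to 1")
})

test_that("the restrictive model forces one global chain split on every class", {
  enh <- toy_enhanced()
  res <- make_restrictive(enh, c("16:0" = 0.5, "18:0" = 0.5))
  r <- max_atp_turnover(res)
  expect_equal(r$solution$status, "optimal")
  prof <- chain_profile(res, r$solution, fractions = TRUE)
  for (i in seq_len(nrow(prof))) {
    expect_equal(unname(prof[i, ]), c(0.5, 0.5), tolerance = 1e-6)
  }
})

test_that("a single chain with fraction 1 forces all lipids onto that chain", {
  enh <- toy_enhanced()
  # data must be consistent with the forced split: all mass on 16:0
  fix <- toy_fixture()
  tr <- fix$truth
  x16 <- tr$class_abundance / (tr$m * tr$chain_mw[["16:0"]])
  data <- fix$data
  data$chain_abundance <- c("16:0" = sum(x16 * tr$chain_mw[["16:0"]]),
                            "18:0" = 0)
  enh2 <- enhance_model(fix$model, data, fix$rules, fix$config,
                        rescale = "none")
  res <- make_restrictive(enh2, c("16:0" = 1))
  r <- max_atp_turnover(res)
  expect_equal(r$solution$status, "optimal")
  prof <- chain_profile(res, r$solution)
  expect_equal(sum(prof[, "18:0"]), 0, tolerance = 1e-9)
})

test_that("enhanced matches heterogeneous truth where restrictive cannot", {
  rn <- random_lipid_network(4, c("16:0", "16:1", "18:0"), seed = 21,
                             corner_preferences = TRUE)
  enh <- enhance_model(rn$model, rn$data, rn$rules, rn$config, rescale = "none")
  res <- make_restrictive(enh)
  pe <- chain_profile(enh, max_atp_turnover(enh)$solution, fractions = TRUE)
  pr <- chain_profile(res, max_atp_turnover(res)$solution, fractions = TRUE)
  truth <- rn$truth$class_chain_mass / rowSums(rn$truth$class_chain_mass)
  rmse <- function(a, b) sqrt(mean((a - b)^2))
  expect_lt(rmse(pe[rownames(truth), colnames(truth)], truth), 1e-6)
  expect_gt(rmse(pr[rownames(truth), colnames(truth)], truth), 0.1)
  # restrictive rows are all identical
  expect_lt(max(apply(pr, 2, function(col) diff(range(col)))), 1e-9)
})
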