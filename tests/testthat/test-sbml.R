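test_that("SBML round-trip preserves every model field", {
  fix <- toy_fixture()
  path <- withr::local_tempfile(fileext = ".xml")
  write_model_sbml(fix$model, path)
  m2 <- read_model_sbml(path)
  expect_identical(fix$model$mets, m2$mets)
  expect_identical(fix$model$rxns, m2$rxns)
  expect_equal(fix$model$stoich, m2$stoich, tolerance = 1e-12)
  expect_identical(fix$model$objective, m2$objective)
  expect_identical(fix$model$id, m2$id)
})

test_that("JSON dialect round-trip preserves the model, including infinite bounds", {
  fix <- toy_fixture()
  path <- withr::local_tempfile(fileext = ".json")
  write_model_json(fix$model, path)
  m2 <- read_model_json(path)
  expect_identical(fix$model$rxns$lb, m2$rxns$lb)
  expect_identical(fix$model$rxns$ub, m2$rxns$ub)
  expect_equal(fix$model$stoich, m2$stoich, tolerance = 1e-12)
  expect_identical(fix$model$mets$formula, m2$mets$formula)
})

test_that("malformed XML propagates a parse error naming the line", {
  path <- withr::local_tempfile(fileext = ".xml")
  writeLines(c("<?xml version=\"1.0\"?>", "<sbml>", "<unclosed>"), path)
  expect_error(read_model_sbml(path))
})

test_that("reactions without FBC bounds are reported by id", {
  fix <- toy_fixture()
  path <- withr::local_tempfile(fileext = ".xml")
  write_model_sbml(fix$model, path)
  txt <- readLines(path)
  txt <- sub('fbc:lowerFluxBound="[^"]*" ', "", txt[seq_along(txt)])
  path2 <- withr::local_tempfile(fileext = ".xml")
  writeLines(txt, path2)
  expect_error(read_model_sbml(path2), "without FBC flux bounds")
})

test_that("a file whose bounds violate lb <= ub fails validation", {
  m <- micro_chain_model()
  path <- withr::local_tempfile(fileext = ".xml")
  write_model_sbml(m, path)
  # swap the supply reaction's bound references to force lb > ub
  txt <- readLines(path)
  i <- grep('reaction id="supply"', txt)
  txt[i] <- sub('fbc:lowerFluxBound="(bnd_[0-9]+)" fbc:upperFluxBound="(bnd_[0-9]+)"',
                'fbc:lowerFluxBound="\\2" fbc:upperFluxBound="\\1"', txt[i])
  writeLines(txt, path)
  expect_error(read_model_sbml(path), "lb")
})

test_that("an independent SBML implementation reads the file identically", {
  # cross-check against the cobra/libsbml stack available in the environment
  fix <- toy_fixture()
  path <- withr::local_tempfile(fileext = ".xml")
  write_model_sbml(fix$model, path)
  script <- paste(
    "import cobra, warnings; warnings.filterwarnings('ignore')",
    sprintf("m = cobra.io.read_sbml_model(%s)", deparse(path)),
    "print(len(m.metabolites)); print(len(m.reactions))",
    "print(m.reactions.get_by_id('EX_glc').lower_bound)",
    "print(m.metabolites.get_by_id('sp_L1_16_0').formula)",
    "print(round(m.optimize().objective_value, 9))",
    sep = "; ")
  out <- suppressWarnings(
    system2("python", c("-c", shQuote(script)), stdout = TRUE, stderr = FALSE))
  expect_equal(as.integer(out[1]), nrow(fix$model$mets))
  expect_equal(as.integer(out[2]), nrow(fix$model$rxns))
  expect_equal(as.numeric(out[3]), -10)
  expect_identical(out[4], "C32H64O4")
  ours <- fba(fix$model, "max")$objective_value
  expect_equal(as.numeric(out[5]), ours, tolerance = 1e-6)
})
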