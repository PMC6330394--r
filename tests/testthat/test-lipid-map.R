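pi_rules <- function() {
  naming_rules(
    rules = list(
      list(class = "PI", pattern = "^PI \\((.+)\\)$", chain_sep = "-"),
      list(class = "ERG", pattern = "^ergosterol$", chains = character(0))),
    candidate_pattern = "^(PI |ergo|lipidlike)")
}

yeastish_model <- function() {
  m <- gem("yeastish")
  m <- add_metabolite(m, "pi_1", name = "PI (16:0-18:1)", formula = "C43H81O13P")
  m <- add_metabolite(m, "erg", name = "ergosterol", formula = "C28H44O")
  m <- add_metabolite(m, "mystery", name = "lipidlike thing", formula = "C10H20O2")
  m <- add_metabolite(m, "glc", name = "glucose", formula = "C6H12O6")
  m
}

test_that("naming rules extract class and chain configuration from names", {
  res <- map_model_lipids(yeastish_model(), pi_rules())
  ids <- vapply(res$species, `[[`, character(1), "id")
  pi <- res$species[[match("pi_1", ids)]]
  expect_equal(pi$lipid_class, "PI")
  expect_setequal(pi$chains, c("16:0", "18:1"))
  erg <- res$species[[match("erg", ids)]]
  expect_equal(erg$lipid_class, "ERG")
  expect_length(erg$chains, 0)
})

test_that("lipid-like metabolites with no matching rule are reported, not dropped", {
  res <- map_model_lipids(yeastish_model(), pi_rules())
  expect_equal(res$unmatched$id, "mystery")
  expect_match(res$unmatched$reason, "no naming rule")
  # non-candidates (glucose) are neither mapped nor reported
  expect_false("glc" %in% c(res$unmatched$id,
                            vapply(res$species, `[[`, character(1), "id")))
})

test_that("a species whose chains outweigh its formula is a consistency error", {
  m <- gem("bad")
  # two C18 chains cannot fit in a C20 molecule
  m <- add_metabolite(m, "bad_sp", name = "PI (18:0-18:0)", formula = "C20H40O4")
  expect_error(map_model_lipids(m, pi_rules()), "exceeds lipid formula")
  expect_error(lipid_species("x", "PI", c("18:0", "18:0"), "C20H40O4"),
               "exceeds")
})

test_that("matched species lacking a formula land in the unmatched report", {
  m <- gem("noformula")
  m <- add_metabolite(m, "pi_nf", name = "PI (16:0-18:1)")
  res <- map_model_lipids(m, pi_rules())
  expect_length(res$species, 0)
  expect_match(res$unmatched$reason, "no formula")
})

test_that("expected chain-position counts are enforced when a rule declares them", {
  rules <- naming_rules(
    rules = list(list(class = "PI", pattern = "^PI \\((.+)\\)$",
                      chain_sep = "-", n_chains = 2L)),
    candidate_pattern = "^PI ")
  m <- gem("lyso")
  m <- add_metabolite(m, "lpi", name = "PI (16:0)", formula = "C25H49O12P")
  res <- map_model_lipids(m, rules)
  expect_length(res$species, 0)
  expect_match(res$unmatched$reason, "expected 2 chain")
})

test_that("the unmatched report writes as TSV", {
  res <- map_model_lipids(yeastish_model(), pi_rules())
  path <- withr::local_tempfile(fileext = ".tsv")
  write_unmatched_report(res$unmatched, path)
  back <- read.delim(path)
  expect_equal(back$id, "mystery")
})
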