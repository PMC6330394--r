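# Shared fixtures, built once per test run. Enhancement of the toy is cheap
# (~1 s) but used by many files, so cache it.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

toy_fixture <- function() cached("toy", toy_fig1_model())

toy_enhanced <- function() {
  cached("toy_enh", {
    fix <- toy_fixture()
    enhance_model(fix$model, fix$data, fix$rules, fix$config,
                  rescale = "classes")
  })
}

toy_permissive <- function() cached("toy_perm", make_permissive(toy_enhanced()))

# A tiny linear chain: S -supply-> A -> B -> demand, supply capped at 1.
micro_chain_model <- function() {
  m <- gem("micro")
  m <- add_metabolite(m, "A", compartment = "c")
  m <- add_metabolite(m, "B", compartment = "c")
  m <- add_reaction(m, "supply", c(A = 1), lb = 0, ub = 1)
  m <- add_reaction(m, "conv", c(A = -1, B = 1))
  m <- add_reaction(m, "demand", c(B = -1))
  set_objective(m, c(demand = 1))
}
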