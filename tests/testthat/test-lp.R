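# The LP core. Oracles: brute-force vertex enumeration on a small network
# polytope, and boot::simplex (an independent implementation) on random
# dense LPs.

test_that("lp_solve handles the elementary cases and statuses", {
  # max 3x + 2y st x + y <= 4, x <= 2
  r <- lp_solve(c(3, 2), rbind(c(1, 1)), "<=", 4, c(0, 0), c(2, Inf), "max")
  expect_equal(r$status, "optimal")
  expect_equal(r$objective, 10)
  expect_equal(r$x, c(2, 2))
  # infeasible
  expect_equal(lp_solve(1, rbind(1), ">=", 5, 0, 2, "max")$status, "infeasible")
  # unbounded
  expect_equal(lp_solve(1, rbind(1), ">=", 0, 0, Inf, "max")$status, "unbounded")
  # free variable through an equality
  r <- lp_solve(c(1, 0), rbind(c(1, -1)), "=", 1, c(0, -Inf), c(Inf, Inf), "min")
  expect_equal(r$objective, 0)
  expect_equal(r$x[1] - r$x[2], 1)
  # fixed variables are substituted out
  r <- lp_solve(c(1, 1), rbind(c(1, 1)), "<=", 10, c(3, 0), c(3, 2), "max")
  expect_equal(r$x, c(3, 2))
})

# Branched network: supply -> A, A -> B, A -> C, B ->, C ->, finite caps so
# every vertex is enumerable.
branched_model <- function() {
  m <- gem("branched")
  for (met in c("A", "B", "C")) m <- add_metabolite(m, met, compartment = "c")
  m <- add_reaction(m, "supply", c(A = 1), lb = 0, ub = 1)
  m <- add_reaction(m, "toB", c(A = -1, B = 1), lb = 0, ub = 10)
  m <- add_reaction(m, "toC", c(A = -1, C = 1), lb = 0, ub = 10)
  m <- add_reaction(m, "useB", c(B = -1), lb = 0, ub = 10)
  m <- add_reaction(m, "useC", c(C = -1), lb = 0, ub = 10)
  m
}

# Enumerate vertices of {S v = 0, lb <= v <= ub}: fix (n - rank) coordinates
# at bounds, solve the square system for the rest, keep feasible solutions.
enumerate_vertices <- function(model) {
  S <- as.matrix(stoich_matrix(model))
  lb <- model$rxns$lb; ub <- model$rxns$ub
  n <- ncol(S); r <- qr(S)$rank; d <- n - r
  verts <- list()
  for (fixed in asplit(combn(n, d), 2)) {
    free <- setdiff(seq_len(n), fixed)
    grid <- expand.grid(rep(list(c("lb", "ub")), d), stringsAsFactors = FALSE)
    for (g in asplit(as.matrix(grid), 1)) {
      vf <- ifelse(g == "lb", lb[fixed], ub[fixed])
      if (any(!is.finite(vf))) next
      Sf <- S[, free, drop = FALSE]
      if (qr(Sf)$rank < length(free)) next
      vr <- tryCatch(qr.solve(Sf, -S[, fixed, drop = FALSE] %*% vf),
                     error = function(e) NULL)
      if (is.null(vr)) next
      v <- numeric(n); v[fixed] <- vf; v[free] <- vr
      if (max(abs(S %*% v)) < 1e-9 &&
          all(v >= lb - 1e-9) && all(v <= ub + 1e-9)) {
        verts[[length(verts) + 1L]] <- v
      }
    }
  }
  do.call(rbind, verts)
}

test_that("fba matches brute-force vertex enumeration on a small network", {
  m <- branched_model()
  verts <- enumerate_vertices(m)
  expect_gt(nrow(verts), 0)
  for (obj in list(c(useB = 2, useC = 1), c(useB = 1), c(toC = 3, useB = 1))) {
    m2 <- set_objective(m, obj)
    w <- setNames(numeric(5), m$rxns$id)
    w[names(obj)] <- obj
    oracle_max <- max(verts %*% w)
    oracle_min <- min(verts %*% w)
    expect_equal(fba(m2, "max")$objective_value, oracle_max, tolerance = 1e-9)
    expect_equal(fba(m2, "min")$objective_value, oracle_min, tolerance = 1e-9)
  }
})

test_that("lp_solve agrees with boot::simplex on random dense LPs", {
  set.seed(7)
  for (case in 1:10) {
    n <- sample(3:6, 1); mrows <- sample(2:5, 1)
    A <- matrix(round(runif(mrows * n, 0.2, 3), 2), mrows, n) # bounded by design
    b <- round(runif(mrows, 1, 6), 2)
    obj <- round(runif(n, 0.1, 2), 2)
    ref <- boot::simplex(a = obj, A1 = A, b1 = b, maxi = TRUE)
    r <- lp_solve(obj, A, rep("<=", mrows), b, rep(0, n), rep(Inf, n), "max")
    if (ref$solved == 1) {
      expect_equal(r$status, "optimal")
      expect_equal(r$objective, unname(ref$value), tolerance = 1e-7)
    }
  }
})
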