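# Flux balance analysis and friends. All solves share one entry point that
# assembles the steady-state system S v = 0 plus optional extra linear rows
# (used to pin an objective at its optimum).

.model_lp <- function(model, obj, sense, extra_A = NULL, extra_dir = NULL,
                      extra_rhs = NULL) {
  S <- as.matrix(stoich_matrix(model))
  A <- S
  dir <- rep("=", nrow(S))
  rhs <- rep(0, nrow(S))
  if (!is.null(extra_A)) {
    A <- rbind(A, extra_A)
    dir <- c(dir, extra_dir)
    rhs <- c(rhs, extra_rhs)
  }
  lp_solve(obj, A, dir, rhs, model$rxns$lb, model$rxns$ub, sense)
}

.objective_vector <- function(model, objective = model$objective) {
  obj <- numeric(nrow(model$rxns))
  names(obj) <- model$rxns$id
  obj[names(objective)] <- objective
  unname(obj)
}

.flux_solution <- function(model, res) {
  if (res$status != "optimal") {
    return(structure(list(fluxes = NULL, objective_value = NA_real_,
                          status = res$status), class = "flux_solution"))
  }
  structure(list(fluxes = stats::setNames(res$x, model$rxns$id),
                 objective_value = res$objective, status = "optimal"),
            class = "flux_solution")
}

#' @export
print.flux_solution <- function(x, ...) {
  cat(sprintf("<flux solution: status %s, objective %s>\n", x$status,
              if (is.na(x$objective_value)) "NA"
              else format(x$objective_value, digits = 8)))
  invisible(x)
}

#' Flux balance analysis
#'
#' Solves the LP `opt c'v` subject to `S v = 0`, `LB <= v <= UB` with the
#' model's current objective vector `c`.
#'
#' @param model A `gem` with a non-empty objective.
#' @param sense `"max"` (default) or `"min"`.
#' @return A `flux_solution`: named flux vector \[mmol/gDW/h\],
#'   `objective_value`, and `status` in optimal/infeasible/unbounded.
#' @export
fba <- function(model, sense = c("max", "min")) {
  sense <- match.arg(sense)
  stopifnot(inherits(model, "gem"))
  if (length(model$objective) == 0L) {
    stop("fba(): the model has an empty objective; use set_objective()")
  }
  .flux_solution(model, .model_lp(model, .objective_vector(model), sense))
}

#' Parsimonious FBA
#'
#' Two-stage LP: stage 1 optimizes the model objective; stage 2 pins the
#' objective to its optimum (to relative tolerance `opt_tol`, which avoids
#' numerically empty feasible sets) and minimizes the total absolute flux
#' `sum(|v|)`. The 1-norm is expressed exactly: irreversible fluxes enter the
#' stage-2 objective directly, reversible ones through an auxiliary magnitude
#' variable `t >= |v|`.
#'
#' @param model A `gem` with a non-empty objective.
#' @param sense Stage-1 direction, `"max"` (default) or `"min"`.
#' @param opt_tol Relative slack used when pinning the stage-1 optimum.
#' @return A `flux_solution`; `objective_value` is the stage-1 optimum
#'   attained by the returned (stage-2 minimal) flux vector.
#' @export
pfba <- function(model, sense = c("max", "min"), opt_tol = 1e-9) {
  sense <- match.arg(sense)
  stopifnot(inherits(model, "gem"))
  stage1 <- fba(model, sense)
  if (stage1$status != "optimal") return(stage1)
  opt <- stage1$objective_value

  n <- nrow(model$rxns)
  obj <- .objective_vector(model)
  rev_idx <- which(model$rxns$lb < 0)
  nt <- length(rev_idx)

  S <- as.matrix(stoich_matrix(model))
  m <- nrow(S)
  A <- cbind(S, matrix(0, m, nt))
  dir <- rep("=", m)
  rhs <- rep(0, m)

  # Pin stage-1 objective.
  slack <- opt_tol * max(1, abs(opt))
  A <- rbind(A, c(obj, numeric(nt)))
  if (sense == "max") {
    dir <- c(dir, ">="); rhs <- c(rhs, opt - slack)
  } else {
    dir <- c(dir, "<="); rhs <- c(rhs, opt + slack)
  }

  # t_r >= v_r and t_r >= -v_r for reversible reactions.
  if (nt > 0L) {
    for (k in seq_len(nt)) {
      row1 <- numeric(n + nt); row1[rev_idx[k]] <- 1; row1[n + k] <- -1
      row2 <- numeric(n + nt); row2[rev_idx[k]] <- -1; row2[n + k] <- -1
      A <- rbind(A, row1, row2)
      dir <- c(dir, "<=", "<=")
      rhs <- c(rhs, 0, 0)
    }
  }

  c2 <- numeric(n + nt)
  c2[setdiff(seq_len(n), rev_idx)] <- 1
  if (nt > 0L) c2[n + seq_len(nt)] <- 1
  lb <- c(model$rxns$lb, rep(0, nt))
  ub <- c(model$rxns$ub, rep(Inf, nt))

  res <- lp_solve(c2, A, dir, rhs, lb, ub, "min")
  if (res$status != "optimal") {
    stop(sprintf("pfba(): stage 2 unexpectedly %s after a successful stage 1",
                 res$status))
  }
  v <- res$x[seq_len(n)]
  structure(list(fluxes = stats::setNames(v, model$rxns$id),
                 objective_value = sum(obj * v), status = "optimal"),
            class = "flux_solution")
}

#' Total absolute flux of a solution
#' @param solution A `flux_solution`.
#' @return `sum(|v|)`.
#' @export
total_flux <- function(solution) {
  stopifnot(inherits(solution, "flux_solution"), solution$status == "optimal")
  sum(abs(solution$fluxes))
}

#' Flux variability of a linear flux combination
#'
#' Minimum and maximum of `sum(w_r v_r)` over the feasible region. With a
#' weight vector concentrated on one reaction this is classical FVA; with the
#' chain-mass coefficients of a lipid class it gives the grouped variability
#' used for lipid analysis.
#'
#' @param model A `gem`.
#' @param combination Named numeric vector, reaction id to weight. An empty
#'   combination returns `c(0, 0)`.
#' @return Named numeric `c(min =, max =)`.
#' @export
fva_linear <- function(model, combination) {
  stopifnot(inherits(model, "gem"))
  unknown <- setdiff(names(combination), model$rxns$id)
  if (length(unknown) > 0L) {
    stop(sprintf("fva_linear(): unknown reaction(s): %s",
                 paste(unknown, collapse = ", ")))
  }
  w <- .objective_vector(model, combination)
  lo <- .model_lp(model, w, "min")
  if (lo$status == "infeasible") {
    stop("fva_linear(): model is infeasible under its current bounds")
  }
  if (lo$status == "unbounded") {
    stop("fva_linear(): combination is unbounded below; cap open exchanges")
  }
  hi <- .model_lp(model, w, "max")
  if (hi$status == "unbounded") {
    stop("fva_linear(): combination is unbounded above; cap open exchanges")
  }
  c(min = lo$objective, max = hi$objective)
}

#' Per-reaction FVA ranges
#'
#' Convenience wrapper running [fva_linear()] for each listed reaction.
#'
#' @param model A `gem`.
#' @param ids Reaction ids (default all).
#' @return Data frame with columns `id`, `min`, `max`.
#' @export
fva_reactions <- function(model, ids = model$rxns$id) {
  out <- lapply(ids, function(r) {
    rng <- fva_linear(model, stats::setNames(1, r))
    data.frame(id = r, min = rng[["min"]], max = rng[["max"]],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Fix the model objective at (near) its optimum
#'
#' Returns a model in which the single-reaction objective flux has its lower
#' bound raised to `(1 - rel_tol)` of the optimum, the formulation used when
#' exploring variability or sampling "at equal energy expenditure".
#'
#' @param model A `gem` whose objective is a single reaction.
#' @param optimum The optimum to pin (default: recomputed by [fba()]).
#' @param rel_tol Relative slack.
#' @return The modified model.
#' @export
fix_objective <- function(model, optimum = NULL, rel_tol = 1e-6) {
  stopifnot(inherits(model, "gem"))
  if (length(model$objective) != 1L) {
    stop("fix_objective() expects a single-reaction objective")
  }
  if (is.null(optimum)) {
    sol <- fba(model, "max")
    if (sol$status != "optimal") {
      stop(sprintf("fix_objective(): model is %s", sol$status))
    }
    optimum <- sol$objective_value
  }
  rid <- names(model$objective)
  set_bounds(model, rid, lb = optimum - rel_tol * max(1, abs(optimum)))
}
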