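# Dense two-phase primal simplex. This is the numerical core behind FBA,
# pFBA and FVA: the LPs built by this package are small and dense enough
# (hundreds of rows/columns) that a careful tableau implementation with
# Dantzig pricing and a Bland anti-cycling fallback is fast, exact and fully
# deterministic. Statuses are reported faithfully: "optimal", "infeasible",
# "unbounded".

.LP_TOL <- 1e-9

#' Solve a linear program
#'
#' Optimizes `obj' x` subject to `A x (dir) rhs` and `lb <= x <= ub`.
#' Variables may be free (`-Inf` lower bound) or unbounded above; fixed
#' variables (`lb == ub`) are substituted out before the solve.
#'
#' @param obj Numeric objective vector (length n).
#' @param A Constraint matrix (m x n), dense or sparse.
#' @param dir Character vector of constraint directions: `"="`, `"<="`, `">="`.
#' @param rhs Right-hand sides (length m).
#' @param lb,ub Variable bounds (length n), may be infinite.
#' @param sense `"max"` or `"min"`.
#' @param tol Pivot/feasibility tolerance.
#' @return List with `status` (`"optimal"`, `"infeasible"`, `"unbounded"`),
#'   `x` (solution, or `NULL` unless optimal) and `objective`.
#' @export
lp_solve <- function(obj, A, dir, rhs, lb, ub, sense = c("max", "min"),
                     tol = .LP_TOL) {
  sense <- match.arg(sense)
  A <- as.matrix(A)
  m <- nrow(A); n <- ncol(A)
  stopifnot(length(obj) == n, length(dir) == m, length(rhs) == m,
            length(lb) == n, length(ub) == n, all(lb <= ub))
  cc <- if (sense == "max") -obj else obj

  # Substitute out fixed variables (lb == ub): common for pinned growth or
  # maintenance fluxes, and removing them avoids needless degeneracy.
  fixed <- is.finite(lb) & lb == ub
  x_full <- numeric(n)
  x_full[fixed] <- lb[fixed]
  obj_fix <- sum(cc[fixed] * lb[fixed])
  if (any(fixed)) {
    rhs <- rhs - as.vector(A[, fixed, drop = FALSE] %*% lb[fixed])
    A <- A[, !fixed, drop = FALSE]
    cc <- cc[!fixed]; lb2 <- lb[!fixed]; ub2 <- ub[!fixed]
  } else {
    lb2 <- lb; ub2 <- ub
  }
  nf <- ncol(A)
  if (nf == 0L) {
    feas <- all(abs(rhs[dir == "="]) <= 1e-7) &&
      all(rhs[dir == "<="] >= -1e-7) && all(rhs[dir == ">="] <= 1e-7)
    if (!feas) return(list(status = "infeasible", x = NULL, objective = NA_real_))
    val <- obj_fix
    return(list(status = "optimal", x = x_full,
                objective = if (sense == "max") -val else val))
  }

  # Shift/mirror/split to non-negative variables.
  #   shift:  x = lb + y            (finite lb)
  #   mirror: x = ub - y            (lb = -Inf, finite ub)
  #   split:  x = y+ - y-           (both infinite)
  kind <- ifelse(is.finite(lb2), "shift",
                 ifelse(is.finite(ub2), "mirror", "split"))
  cols <- list(); ccols <- list(); yub <- list()
  shift_const <- 0
  for (j in seq_len(nf)) {
    aj <- A[, j]
    if (kind[j] == "shift") {
      cols[[length(cols) + 1L]] <- aj
      ccols[[length(ccols) + 1L]] <- cc[j]
      yub[[length(yub) + 1L]] <- ub2[j] - lb2[j]
      rhs <- rhs - aj * lb2[j]
      shift_const <- shift_const + cc[j] * lb2[j]
    } else if (kind[j] == "mirror") {
      cols[[length(cols) + 1L]] <- -aj
      ccols[[length(ccols) + 1L]] <- -cc[j]
      yub[[length(yub) + 1L]] <- Inf
      rhs <- rhs - aj * ub2[j]
      shift_const <- shift_const + cc[j] * ub2[j]
    } else {
      cols[[length(cols) + 1L]] <- aj
      ccols[[length(ccols) + 1L]] <- cc[j]
      yub[[length(yub) + 1L]] <- Inf
      cols[[length(cols) + 1L]] <- -aj
      ccols[[length(ccols) + 1L]] <- -cc[j]
      yub[[length(yub) + 1L]] <- Inf
    }
  }
  B <- do.call(cbind, cols)
  cy <- unlist(ccols)
  yu <- unlist(yub)

  # Finite variable upper bounds become explicit rows.
  ub_rows <- which(is.finite(yu))
  if (length(ub_rows) > 0L) {
    extra <- matrix(0, length(ub_rows), ncol(B))
    extra[cbind(seq_along(ub_rows), ub_rows)] <- 1
    B <- rbind(B, extra)
    rhs <- c(rhs, yu[ub_rows])
    dir <- c(dir, rep("<=", length(ub_rows)))
  }

  # Normalize to non-negative rhs.
  neg <- rhs < 0
  if (any(neg)) {
    B[neg, ] <- -B[neg, , drop = FALSE]
    rhs[neg] <- -rhs[neg]
    dir[neg] <- c("=" = "=", "<=" = ">=", ">=" = "<=")[dir[neg]]
  }

  res <- .simplex_two_phase(B, dir, rhs, cy, tol)
  if (res$status != "optimal") {
    return(list(status = res$status, x = NULL, objective = NA_real_))
  }

  # Map back to original variables.
  y <- res$y
  xi <- numeric(nf)
  p <- 1L
  for (j in seq_len(nf)) {
    if (kind[j] == "shift") {
      xi[j] <- lb2[j] + y[p]; p <- p + 1L
    } else if (kind[j] == "mirror") {
      xi[j] <- ub2[j] - y[p]; p <- p + 1L
    } else {
      xi[j] <- y[p] - y[p + 1L]; p <- p + 2L
    }
  }
  x_full[!fixed] <- xi
  val <- res$objective + shift_const + obj_fix
  list(status = "optimal", x = x_full,
       objective = if (sense == "max") -val else val)
}

# Two-phase tableau simplex minimizing cy' y over B y (dir) rhs, y >= 0,
# rhs >= 0. Returns y and the minimal objective.
.simplex_two_phase <- function(B, dir, rhs, cy, tol) {
  m <- nrow(B); nv <- ncol(B)
  n_le <- sum(dir == "<="); n_ge <- sum(dir == ">=")
  n_art <- sum(dir != "<=")
  ncols <- nv + n_le + n_ge + n_art

  Tab <- matrix(0, m, ncols + 1L)
  Tab[, seq_len(nv)] <- B
  Tab[, ncols + 1L] <- rhs
  basis <- integer(m)
  slack_j <- nv; surp_j <- nv + n_le; art_j <- nv + n_le + n_ge
  art_cols <- integer(0)
  for (i in seq_len(m)) {
    if (dir[i] == "<=") {
      slack_j <- slack_j + 1L
      Tab[i, slack_j] <- 1
      basis[i] <- slack_j
    } else {
      if (dir[i] == ">=") {
        surp_j <- surp_j + 1L
        Tab[i, surp_j] <- -1
      }
      art_j <- art_j + 1L
      Tab[i, art_j] <- 1
      basis[i] <- art_j
      art_cols <- c(art_cols, art_j)
    }
  }
  allowed <- rep(TRUE, ncols)
  max_iter <- 20000L + 60L * (m + ncols)

  if (length(art_cols) > 0L) {
    cost1 <- numeric(ncols)
    cost1[art_cols] <- 1
    r1 <- .simplex_iterate(Tab, basis, cost1, allowed, tol, max_iter)
    if (r1$status == "maxiter") {
      stop("simplex: phase 1 iteration limit reached")
    }
    Tab <- r1$Tab; basis <- r1$basis
    phase1_val <- sum(cost1[basis] * Tab[, ncols + 1L])
    if (phase1_val > 1e-7) {
      return(list(status = "infeasible"))
    }
    # Drive leftover artificials out of the basis (degenerate rows).
    for (i in which(basis %in% art_cols)) {
      piv_cols <- which(allowed & !(seq_len(ncols) %in% art_cols) &
                          abs(Tab[i, seq_len(ncols)]) > tol)
      if (length(piv_cols) > 0L) {
        j <- piv_cols[1]
        Tab <- .pivot(Tab, i, j)
        basis[i] <- j
      }
    }
    allowed[art_cols] <- FALSE
  }

  cost2 <- numeric(ncols)
  cost2[seq_len(nv)] <- cy
  r2 <- .simplex_iterate(Tab, basis, cost2, allowed, tol, max_iter)
  if (r2$status == "maxiter") stop("simplex: phase 2 iteration limit reached")
  if (r2$status == "unbounded") return(list(status = "unbounded"))
  Tab <- r2$Tab; basis <- r2$basis
  y <- numeric(nv)
  in_struct <- basis <= nv
  y[basis[in_struct]] <- Tab[in_struct, ncols + 1L]
  list(status = "optimal", y = y,
       objective = sum(cost2[basis] * Tab[, ncols + 1L]))
}

.pivot <- function(Tab, i, j) {
  Tab[i, ] <- Tab[i, ] / Tab[i, j]
  other <- Tab[, j]
  other[i] <- 0
  Tab <- Tab - outer(other, Tab[i, ])
  Tab
}

.simplex_iterate <- function(Tab, basis, cost, allowed, tol, max_iter) {
  m <- nrow(Tab); ncols <- ncol(Tab) - 1L
  cols <- seq_len(ncols)
  last_obj <- Inf; stall <- 0L; bland <- FALSE
  for (it in seq_len(max_iter)) {
    cB <- cost[basis]
    red <- cost[cols] - as.vector(crossprod(cB, Tab[, cols, drop = FALSE]))
    red[!allowed] <- 0
    red[basis] <- 0
    cand <- which(red < -tol)
    if (length(cand) == 0L) {
      return(list(Tab = Tab, basis = basis, status = "optimal"))
    }
    j <- if (bland) cand[1L] else cand[which.min(red[cand])]
    col <- Tab[, j]
    pos <- which(col > tol)
    if (length(pos) == 0L) {
      return(list(Tab = Tab, basis = basis, status = "unbounded"))
    }
    ratios <- Tab[pos, ncols + 1L] / col[pos]
    rmin <- min(ratios)
    ties <- pos[ratios <= rmin + tol]
    i <- ties[which.min(basis[ties])]
    Tab <- .pivot(Tab, i, j)
    basis[i] <- j
    obj <- sum(cost[basis] * Tab[, ncols + 1L])
    if (obj < last_obj - tol) {
      last_obj <- obj; stall <- 0L; bland <- FALSE
    } else {
      stall <- stall + 1L
      if (stall > 2L * (m + 10L)) bland <- TRUE
    }
  }
  list(Tab = Tab, basis = basis, status = "maxiter")
}
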