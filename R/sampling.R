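# Hit-and-run sampling of the steady-state flux polytope, artificial
# centering flavor: chord directions are drawn from warm-up points (the FVA
# extreme solutions) relative to a running center, which adapts the step
# distribution to the polytope's shape. Fully deterministic under a seed.

#' Sample flux vectors from the feasible polytope
#'
#' Artificial-centering hit-and-run over `{v : S v = 0, LB <= v <= UB}`.
#' Warm-up points are the per-reaction FVA optima; every `thin` chord steps
#' one sample is emitted. The chain is periodically re-projected onto the
#' steady-state subspace to keep `max |S v|` at solver tolerance.
#'
#' @param model A `gem`. The polytope must be bounded: any open exchange
#'   must be capped first (an unbounded FVA range raises an error saying so).
#' @param n_samples Number of samples.
#' @param seed Integer seed; identical seeds give identical output.
#' @param thin Chord steps between emitted samples (default 100).
#' @return Numeric matrix `n_samples x n_reactions` with reaction ids as
#'   column names.
#' @export
sample_fluxes <- function(model, n_samples, seed, thin = 100L) {
  stopifnot(inherits(model, "gem"), n_samples >= 1L)
  n <- nrow(model$rxns)
  lb <- model$rxns$lb
  ub <- model$rxns$ub

  # Warm-up: min and max LP solutions per reaction; doubles as the
  # boundedness check the sampler requires.
  pts <- matrix(NA_real_, n, 0L)
  for (j in seq_len(n)) {
    w <- numeric(n); w[j] <- 1
    for (sense in c("min", "max")) {
      res <- .model_lp(model, w, sense)
      if (res$status == "unbounded") {
        stop(sprintf(paste0("sample_fluxes(): flux '%s' is unbounded; cap the",
                            " open exchange bounds before sampling"),
                     model$rxns$id[j]))
      }
      if (res$status == "infeasible") {
        stop("sample_fluxes(): model is infeasible under its current bounds")
      }
      pts <- cbind(pts, res$x)
    }
  }

  # Null space of the steady-state system, with numerically fixed fluxes
  # pinned so chord directions never move them.
  S <- as.matrix(stoich_matrix(model))
  fixed <- (ub - lb) < 1e-12
  Aeq <- S
  if (any(fixed)) {
    pin <- matrix(0, sum(fixed), n)
    pin[cbind(seq_len(sum(fixed)), which(fixed))] <- 1
    Aeq <- rbind(S, pin)
  }
  sv <- svd(Aeq, nu = 0, nv = n)
  rank_tol <- max(dim(Aeq)) * max(sv$d, 0) * .Machine$double.eps * 100
  d_full <- c(sv$d, rep(0, n - length(sv$d)))
  null_cols <- which(d_full <= rank_tol)
  xref <- pts[, 1L]
  samples <- matrix(NA_real_, n_samples, n,
                    dimnames = list(NULL, model$rxns$id))
  if (length(null_cols) == 0L) {
    # Degenerate polytope: a single point.
    for (i in seq_len(n_samples)) samples[i, ] <- xref
    return(samples)
  }
  Nb <- sv$v[, null_cols, drop = FALSE]
  Proj <- Nb %*% t(Nb)

  withr::with_seed(seed, {
    K <- ncol(pts)
    center <- rowMeans(pts)
    x <- xref
    visited <- 1
    emitted <- 0L
    step <- 0L
    while (emitted < n_samples) {
      step <- step + 1L
      d <- pts[, sample.int(K, 1L)] - center
      nd <- sqrt(sum(d * d))
      if (nd < 1e-12) next
      d <- d / nd
      act <- which(abs(d) > 1e-11)
      hi_cap <- (ub[act] - x[act]) / d[act]
      lo_cap <- (lb[act] - x[act]) / d[act]
      tmax <- min(pmax(hi_cap, lo_cap))
      tmin <- max(pmin(hi_cap, lo_cap))
      if (!is.finite(tmax) || !is.finite(tmin)) {
        stop("sample_fluxes(): unbounded chord; cap open exchanges")
      }
      if (tmin > tmax) { tmin <- 0; tmax <- 0 }
      t_step <- stats::runif(1L, tmin, tmax)
      x <- x + t_step * d
      visited <- visited + 1
      center <- center + (x - center) / visited
      if (step %% 200L == 0L) {
        x <- xref + as.vector(Proj %*% (x - xref))
        x <- pmin(pmax(x, lb), ub)
      }
      if (step %% thin == 0L) {
        emitted <- emitted + 1L
        xs <- xref + as.vector(Proj %*% (x - xref))
        samples[emitted, ] <- pmin(pmax(xs, lb), ub)
      }
    }
  })
  samples
}
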