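#' Particle swarm optimizer settings
#'
#' Constriction-style defaults (inertia 0.729, cognitive and social factors
#' 1.49) with a global-best topology. `max_iter` counts objective-evaluation
#' sweeps, including the initial one, so the total evaluation budget is
#' `swarm_size * max_iter`.
#'
#' @param swarm_size particles (>= 2 for a meaningful swarm; 1 is allowed and
#'   degenerates to evaluating points on a single trajectory).
#' @param max_iter evaluation sweeps (>= 1).
#' @param inertia,c1,c2 velocity-update coefficients.
#' @return A `pso_control` list.
#' @export
pso_control <- function(swarm_size = 20L, max_iter = 10L,
                        inertia = 0.729, c1 = 1.49, c2 = 1.49) {
  stopifnot(swarm_size >= 1L, max_iter >= 1L)
  structure(list(swarm_size = as.integer(swarm_size),
                 max_iter = as.integer(max_iter),
                 inertia = inertia, c1 = c1, c2 = c2),
            class = "pso_control")
}

#' Bounded, seeded particle swarm maximization
#'
#' Maximizes `objective` over the box `[lower, upper]`. Positions are
#' initialized uniformly in the box; initial velocities follow the standard
#' half-difference rule `(U(lower, upper) - x0) / 2`. Each iteration applies
#' the inertia/cognitive/social velocity update toward the particle's own best
#' and the swarm's global best, clamps positions to the bounds (zeroing the
#' velocity of a clamped dimension), and re-evaluates. A non-finite objective
#' value is treated as `-Inf` and the run continues.
#'
#' @param objective `function(x) -> numeric(1)` on the box.
#' @param lower,upper numeric bound vectors (recycled against each other),
#'   `lower < upper` per dimension.
#' @param control a [pso_control()].
#' @param seed integer seed; identical seed, control and objective give an
#'   identical trajectory.
#' @return List: `par` (best position found), `value`, `history`
#'   (best-ever value after each evaluation sweep; non-decreasing).
#' @export
pso_maximize <- function(objective, lower, upper, control = pso_control(),
                         seed = NULL) {
  d <- max(length(lower), length(upper))
  lower <- rep_len(as.numeric(lower), d)
  upper <- rep_len(as.numeric(upper), d)
  if (any(lower >= upper)) stop("lower bound must be strictly below upper bound")
  S <- control$swarm_size

  eval1 <- function(x) {
    v <- tryCatch(objective(x), error = function(e) -Inf)
    if (!is.finite(v)) -Inf else v
  }

  with_seed(seed, {
    X <- matrix(stats::runif(S * d, lower, upper), nrow = S, byrow = TRUE)
    V <- (matrix(stats::runif(S * d, lower, upper), nrow = S, byrow = TRUE) - X) / 2
    val <- apply(X, 1L, eval1)
    Pb <- X; pval <- val
    g <- which.max(pval)
    gbest <- X[g, ]; gval <- pval[g]
    history <- gval

    if (control$max_iter > 1L) {
      for (t in 2:control$max_iter) {
        r1 <- matrix(stats::runif(S * d), S, d)
        r2 <- matrix(stats::runif(S * d), S, d)
        V <- control$inertia * V +
          control$c1 * r1 * (Pb - X) +
          control$c2 * r2 * (matrix(gbest, S, d, byrow = TRUE) - X)
        X <- X + V
        for (j in seq_len(d)) {
          lo <- X[, j] < lower[j]; hi <- X[, j] > upper[j]
          X[lo, j] <- lower[j]; X[hi, j] <- upper[j]
          V[lo | hi, j] <- 0
        }
        val <- apply(X, 1L, eval1)
        better <- val > pval
        Pb[better, ] <- X[better, , drop = FALSE]
        pval[better] <- val[better]
        g <- which.max(pval)
        if (pval[g] > gval) { gbest <- Pb[g, ]; gval <- pval[g] }
        history <- c(history, gval)
      }
    }
    list(par = gbest, value = gval, history = history)
  })
}
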