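# Local geometry relaxation: quasi-Newton (BFGS) descent with a trust-style
# step cap and backtracking, honouring frozen atoms and an optional
# all-substrate constraint.

#' Relax a structure on a calculator
#'
#' Quasi-Newton descent (BFGS inverse-Hessian update, line-search-free with
#' a per-atom step cap and energy backtracking) until the largest force
#' component on any free atom drops below `fmax` or the step budget is
#' exhausted.  Frozen atoms never move; `fix_substrate` additionally
#' freezes every substrate-tagged atom (the rigid-surface approximation).
#' The energy is non-increasing over accepted steps.  The returned step
#' count is the number of force evaluations after the first.
#'
#' @param s starting structure.
#' @param calc a `surfbo_calculator` providing forces.
#' @param fmax force-component threshold (eV/Angstrom), default 0.01.
#' @param max_steps evaluation budget.
#' @param fix_substrate freeze all substrate atoms regardless of mask.
#' @param max_step largest allowed per-atom displacement per step
#'   (Angstrom).
#' @return list with `structure` (relaxed, energy attached), `energy` (eV),
#'   `n_steps`, `converged`, and `fmax_final`.
#' @export
relax <- function(s, calc, fmax = 0.01, max_steps = 300,
                  fix_substrate = FALSE, max_step = 0.2) {
  free <- !s$frozen
  if (fix_substrate) free <- free & s$tags != "substrate"
  idx <- which(free)
  if (!length(idx)) stop("no free atoms to relax")
  cur <- s
  ev <- calc$evaluate(cur)
  n_eval <- 1L
  E <- ev$energy
  g <- -as.numeric(t(ev$forces[idx, , drop = FALSE]))
  m <- length(g)
  h0 <- 1 / 70                 # initial inverse stiffness ((eV/A^2)^-1)
  H <- diag(m) * h0
  have_curv <- FALSE
  maxf <- max(abs(ev$forces[idx, ]))
  converged <- maxf < fmax
  while (!converged && n_eval <= max_steps) {
    p <- -as.numeric(H %*% g)
    # cap the largest per-atom displacement
    steps <- sqrt(rowSums(matrix(p, ncol = 3, byrow = TRUE)^2))
    if (max(steps) > max_step) p <- p * (max_step / max(steps))
    accepted <- FALSE
    lam <- 1
    for (bt in 1:8) {
      trial <- cur
      trial$positions[idx, ] <- cur$positions[idx, ] +
        matrix(lam * p, ncol = 3, byrow = TRUE)
      ev1 <- calc$evaluate(trial)
      n_eval <- n_eval + 1L
      if (ev1$energy <= E + 1e-12) { accepted <- TRUE; break }
      lam <- lam / 2
      if (n_eval > max_steps) break
    }
    if (!accepted) {
      # descent failed along the quasi-Newton direction: reset curvature
      h0 <- h0 / 4
      H <- diag(m) * h0
      have_curv <- FALSE
      if (ev1$energy > E + 1e-12) break
    }
    s_vec <- lam * p
    g1 <- -as.numeric(t(ev1$forces[idx, , drop = FALSE]))
    y_vec <- g1 - g
    sy <- sum(s_vec * y_vec)
    if (sy > 1e-8 * sqrt(sum(s_vec^2)) * sqrt(sum(y_vec^2))) {
      rho <- 1 / sy
      I <- diag(m)
      V <- I - rho * (s_vec %o% y_vec)
      H <- V %*% H %*% t(V) + rho * (s_vec %o% s_vec)
      have_curv <- TRUE
    } else if (!have_curv && accepted && lam == 1) {
      # flat or concave region with no usable curvature: accelerate the
      # steepest-descent scale (the per-atom step cap still bounds moves)
      h0 <- h0 * 2
      H <- diag(m) * h0
    }
    cur <- trial
    E <- ev1$energy
    g <- g1
    maxf <- max(abs(ev1$forces[idx, ]))
    converged <- maxf < fmax
  }
  cur$energy <- E
  list(structure = cur, energy = E, n_steps = n_eval - 1L,
       converged = converged, fmax_final = maxf)
}
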