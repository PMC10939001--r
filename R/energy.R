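# Calculator contract, the contact-capped logarithmic energy transformation,
# and the packaged empirical toy backends that stand in for an electronic-
# structure engine.  Any external calculator (DFT, MLIP) can be plugged in by
# wrapping it in `calculator_new()`.

#' Create a calculator
#'
#' The calculator contract used everywhere in the package: a function mapping
#' a structure to a total energy (eV) and per-atom forces (eV/Angstrom), plus
#' a reference energy (the energy of the relaxed isolated building blocks at
#' infinite separation) defining the zero of relative energies.
#'
#' @param evaluate `function(structure) -> list(energy =, forces =)`.
#' @param reference_energy reference zero in eV.
#' @param label short descriptive name.
#' @return object of class `surfbo_calculator`.
#' @export
calculator_new <- function(evaluate, reference_energy = 0,
                           label = "calculator") {
  obj <- list(evaluate = evaluate, reference_energy = reference_energy,
              label = label)
  class(obj) <- "surfbo_calculator"
  obj
}

#' @export
print.surfbo_calculator <- function(x, ...) {
  cat(sprintf("<surfbo_calculator: %s (reference %.6f eV)>\n",
              x$label, x$reference_energy))
  invisible(x)
}

#' Energy-transformation settings
#'
#' @param contact_cutoff hard-contact distance (Angstrom); below it the
#'   backend evaluation is skipped and the cap energy assigned.
#' @param cap_energy placeholder energy (eV) for contact configurations,
#'   representing the Pauli-repulsive wall.
#' @param tail_threshold energy (eV) above which the logarithmic compression
#'   `1 + log(E)` is applied.
#' @return object of class `surfbo_transform`.
#' @export
transform_settings <- function(contact_cutoff = 0.5, cap_energy = 5.0,
                               tail_threshold = 1.0) {
  stopifnot(contact_cutoff > 0, cap_energy > 0, tail_threshold > 0,
            cap_energy > tail_threshold)
  obj <- list(contact_cutoff = contact_cutoff, cap_energy = cap_energy,
              tail_threshold = tail_threshold)
  class(obj) <- "surfbo_transform"
  obj
}

#' Transform a relative energy for surrogate fitting
#'
#' Compresses the high-energy tail of the landscape so the Gaussian process
#' concentrates its capacity on the low-energy region: configurations with
#' any interatomic distance below the contact cutoff get the fixed cap
#' energy; energies above the tail threshold are replaced by
#' `1 + log(E)` (natural logarithm, continuous at the 1 eV threshold);
#' energies at or below the threshold pass through unchanged.
#'
#' @param E_rel energy relative to the calculator reference (eV).
#' @param min_dist minimum interatomic distance of the configuration
#'   (Angstrom).
#' @param settings a [transform_settings()].
#' @return transformed energy (eV).
#' @export
transform_energy <- function(E_rel, min_dist,
                             settings = transform_settings()) {
  if (min_dist < settings$contact_cutoff) return(settings$cap_energy)
  if (!is.finite(E_rel)) return(settings$cap_energy)
  if (E_rel <= settings$tail_threshold) E_rel else 1 + log(E_rel)
}

# ---------------------------------------------------------------------------
# Toy intramolecular backend: Lennard-Jones non-bonded terms (pairs at least
# four bonds apart, Lorentz-Berthelot mixing) plus a directional
# donor-H...acceptor hydrogen-bond well between O-H...O triples.

#' Default toy backend parameters
#' @return named list of empirical parameters (eV, Angstrom).
#' @export
toy_params <- function() {
  list(
    lj_eps   = c(H = 0.0015, C = 0.0035, O = 0.0060, Cu = 0.0100),
    lj_sigma = c(H = 2.40,   C = 3.40,   O = 3.10,   Cu = 2.90),
    hb_eps = 0.20, hb_r0 = 1.90, hb_w = 0.30,
    morse_D  = c(H = 0.02, C = 0.06, O = 0.10, Cu = 0.05),
    morse_r0 = 2.35, morse_a = 1.40, surf_cutoff = 3.5
  )
}

# topology cache: LJ pair list (graph distance >= 4 bonds or disconnected)
# and O-H...O hydrogen-bond triples
intramolecular_topology <- function(s) {
  n <- n_atoms(s)
  bonds <- bond_list(s)
  adj <- adjacency(bonds, n)
  gd <- graph_distances(adj)
  pairs <- which(upper.tri(gd) & gd >= 4, arr.ind = TRUE)
  sym <- s$symbols
  hb <- matrix(0L, 0, 3)   # donor O, H, acceptor O
  for (k in seq_len(nrow(bonds))) {
    i <- bonds[k, 1]; j <- bonds[k, 2]
    if (sym[i] == "O" && sym[j] == "H") { dO <- i; dH <- j }
    else if (sym[j] == "O" && sym[i] == "H") { dO <- j; dH <- i }
    else next
    acc <- which(sym == "O" & gd[dH, ] >= 4)
    if (length(acc)) hb <- rbind(hb, cbind(dO, dH, acc))
  }
  list(pairs = pairs, hb = hb)
}

toy_intramolecular_eval <- function(pos, sym, topo, params) {
  n <- nrow(pos)
  grad <- matrix(0, n, 3)
  E <- 0
  if (nrow(topo$pairs)) {
    i <- topo$pairs[, 1]; j <- topo$pairs[, 2]
    D <- pos[i, , drop = FALSE] - pos[j, , drop = FALSE]
    r <- sqrt(rowSums(D * D))
    eps <- sqrt(params$lj_eps[sym[i]] * params$lj_eps[sym[j]])
    sig <- (params$lj_sigma[sym[i]] + params$lj_sigma[sym[j]]) / 2
    sr6 <- (sig / r)^6
    E <- E + sum(4 * eps * (sr6^2 - sr6))
    dEdr <- 4 * eps * (-12 * sr6^2 + 6 * sr6) / r
    G <- D * (dEdr / r)
    for (k in seq_along(i)) {
      grad[i[k], ] <- grad[i[k], ] + G[k, ]
      grad[j[k], ] <- grad[j[k], ] - G[k, ]
    }
  }
  if (nrow(topo$hb)) {
    for (k in seq_len(nrow(topo$hb))) {
      dO <- topo$hb[k, 1]; dH <- topo$hb[k, 2]; aO <- topo$hb[k, 3]
      a <- pos[dH, ] - pos[dO, ]       # donor O -> H
      b <- pos[aO, ] - pos[dH, ]       # H -> acceptor O
      na <- vnorm(a); nb <- vnorm(b)
      cth <- sum(a * b) / (na * nb)
      if (cth <= 0) next
      r <- nb
      phi <- exp(-(r - params$hb_r0)^2 / (2 * params$hb_w^2))
      g <- cth^4
      E <- E - params$hb_eps * g * phi
      dE_dc <- -params$hb_eps * 4 * cth^3 * phi
      dE_dr <- params$hb_eps * g * phi * (r - params$hb_r0) / params$hb_w^2
      dc_da <- b / (na * nb) - cth * a / na^2
      dc_db <- a / (na * nb) - cth * b / nb^2
      dr_db <- b / r
      grad[dO, ] <- grad[dO, ] - dE_dc * dc_da
      grad[dH, ] <- grad[dH, ] + dE_dc * (dc_da - dc_db) - dE_dr * dr_db
      grad[aO, ] <- grad[aO, ] + dE_dc * dc_db + dE_dr * dr_db
    }
  }
  list(energy = E, forces = -grad)
}

#' Toy intramolecular calculator
#'
#' An empirical desk-scale molecular energy: Lennard-Jones interactions
#' between atoms at least four bonds apart (Lorentz-Berthelot mixing) plus a
#' directional O-H...O hydrogen-bond well.  Forces are analytic; the energy
#' is exactly invariant under rigid motion.  Topology (bond graph, pair and
#' hydrogen-bond lists) is taken from `template` and reused for every
#' evaluation, which is what makes the backend consistent across realized
#' conformers of one molecule.
#'
#' @param template structure fixing the bond topology (defaults to the first
#'   structure evaluated).
#' @param params parameter list, see [toy_params()].
#' @param reference_energy reference zero (eV).
#' @return a `surfbo_calculator`.
#' @export
toy_intramolecular_calculator <- function(template = NULL,
                                          params = toy_params(),
                                          reference_energy = 0) {
  cache <- new.env(parent = emptyenv())
  if (!is.null(template)) {
    cache$topo <- intramolecular_topology(template)
    cache$n <- n_atoms(template)
  }
  evaluate <- function(s) {
    if (is.null(cache$topo) || n_atoms(s) != cache$n) {
      cache$topo <- intramolecular_topology(s)
      cache$n <- n_atoms(s)
    }
    toy_intramolecular_eval(s$positions, s$symbols, cache$topo, params)
  }
  calculator_new(evaluate, reference_energy, "toy-intramolecular")
}

# ---------------------------------------------------------------------------
# Toy adsorbate-surface backend: pairwise Morse attraction between adsorbate
# and substrate atoms, smoothly switched off at a finite interaction range,
# plus the intramolecular terms.  Because the substrate interaction is
# computed from the actual slab atom positions under minimum image, every
# symmetry of the periodic slab (surface-cell translations including the
# centring translation, 3-fold rotation about an atop axis) is an exact
# symmetry of the model.

# C1 polynomial switch: 1 at r = 0, 0 with zero slope at rc
switch_c1 <- function(r, rc) {
  u <- pmin(r / rc, 1)
  1 - 3 * u^2 + 2 * u^3
}
switch_c1_d <- function(r, rc) {
  u <- r / rc
  ifelse(u < 1, (-6 * u + 6 * u^2) / rc, 0)
}

#' Toy adsorbate-surface calculator
#'
#' Empirical stand-in for an electronic-structure engine for adsorption
#' searches.  Every adsorbate-substrate atom pair within the interaction
#' range contributes a Morse term (per-adsorbate-element depth), smoothly
#' switched off at the `surf_cutoff` range; minimum image is applied along
#' periodic directions.  Since the substrate field derives from the actual
#' slab geometry, the (111) surface symmetry operations used for data
#' augmentation (centring translation, 3-fold rotation about the atop axis
#' at the origin) leave the energy exactly invariant.  The short interaction
#' range matches the locality of the descriptor-regression surrogate
#' potential, so the surrogate can in principle represent this backend --
#' the property the workflow-closure check exercises.  Intramolecular terms
#' from [toy_intramolecular_calculator()] are added for multi-atom
#' adsorbates.
#'
#' @param slab the slab the adsorbate will be placed on.
#' @param template optional adsorbate template fixing the intramolecular
#'   topology.
#' @param params parameter list, see [toy_params()].
#' @param reference_energy reference zero (eV), typically the relaxed
#'   isolated-conformer energy (the clean slab contributes no
#'   adsorbate-substrate terms).
#' @return a `surfbo_calculator`.
#' @export
toy_surface_calculator <- function(slab, template = NULL,
                                   params = toy_params(),
                                   reference_energy = 0) {
  if (is.null(slab$info$surface_a))
    stop("slab must carry surface-cell info (build_slab)")
  cache <- new.env(parent = emptyenv())
  if (!is.null(template)) {
    cache$topo <- intramolecular_topology(template)
    cache$n <- n_atoms(template)
  }
  rc <- params$surf_cutoff
  evaluate <- function(s) {
    ads <- which(s$tags == "adsorbate")
    sub <- which(s$tags == "substrate")
    n <- n_atoms(s)
    grad <- matrix(0, n, 3)
    E <- 0
    L <- sqrt(rowSums(s$cell^2))
    for (i in ads) {
      el <- s$symbols[i]
      D <- params$morse_D[[el]]
      al <- params$morse_a; r0 <- params$morse_r0
      Dv <- sweep(s$positions[sub, , drop = FALSE], 2, s$positions[i, ])
      for (k in which(s$pbc)) Dv[, k] <- Dv[, k] - round(Dv[, k] / L[k]) * L[k]
      r <- sqrt(rowSums(Dv * Dv))
      sel <- which(r < rc)
      if (!length(sel)) next
      r_s <- r[sel]
      ex <- exp(-al * (r_s - r0))
      morse <- D * ((1 - ex)^2 - 1)
      sw <- switch_c1(r_s, rc)
      E <- E + sum(morse * sw)
      dmorse <- 2 * D * (1 - ex) * al * ex
      dEdr <- dmorse * sw + morse * switch_c1_d(r_s, rc)
      U <- Dv[sel, , drop = FALSE] / r_s     # unit vectors i -> j
      gi <- -colSums(U * dEdr)
      grad[i, ] <- grad[i, ] + gi
      grad[sub[sel], ] <- grad[sub[sel], , drop = FALSE] + U * dEdr
    }
    if (length(ads) >= 2) {
      subp <- s$positions[ads, , drop = FALSE]
      sym <- s$symbols[ads]
      if (is.null(cache$topo) || length(ads) != cache$n) {
        cache$topo <- intramolecular_topology(structure_new(sym, subp))
        cache$n <- length(ads)
      }
      intra <- toy_intramolecular_eval(subp, sym, cache$topo, params)
      E <- E + intra$energy
      grad[ads, ] <- grad[ads, ] - intra$forces
    }
    list(energy = E, forces = -grad)
  }
  calculator_new(evaluate, reference_energy, "toy-surface")
}

#' Central-difference forces
#'
#' Numerical check of a calculator's analytic forces.
#'
#' @param calc a calculator.
#' @param s a structure.
#' @param eps finite-difference step (Angstrom).
#' @param atoms subset of atoms to differentiate (default all).
#' @return N x 3 matrix of numerical forces (rows outside `atoms` are zero).
#' @export
numeric_forces <- function(calc, s, eps = 1e-5, atoms = NULL) {
  if (is.null(atoms)) atoms <- seq_len(n_atoms(s))
  Fn <- matrix(0, n_atoms(s), 3)
  for (i in atoms) for (k in 1:3) {
    sp <- s; sp$positions[i, k] <- sp$positions[i, k] + eps
    sm <- s; sm$positions[i, k] <- sm$positions[i, k] - eps
    Fn[i, k] <- -(calc$evaluate(sp)$energy - calc$evaluate(sm)$energy) /
      (2 * eps)
  }
  Fn
}
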