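# Reduced search spaces and their realizers: mapping a low-dimensional
# vector (torsions, ring-flip coordinates, rigid-body placement) to a full
# Cartesian structure.

#' Define a search space
#'
#' An ordered set of bounded, possibly periodic variables.  Each variable
#' carries a realizer tag describing how it acts on a structure:
#' `dihedral`, `ringflip_coord`, `translation_x/y/z`, or
#' `euler_alpha/beta/gamma`.
#'
#' @param labels character variable names.
#' @param lower,upper numeric bounds (degrees for angular variables,
#'   Angstrom for translations).
#' @param periodic logical; periodic variables must span exactly one period.
#' @param tags realizer tags (see above).
#' @param specs optional per-variable metadata (e.g. dihedral atom indices).
#' @param kind free-form space kind (`"conformer"`, `"adsorption"`, ...).
#' @return object of class `surfbo_space`.
#' @export
search_space_new <- function(labels, lower, upper, periodic, tags,
                             specs = NULL, kind = "custom") {
  stopifnot(length(labels) == length(lower),
            length(lower) == length(upper),
            length(upper) == length(periodic),
            length(periodic) == length(tags))
  if (any(lower >= upper)) stop("lower bounds must be below upper bounds")
  vars <- data.frame(label = labels, lower = lower, upper = upper,
                     periodic = periodic, tag = tags,
                     stringsAsFactors = FALSE)
  out <- list(vars = vars, specs = specs, kind = kind)
  class(out) <- "surfbo_space"
  out
}

#' @export
print.surfbo_space <- function(x, ...) {
  cat(sprintf("<surfbo_space (%s): %d dimensions>\n", x$kind, space_dim(x)))
  print(x$vars)
  invisible(x)
}

#' Dimensionality of a search space
#' @param space a `surfbo_space`.
#' @return integer.
#' @export
space_dim <- function(space) nrow(space$vars)

#' Wrap a vector into the bounds of a space
#'
#' Periodic variables are wrapped modulo their period; non-periodic ones are
#' clipped to the bounds.
#' @param space a `surfbo_space`.
#' @param x numeric vector of length `space_dim(space)`.
#' @return wrapped vector.
#' @export
space_wrap <- function(space, x) {
  v <- space$vars
  for (d in seq_len(nrow(v))) {
    if (v$periodic[d]) {
      x[d] <- wrap_period(x[d], v$lower[d], v$upper[d] - v$lower[d])
    } else {
      x[d] <- min(max(x[d], v$lower[d]), v$upper[d])
    }
  }
  x
}

# per-dimension displacement honouring periodicity
space_delta <- function(space, x, y) {
  v <- space$vars
  d <- x - y
  for (k in which(v$periodic)) {
    p <- v$upper[k] - v$lower[k]
    d[k] <- d[k] - round(d[k] / p) * p
  }
  d
}

#' Count search dimensions for an annotated molecule
#'
#' The dimensionality of a conformer search: one variable per hydroxyl
#' rotation, two per glycosidic linkage (phi and psi), and per ring either
#' two (the reduced ring-flip parametrization) or six (one coordinate per
#' ring atom, the full parametrization).
#'
#' @param sugar a list with `annotations` as returned by [make_sugar()], or
#'   the annotation list itself.
#' @param hydroxyls include hydroxyl rotations.
#' @param glycosidic include glycosidic phi/psi torsions.
#' @param ring_mode `"none"`, `"reduced"` (2 coordinates per ring) or
#'   `"full"` (6 per ring).
#' @return integer dimensionality.
#' @examples
#' count_dimensions(make_sugar("xylose_4C1"), hydroxyls = TRUE,
#'                  ring_mode = "reduced")   # 6
#' @export
count_dimensions <- function(sugar, hydroxyls = TRUE, glycosidic = FALSE,
                             ring_mode = c("none", "reduced", "full")) {
  ring_mode <- match.arg(ring_mode)
  ann <- if (!is.null(sugar$annotations)) sugar$annotations else sugar
  need <- c("hydroxyls", "ring_atoms", "glycosidic")
  if (!all(need %in% names(ann)))
    stop("molecule is missing coordinate annotations")
  d <- 0L
  if (hydroxyls) d <- d + length(ann$hydroxyls)
  if (glycosidic) d <- d + 2L * length(ann$glycosidic)
  n_rings <- length(ann$ring_atoms)
  if (ring_mode == "reduced") d <- d + 2L * n_rings
  if (ring_mode == "full") d <- d + 6L * n_rings
  as.integer(d)
}

# moving set of a rotation about bond j-k: atoms downstream of k
moving_set <- function(adj, j, k) {
  comp <- graph_component(adj, k, cut = list(c(j, k)))
  if (j %in% comp)
    stop("bond ", j, "-", k, " lies on a ring; cannot define a moving set")
  setdiff(comp, k)
}

#' Build a conformer search space for an annotated sugar
#'
#' Variables in order: glycosidic phi/psi pairs, hydroxyl torsions, then
#' ring-flip coordinate pairs.  Torsions are periodic on `[-180, 180)`
#' degrees; ring-flip coordinates (the two opposing ring torsions
#' O5-C1-C2-C3 and C3-C4-C5-O5) are bounded on `[-75, 75]` degrees, spanning
#' the two chairs.
#'
#' @param sugar list with `structure` and `annotations` ([make_sugar()]).
#' @param hydroxyls,glycosidic,ring_mode as in [count_dimensions()]
#'   (`ring_mode = "full"` is an accounting device and cannot be realized).
#' @return a `surfbo_space` with realizer metadata attached.
#' @export
conformer_space <- function(sugar, hydroxyls = TRUE, glycosidic = TRUE,
                            ring_mode = c("none", "reduced")) {
  ring_mode <- match.arg(ring_mode)
  ann <- sugar$annotations
  s <- sugar$structure
  adj <- adjacency(bond_list(s), n_atoms(s))
  labels <- character(0); lower <- numeric(0); upper <- numeric(0)
  periodic <- logical(0); tags <- character(0); specs <- list()
  add <- function(lab, lo, hi, per, tag, spec) {
    labels <<- c(labels, lab); lower <<- c(lower, lo); upper <<- c(upper, hi)
    periodic <<- c(periodic, per); tags <<- c(tags, tag)
    specs[[length(specs) + 1]] <<- spec
  }
  if (glycosidic) {
    for (i in seq_along(ann$glycosidic)) {
      g <- ann$glycosidic[[i]]
      for (nm in c("phi", "psi")) {
        q <- g[[nm]]
        add(sprintf("%s_%d", nm, i), -180, 180, TRUE, "dihedral",
            list(atoms = q, moving = moving_set(adj, q[2], q[3])))
      }
    }
  }
  if (hydroxyls) {
    for (i in seq_along(ann$hydroxyls)) {
      q <- ann$hydroxyls[[i]]
      add(sprintf("oh_%d", i), -180, 180, TRUE, "dihedral",
          list(atoms = q, moving = moving_set(adj, q[2], q[3])))
    }
  }
  if (ring_mode == "reduced") {
    for (i in seq_along(ann$ringflip)) {
      f <- ann$ringflip[[i]]
      ring <- ann$ring_atoms[[i]]
      for (nm in c("t1", "t2")) {
        add(sprintf("ring%d_%s", i, nm), -75, 75, FALSE, "ringflip_coord",
            list(atoms = f[[nm]], ring = ring, which = nm))
      }
    }
  }
  search_space_new(labels, lower, upper, periodic, tags, specs, "conformer")
}

#' Build a rigid-body adsorption search space
#'
#' Up to six variables: in-plane translations over one surface search cell
#' (periodic), height of the adsorbate geometric center above the top-layer
#' plane, and three Euler angles (z-y-z as in [euler_matrix()]; `gamma` is
#' the azimuthal angle about the surface normal).
#'
#' @param slab a slab from [build_slab()] (provides the search-cell
#'   dimensions), or a length-2 numeric `c(a, b)`.
#' @param vars subset of `c("tx","ty","tz","alpha","beta","gamma")`.
#' @param tz_bounds height bounds in Angstrom (default 3 to 12 above the
#'   surface).
#' @return a `surfbo_space`.
#' @export
adsorption_space <- function(slab,
                             vars = c("tx", "ty", "tz",
                                      "alpha", "beta", "gamma"),
                             tz_bounds = c(3, 12)) {
  if (inherits(slab, "surfbo_structure")) {
    a <- slab$info$surface_a; b <- slab$info$surface_b
  } else {
    a <- slab[1]; b <- slab[2]
  }
  defs <- list(
    tx    = list(0, a, TRUE,  "translation_x"),
    ty    = list(0, b, TRUE,  "translation_y"),
    tz    = list(tz_bounds[1], tz_bounds[2], FALSE, "translation_z"),
    alpha = list(0, 360, TRUE, "euler_alpha"),
    beta  = list(0, 180, FALSE, "euler_beta"),
    gamma = list(0, 360, TRUE, "euler_gamma"))
  vars <- match.arg(vars, names(defs), several.ok = TRUE)
  pick <- defs[vars]
  sp <- search_space_new(vars,
                         vapply(pick, `[[`, 0, 1),
                         vapply(pick, `[[`, 0, 2),
                         vapply(pick, `[[`, TRUE, 3),
                         vapply(pick, `[[`, "", 4),
                         kind = "adsorption")
  sp$cell_ab <- c(a, b)
  sp
}

# ---------------------------------------------------------------------------
# Dihedral realization

#' Measure a dihedral in a structure
#' @param s a structure.
#' @param atoms length-4 atom indices (i, j, k, l).
#' @return signed dihedral in degrees.
#' @export
structure_dihedral <- function(s, atoms) {
  P <- s$positions
  measure_dihedral(P[atoms[1], ], P[atoms[2], ], P[atoms[3], ], P[atoms[4], ])
}

set_dihedral <- function(pos, atoms, moving, target) {
  cur <- measure_dihedral(pos[atoms[1], ], pos[atoms[2], ],
                          pos[atoms[3], ], pos[atoms[4], ])
  axis <- pos[atoms[3], ] - pos[atoms[2], ]
  R <- rotation_about_axis(axis, cur - target)
  pivot <- pos[atoms[3], ]
  pos[moving, ] <- sweep(sweep(pos[moving, , drop = FALSE], 2, pivot) %*%
                           t(R), 2, pivot, "+")
  pos
}

# ---------------------------------------------------------------------------
# Ring flip: rebuild the six-membered ring with the two driving torsions set
# to their targets, closing the ring by Gauss-Newton adjustment of the
# remaining free torsions and (softly) the placement angles, then carry each
# ring atom's pendant subtree along with its local frame.

ring_internal <- function(P, ring) {
  # lengths l[i] = |r_i - r_{i+1}|, angles a[i] at atom i+1 (r_i, r_i+1, r_i+2)
  idx <- function(i) ring[((i - 1) %% 6) + 1]
  lens <- vapply(1:6, function(i) vnorm(P[idx(i + 1), ] - P[idx(i), ]),
                 numeric(1))
  angs <- vapply(1:6, function(i) {
    u <- unit(P[idx(i), ] - P[idx(i + 1), ])
    v <- unit(P[idx(i + 2), ] - P[idx(i + 1), ])
    rad2deg(acos(max(-1, min(1, sum(u * v)))))
  }, numeric(1))
  tors <- vapply(1:6, function(i) {
    measure_dihedral(P[idx(i), ], P[idx(i + 1), ],
                     P[idx(i + 2), ], P[idx(i + 3), ])
  }, numeric(1))
  list(lens = lens, angs = angs, tors = tors)
}

ring_residual <- function(P, ring, t1, t2, u, geo, w_ang = 0.02) {
  q <- matrix(0, 6, 3)
  q[1, ] <- P[ring[1], ]; q[2, ] <- P[ring[2], ]; q[3, ] <- P[ring[3], ]
  q[4, ] <- nerf_place(q[1, ], q[2, ], q[3, ], geo$lens[3], geo$angs[2], t1)
  q[5, ] <- nerf_place(q[2, ], q[3, ], q[4, ], geo$lens[4], u[3], u[1])
  q[6, ] <- nerf_place(q[3, ], q[4, ], q[5, ], geo$lens[5], u[4], u[2])
  # close with the second driven torsion: position where O5 must sit
  close_pt <- nerf_place(q[4, ], q[5, ], q[6, ], geo$lens[6], u[5], t2)
  res <- c(close_pt - q[1, ],
           w_ang * (u[3] - geo$angs[3]),
           w_ang * (u[4] - geo$angs[4]),
           w_ang * (u[5] - geo$angs[5]))
  list(res = res, q = q)
}

solve_ring_closure <- function(P, ring, t1, t2, geo, tol = 1e-4,
                               max_iter = 60) {
  # initial guess: interpolate free torsions between the template chair and
  # its sign-flipped image according to the driven torsion t1
  lam <- (t1 - geo$tors[1]) / (-2 * geo$tors[1])
  lam <- max(0, min(1, if (is.finite(lam)) lam else 0))
  u <- c((1 - 2 * lam) * geo$tors[2], (1 - 2 * lam) * geo$tors[3],
         geo$angs[3], geo$angs[4], geo$angs[5])
  f <- function(u) ring_residual(P, ring, t1, t2, u, geo)
  cur <- f(u)
  for (it in seq_len(max_iter)) {
    r0 <- cur$res
    if (sqrt(sum(r0[1:3]^2)) < tol) break
    J <- matrix(0, length(r0), length(u))
    eps <- 1e-5
    for (k in seq_along(u)) {
      up <- u; up[k] <- up[k] + eps
      J[, k] <- (f(up)$res - r0) / eps
    }
    step <- tryCatch(
      solve(t(J) %*% J + 1e-10 * diag(length(u)), -t(J) %*% r0),
      error = function(e) NULL)
    if (is.null(step)) break
    # damped update
    lam_d <- 1
    repeat {
      u_try <- u + lam_d * as.numeric(step)
      cand <- f(u_try)
      if (sum(cand$res^2) < sum(r0^2) || lam_d < 1e-3) break
      lam_d <- lam_d / 2
    }
    u <- u + lam_d * as.numeric(step)
    cur <- f(u)
  }
  gap <- sqrt(sum(cur$res[1:3]^2))
  list(q = cur$q, gap = gap, ok = gap < tol)
}

apply_ring_flip <- function(pos, ring, t1, t2, adj, tol = 1e-4) {
  geo <- ring_internal(pos, ring)
  sol <- solve_ring_closure(pos, ring, t1, t2, geo, tol = tol)
  if (!sol$ok) return(list(pos = pos, ok = FALSE))
  qnew <- sol$q
  new_pos <- pos
  new_pos[ring, ] <- qnew
  # carry pendant subtrees: rotation from the ring atom's old local frame
  # (its two ring neighbours) to the new one, anchored exactly at the atom
  for (i in 1:6) {
    ai <- ring[i]
    prev <- ring[((i - 2) %% 6) + 1]
    nxt <- ring[(i %% 6) + 1]
    pend <- setdiff(graph_component(adj, ai,
                                    cut = list(c(ai, prev), c(ai, nxt))), ai)
    if (!length(pend)) next
    Pold <- rbind(pos[prev, ] - pos[ai, ], pos[nxt, ] - pos[ai, ])
    Pnew <- rbind(new_pos[prev, ] - new_pos[ai, ],
                  new_pos[nxt, ] - new_pos[ai, ])
    k <- kabsch(rbind(Pold, pracma_cross(Pold[1, ], Pold[2, ])),
                rbind(Pnew, pracma_cross(Pnew[1, ], Pnew[2, ])))
    new_pos[pend, ] <- sweep(sweep(pos[pend, , drop = FALSE], 2,
                                   pos[ai, ]) %*% t(k$R),
                             2, new_pos[ai, ], "+")
  }
  list(pos = new_pos, ok = TRUE)
}

#' Realize a conformer from reduced coordinates
#'
#' Applies the variables of a conformer space to the template: ring-flip
#' coordinate pairs first (ring rebuild with Gauss-Newton closure), then
#' glycosidic and hydroxyl torsions (rotation of the moving set about the
#' bond axis).  Bond lengths are preserved; a failed ring closure is
#' reported via the `ok` field and should be treated as a high-energy point.
#'
#' @param sugar list with `structure` and `annotations`.
#' @param space a [conformer_space()].
#' @param x numeric vector of length `space_dim(space)`.
#' @return list with `structure` (the realized conformer) and `ok`.
#' @export
realize_conformer <- function(sugar, space, x) {
  stopifnot(length(x) == space_dim(space))
  x <- space_wrap(space, x)
  s <- sugar$structure
  pos <- s$positions
  adj <- adjacency(bond_list(s), n_atoms(s))
  v <- space$vars
  ok <- TRUE
  # ring flips first (they rebuild frames that torsions then refine)
  flip_idx <- which(v$tag == "ringflip_coord")
  if (length(flip_idx)) {
    byring <- split(flip_idx,
                    vapply(space$specs[flip_idx],
                           function(sp) paste(sp$ring, collapse = "-"), ""))
    for (grp in byring) {
      sp1 <- space$specs[[grp[1]]]
      t1 <- x[grp[1]]; t2 <- x[grp[2]]
      res <- apply_ring_flip(pos, sp1$ring, t1, t2, adj)
      if (!res$ok) ok <- FALSE else pos <- res$pos
    }
  }
  for (d in which(v$tag == "dihedral")) {
    sp <- space$specs[[d]]
    pos <- set_dihedral(pos, sp$atoms, sp$moving, x[d])
  }
  out <- s
  out$positions <- pos
  out$info$x <- x
  list(structure = out, ok = ok)
}

#' Realize a rigid adsorption placement
#'
#' Rotates the rigid conformer about its geometric center by the Euler
#' angles, translates the center to `(tx, ty, top-plane + tz)` and combines
#' it with the slab.  Variables absent from the space take the defaults.
#'
#' @param conformer rigid adsorbate structure.
#' @param slab slab structure from [build_slab()].
#' @param space an [adsorption_space()].
#' @param x numeric vector matching the space.
#' @param defaults named defaults for absent variables.
#' @return combined `surfbo_structure` (adsorbate atoms first).
#' @export
realize_adsorption <- function(conformer, slab, space, x,
                               defaults = c(tx = 0, ty = 0, tz = 5,
                                            alpha = 0, beta = 0, gamma = 0)) {
  stopifnot(length(x) == space_dim(space))
  x <- space_wrap(space, x)
  p <- as.list(defaults)
  for (d in seq_len(space_dim(space))) p[[space$vars$label[d]]] <- x[d]
  R <- euler_matrix(p$alpha, p$beta, p$gamma)
  ctr <- geometric_center(conformer)
  ztop <- top_layer_z(slab)
  target <- c(p$tx, p$ty, ztop + p$tz)
  ads <- conformer
  ads$positions <- sweep(sweep(conformer$positions, 2, ctr) %*% t(R),
                         2, target, "+")
  ads$tags <- rep("adsorbate", n_atoms(ads))
  ads$frozen <- rep(FALSE, n_atoms(ads))
  out <- structure_cat(ads, slab)
  out$info$x <- x
  out
}
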