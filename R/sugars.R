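# Idealized pyranose templates: beta-d-xylopyranose in the 4C1 and 1C4 chair
# and alpha-terminated 1,4-beta-d-xylotetraose, together with the coordinate
# annotations (hydroxyl torsions, ring atoms, ring-flip torsions, glycosidic
# torsions) that drive the reduced search spaces.
#
# Geometries are idealized: uniform ring bond length, alternating-chair ring
# pucker, tetrahedral substitution.  They serve as rigid templates for the
# internal-coordinate realizers, not as relaxed reference structures.

COVALENT_RADII <- c(H = 0.31, C = 0.76, N = 0.71, O = 0.66, Cu = 1.32)

RING_BOND  <- 1.50   # uniform ring bond length (Angstrom)
RING_PUCK  <- 0.25   # half chair amplitude (Angstrom)
CO_BOND    <- 1.43
CH_BOND    <- 1.10
OH_BOND    <- 0.97
TET_HALF   <- 54.75  # half tetrahedral angle for substituent fan-out

#' Covalent bond list of a structure
#'
#' Bonds are detected from covalent radii (pair closer than 1.25 times the
#' radius sum).  Periodicity is ignored: intended for isolated molecules.
#'
#' @param s a `surfbo_structure`.
#' @return two-column integer matrix of bonded atom index pairs.
#' @export
bond_list <- function(s) {
  n <- n_atoms(s)
  r <- COVALENT_RADII[s$symbols]
  if (anyNA(r)) stop("unknown element for bond detection")
  out <- matrix(0L, 0, 2)
  if (n < 2) return(out)
  P <- s$positions
  for (i in seq_len(n - 1L)) {
    d <- sqrt(rowSums(sweep(P[(i + 1L):n, , drop = FALSE], 2, P[i, ])^2))
    cut <- 1.25 * (r[i] + r[(i + 1L):n])
    j <- which(d < cut)
    if (length(j)) out <- rbind(out, cbind(i, i + j))
  }
  out
}

# adjacency list from a bond matrix
adjacency <- function(bonds, n) {
  adj <- vector("list", n)
  for (k in seq_len(nrow(bonds))) {
    i <- bonds[k, 1]; j <- bonds[k, 2]
    adj[[i]] <- c(adj[[i]], j)
    adj[[j]] <- c(adj[[j]], i)
  }
  adj
}

# connected component of `start` after removing edges in `cut` (list of pairs)
graph_component <- function(adj, start, cut = NULL) {
  blocked <- function(i, j) {
    if (is.null(cut)) return(FALSE)
    any(vapply(cut, function(e) (e[1] == i && e[2] == j) ||
                                (e[1] == j && e[2] == i), logical(1)))
  }
  seen <- logical(length(adj))
  queue <- start
  seen[start] <- TRUE
  while (length(queue)) {
    i <- queue[[1]]; queue <- queue[-1]
    for (j in adj[[i]]) {
      if (!seen[j] && !blocked(i, j)) {
        seen[j] <- TRUE
        queue <- c(queue, j)
      }
    }
  }
  which(seen)
}

# pairwise bond-graph distances (BFS from every atom)
graph_distances <- function(adj) {
  n <- length(adj)
  D <- matrix(Inf, n, n)
  for (s in seq_len(n)) {
    D[s, s] <- 0
    queue <- s
    while (length(queue)) {
      i <- queue[[1]]; queue <- queue[-1]
      for (j in adj[[i]]) {
        if (!is.finite(D[s, j])) {
          D[s, j] <- D[s, i] + 1
          queue <- c(queue, j)
        }
      }
    }
  }
  D
}

#' Molecular formula in Hill order
#' @param s a structure.
#' @return character scalar, e.g. `"C5H10O5"`.
#' @export
chem_formula <- function(s) {
  tab <- table(s$symbols)
  elems <- names(tab)
  ord <- c(intersect(c("C", "H"), elems), sort(setdiff(elems, c("C", "H"))))
  paste0(vapply(ord, function(e)
    paste0(e, if (tab[[e]] > 1) tab[[e]] else ""), ""), collapse = "")
}

# The two exocyclic substituent directions at ring atom `p` with ring
# neighbours `n1`, `n2`: returns list(axial=, equatorial=) unit vectors,
# axial being the one more aligned with the ring normal (z of the template).
substituent_dirs <- function(p, n1, n2) {
  b1 <- unit(n1 - p); b2 <- unit(n2 - p)
  s <- -unit(b1 + b2)
  t <- unit(pracma_cross(b1, b2))
  w <- deg2rad(TET_HALF)
  d1 <- cos(w) * s + sin(w) * t
  d2 <- cos(w) * s - sin(w) * t
  if (abs(d1[3]) >= abs(d2[3])) list(axial = d1, equatorial = d2)
  else list(axial = d2, equatorial = d1)
}

#' Build an idealized beta-d-xylopyranose template
#'
#' Ring atoms are placed on an ideal alternating chair (hexagon of uniform
#' bond length with alternating z displacement).  In the `"4C1"` chair all
#' four hydroxyls are equatorial (the beta-d-xylose ground-state pattern);
#' `"1C4"` is its ring-flipped mirror.  Atom order: O5 C1 C2 C3 C4 C5 (1-6),
#' then O/H pairs on C1..C4 (O1 H1 ... O4 H4, 7-14), H5a H5b (15-16),
#' hydroxyl protons HO1-HO4 (17-20).
#'
#' @param chair `"4C1"` or `"1C4"`.
#' @param alpha if `TRUE` the anomeric hydroxyl (C1-O1) is placed axially
#'   (alpha configuration) instead of equatorially (beta).
#' @return list with `structure` (a 20-atom `surfbo_structure`) and
#'   `annotations` (hydroxyl/ring/ring-flip index lists).
#' @export
build_xylose_template <- function(chair = c("4C1", "1C4"), alpha = FALSE) {
  chair <- match.arg(chair)
  h <- if (chair == "4C1") RING_PUCK else -RING_PUCK
  # hexagon radius giving uniform ring bond length
  R <- sqrt(RING_BOND^2 - 4 * RING_PUCK^2)
  ring <- t(vapply(0:5, function(k) {
    c(R * cos(pi / 3 * k), R * sin(pi / 3 * k), h * (-1)^k)
  }, numeric(3)))
  # ring order: O5 C1 C2 C3 C4 C5 at k = 0..5
  symbols <- c("O", rep("C", 5))
  pos <- ring
  nbr <- function(k) ring[((k - 1) %% 6) + 1, ]  # 1-based circular index
  add <- function(sym, p) {
    symbols <<- c(symbols, sym)
    pos <<- rbind(pos, p)
    nrow(pos)
  }
  o_idx <- integer(4); h_idx <- integer(4)
  for (c_k in 2:5) {                       # C1..C4 carry one OH + one H
    dirs <- substituent_dirs(ring[c_k, ], nbr(c_k - 1), nbr(c_k + 1))
    o_dir <- dirs$equatorial; h_dir <- dirs$axial
    if (alpha && c_k == 2) { o_dir <- dirs$axial; h_dir <- dirs$equatorial }
    o_idx[c_k - 1] <- add("O", ring[c_k, ] + CO_BOND * o_dir)
    h_idx[c_k - 1] <- add("H", ring[c_k, ] + CH_BOND * h_dir)
  }
  dirs5 <- substituent_dirs(ring[6, ], nbr(5), nbr(7))
  add("H", ring[6, ] + CH_BOND * dirs5$axial)
  add("H", ring[6, ] + CH_BOND * dirs5$equatorial)
  ho_idx <- integer(4)
  for (k in 1:4) {
    c_k <- k + 1
    ho_idx[k] <- add("H", nerf_place(ring[c_k - 1, ], ring[c_k, ],
                                     pos[o_idx[k], ], OH_BOND, 108, 180))
  }
  s <- structure_new(symbols, pos)
  ann <- list(
    hydroxyls = lapply(1:4, function(k) c(k, k + 1, o_idx[k], ho_idx[k])),
    ring_atoms = list(1:6),
    ringflip = list(list(t1 = c(1L, 2L, 3L, 4L), t2 = c(4L, 5L, 6L, 1L))),
    glycosidic = list()
  )
  list(structure = s, annotations = ann)
}

#' Build an idealized 1,4-beta-d-xylotetraose template
#'
#' Four xylopyranose units joined by beta(1->4) glycosidic bonds; the chain
#' is alpha-terminated (the free anomeric hydroxyl of the last unit is
#' axial).  Each condensation removes the donor anomeric hydroxyl (O1 + HO1)
#' and the acceptor HO4, leaving C20H34O17 (71 atoms).
#'
#' @param phi,psi default glycosidic torsions (degrees) applied to every
#'   linkage; phi is O5'-C1'-O4-C4, psi is C1'-O4-C4-C3.
#' @return list with `structure` and `annotations` as in
#'   [build_xylose_template()].
#' @export
build_xylotetraose_template <- function(phi = -120, psi = -100) {
  unit_t <- build_xylose_template("4C1")
  unit_a <- build_xylose_template("4C1", alpha = TRUE)
  units <- list(unit_t, unit_t, unit_t, unit_a)
  placed <- list(units[[1]]$structure$positions)
  # template indices within one unit
  iO5 <- 1L; iC1 <- 2L; iC3 <- 4L; iC4 <- 5L
  iO1 <- 7L; iO4 <- 13L
  for (k in 1:3) {
    Pk <- placed[[k]]
    tmpl <- units[[k + 1]]$structure$positions
    # glycosidic oxygen replaces the donor anomeric oxygen direction
    o4p <- Pk[iC1, ] + CO_BOND * unit(Pk[iO1, ] - Pk[iC1, ])
    len_o4c4 <- vnorm(tmpl[iC4, ] - tmpl[iO4, ])
    len_c4c3 <- vnorm(tmpl[iC3, ] - tmpl[iC4, ])
    ang_o4c4c3 <- rad2deg(acos(sum(unit(tmpl[iO4, ] - tmpl[iC4, ]) *
                                   unit(tmpl[iC3, ] - tmpl[iC4, ]))))
    c4p <- nerf_place(Pk[iO5, ], Pk[iC1, ], o4p, len_o4c4, 117, phi)
    c3p <- nerf_place(Pk[iC1, ], o4p, c4p, len_c4c3, ang_o4c4c3, psi)
    tr <- frame_transform(tmpl[iO4, ], tmpl[iC4, ], tmpl[iC3, ],
                          o4p, c4p, c3p)
    placed[[k + 1]] <- apply_frame_transform(tr, tmpl)
  }
  # assemble with deletions and build the global index map
  symbols <- character(0); pos <- matrix(0, 0, 3)
  maps <- vector("list", 4)
  for (k in 1:4) {
    drop <- integer(0)
    if (k <= 3) drop <- c(drop, iO1, 17L)       # donor loses O1 + HO1
    if (k >= 2) drop <- c(drop, 20L)            # acceptor loses HO4
    keep <- setdiff(1:20, drop)
    map <- rep(NA_integer_, 20)
    map[keep] <- nrow(pos) + seq_along(keep)
    maps[[k]] <- map
    symbols <- c(symbols, units[[k]]$structure$symbols[keep])
    pos <- rbind(pos, placed[[k]][keep, , drop = FALSE])
  }
  s <- structure_new(symbols, pos)
  hydroxyls <- list(); rings <- list(); flips <- list(); glyc <- list()
  for (k in 1:4) {
    map <- maps[[k]]
    for (hd in units[[k]]$annotations$hydroxyls) {
      g <- map[hd]
      if (!anyNA(g)) hydroxyls[[length(hydroxyls) + 1]] <- g
    }
    rings[[k]] <- map[1:6]
    flips[[k]] <- list(t1 = map[c(1, 2, 3, 4)], t2 = map[c(4, 5, 6, 1)])
  }
  for (k in 1:3) {
    mk <- maps[[k]]; mk1 <- maps[[k + 1]]
    glyc[[k]] <- list(phi = c(mk[iO5], mk[iC1], mk1[iO4], mk1[iC4]),
                      psi = c(mk[iC1], mk1[iO4], mk1[iC4], mk1[iC3]))
  }
  list(structure = s,
       annotations = list(hydroxyls = hydroxyls, ring_atoms = rings,
                          ringflip = flips, glycosidic = glyc))
}

#' Load a packaged sugar template
#'
#' Returns the frozen packaged template (structure plus annotations) for the
#' requested sugar.  Templates were generated once with
#' [build_xylose_template()] / [build_xylotetraose_template()] and shipped as
#' extended-XYZ plus JSON annotation files, so downstream results do not
#' depend on re-running the builder.
#'
#' @param kind one of `"xylose_4C1"`, `"xylose_1C4"`, `"xylotetraose"`.
#' @param rebuild build freshly in code instead of reading the packaged file.
#' @return list with `structure` and `annotations`.
#' @export
make_sugar <- function(kind = c("xylose_4C1", "xylose_1C4", "xylotetraose"),
                       rebuild = FALSE) {
  kind <- match.arg(kind)
  if (rebuild) {
    return(switch(kind,
      xylose_4C1   = build_xylose_template("4C1"),
      xylose_1C4   = build_xylose_template("1C4"),
      xylotetraose = build_xylotetraose_template()))
  }
  xyz <- system.file("extdata", paste0(kind, ".xyz"), package = "surfbo")
  ann <- system.file("extdata", paste0(kind, "_annotations.json"),
                     package = "surfbo")
  if (!nzchar(xyz) || !nzchar(ann)) return(make_sugar(kind, rebuild = TRUE))
  a <- jsonlite::read_json(ann, simplifyVector = FALSE)
  iv <- function(v) as.integer(unlist(v))
  list(structure = read_xyz(xyz),
       annotations = list(
         hydroxyls = lapply(a$hydroxyls, iv),
         ring_atoms = lapply(a$ring_atoms, iv),
         ringflip = lapply(a$ringflip, function(f)
           list(t1 = iv(f$t1), t2 = iv(f$t2))),
         glycosidic = lapply(a$glycosidic, function(g)
           list(phi = iv(g$phi), psi = iv(g$psi)))))
}
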