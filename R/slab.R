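# Orthogonal fcc(111) slab construction and distance measures.

#' Orthogonal (111) surface cell dimensions
#'
#' In-plane repeat lengths of the rectangular (centred) surface cell of an
#' fcc(111) face: `a = a_fcc / sqrt(2)` (the nearest-neighbour distance) and
#' `b = a_fcc * sqrt(3) / sqrt(2)`.  These define the bounds of the
#' translational part of an adsorption search.
#'
#' @param a_fcc bulk fcc lattice constant (Angstrom).
#' @return named numeric vector `c(a = ..., b = ...)` in Angstrom.
#' @examples
#' surface_cell_dimensions(3.632)  # Cu(111): c(a = 2.568, b = 4.448)
#' @export
surface_cell_dimensions <- function(a_fcc) {
  if (!is.numeric(a_fcc) || length(a_fcc) != 1 || !is.finite(a_fcc) ||
      a_fcc <= 0)
    stop("a_fcc must be a positive number")
  c(a = a_fcc / sqrt(2), b = a_fcc * sqrt(3) / sqrt(2))
}

#' Slab specification
#'
#' @param a_fcc bulk fcc lattice constant (Angstrom).
#' @param nx,ny number of atoms per layer along the two orthogonal in-plane
#'   directions.  A layer holds `nx * ny` atoms, so a `6 x 8 x 4` slab has 192
#'   atoms: layer size is counted in atoms, not in two-atom orthogonal cells.
#' @param n_layers number of (111) layers.
#' @param vacuum vacuum thickness added along z (Angstrom), split evenly
#'   above and below the slab.
#' @param n_frozen_layers number of bottom layers kept frozen (bulk-like).
#' @param element chemical symbol of the metal.
#' @return object of class `surfbo_slab_spec`.
#' @export
slab_spec <- function(a_fcc, nx, ny, n_layers, vacuum = 60,
                      n_frozen_layers = 2, element = "Cu") {
  stopifnot(a_fcc > 0, nx >= 1, ny >= 1, n_layers >= 1, vacuum >= 0,
            n_frozen_layers >= 0, n_frozen_layers < n_layers)
  out <- list(a_fcc = a_fcc, nx = as.integer(nx), ny = as.integer(ny),
              n_layers = as.integer(n_layers), vacuum = vacuum,
              n_frozen_layers = as.integer(n_frozen_layers),
              element = element)
  class(out) <- "surfbo_slab_spec"
  out
}

#' Build an orthogonal fcc(111) slab
#'
#' Constructs an `nx x ny x n_layers` slab (atoms per layer = `nx * ny`) with
#' ABC stacking along z, interlayer spacing `a_fcc / sqrt(3)`, the bottom
#' `n_frozen_layers` layers frozen, and the requested vacuum along z.  The
#' in-plane cell is orthogonal with dimensions `nx * a` by `ny * b / 2` where
#' `(a, b)` are the surface-cell dimensions; rows within a layer alternate by
#' half the nearest-neighbour spacing, reproducing the triangular (111)
#' surface net with an atop atom at the top-layer xy origin.
#'
#' @param spec a [slab_spec()].
#' @return a `surfbo_structure`; all atoms tagged `"substrate"`.  The
#'   structure `info` carries `surface_a`, `surface_b` (search-cell
#'   dimensions) and `top_z` (mean z of the top layer).
#' @export
build_slab <- function(spec) {
  stopifnot(inherits(spec, "surfbo_slab_spec"))
  sc <- surface_cell_dimensions(spec$a_fcc)
  a1 <- sc[["a"]]                # nearest-neighbour / row period
  ry <- sc[["b"]] / 2            # spacing between atom rows
  dz <- spec$a_fcc / sqrt(3)     # (111) interlayer spacing
  Lx <- spec$nx * a1
  Ly <- spec$ny * ry
  z0 <- spec$vacuum / 2
  pos <- matrix(0, spec$nx * spec$ny * spec$n_layers, 3)
  frozen <- logical(nrow(pos))
  idx <- 1L
  for (l in seq_len(spec$n_layers) - 1L) {
    # stacking so the *top* layer sits at offset (0, 0): atop site at origin
    stack <- (l - (spec$n_layers - 1L)) %% 3L
    ox <- stack * a1 / 2
    oy <- stack * ry / 3
    for (j in seq_len(spec$ny) - 1L) {
      for (i in seq_len(spec$nx) - 1L) {
        x <- (i + 0.5 * (j %% 2L)) * a1 + ox
        y <- j * ry + oy
        pos[idx, ] <- c(x %% Lx, y %% Ly, z0 + l * dz)
        frozen[idx] <- l < spec$n_frozen_layers
        idx <- idx + 1L
      }
    }
  }
  cell <- diag(c(Lx, Ly, (spec$n_layers - 1L) * dz + spec$vacuum))
  structure_new(rep(spec$element, nrow(pos)), pos,
                cell = cell, pbc = c(TRUE, TRUE, FALSE),
                frozen = frozen, tags = rep("substrate", nrow(pos)),
                info = list(surface_a = a1, surface_b = sc[["b"]],
                            top_z = z0 + (spec$n_layers - 1L) * dz,
                            slab_spec = unclass(spec)))
}

#' Mean z of the top substrate layer
#' @param s a structure containing substrate atoms.
#' @param tol atoms within `tol` Angstrom of the highest substrate atom count
#'   as the top layer.
#' @return z of the top-layer plane (Angstrom).
#' @export
top_layer_z <- function(s, tol = 0.1) {
  z <- s$positions[s$tags == "substrate", 3]
  if (!length(z)) stop("structure has no substrate atoms")
  mean(z[z > max(z) - tol])
}

#' Place an adsorbate over a slab
#'
#' The adsorbate's geometric center is positioned `height` Angstrom above the
#' mean z of the top substrate layer; its in-plane center position is kept.
#' Atom order is adsorbate first, then slab; tags and frozen masks carry over.
#'
#' @param adsorbate non-periodic molecule (`surfbo_structure`).
#' @param slab periodic slab from [build_slab()].
#' @param height target height of the adsorbate geometric center above the
#'   top-layer plane (Angstrom).
#' @return combined `surfbo_structure`.
#' @export
assemble <- function(adsorbate, slab, height) {
  if (n_atoms(adsorbate) == 0) return(slab)
  if (any(adsorbate$pbc)) stop("adsorbate must be non-periodic")
  if (!any(slab$pbc)) stop("slab must be periodic in-plane")
  ztop <- top_layer_z(slab)
  ctr <- geometric_center(adsorbate)
  ads <- adsorbate
  ads$positions <- sweep(ads$positions, 2, c(0, 0, ctr[3] - (ztop + height)))
  ads$tags <- rep("adsorbate", n_atoms(ads))
  structure_cat(ads, slab)
}

#' Minimum interatomic distance
#'
#' Minimum over all atom pairs, applying the minimum-image convention along
#' periodic directions (orthogonal cells).
#'
#' @param s a structure with at least two atoms.
#' @return smallest pair distance (Angstrom).
#' @export
min_interatomic_distance <- function(s) {
  n <- n_atoms(s)
  if (n < 2) stop("need at least two atoms")
  P <- s$positions
  L <- sqrt(rowSums(s$cell^2))
  mind <- Inf
  for (i in seq_len(n - 1L)) {
    D <- sweep(P[(i + 1L):n, , drop = FALSE], 2, P[i, ])
    for (k in which(s$pbc)) {
      D[, k] <- D[, k] - round(D[, k] / L[k]) * L[k]
    }
    mind <- min(mind, sqrt(min(rowSums(D * D))))
  }
  mind
}

# Minimum-image distance between an adsorbate block and the rest, used for
# cheap contact screening: same as min_interatomic_distance but restricted to
# cross pairs plus intra-adsorbate pairs.
contact_distance <- function(s) {
  min_interatomic_distance(s)
}
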