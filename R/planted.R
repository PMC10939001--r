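# Synthetic periodic landscape with planted minima: the oracle fixture for
# search-loop testing.  Minima locations and energies are known by
# construction, so grid scans and the Bayesian-optimization loop can be
# compared against ground truth.

#' Toy periodic landscape with planted minima
#'
#' A two-dimensional periodic potential over one rectangular surface cell
#' (by default twice the Cu(111) search cell in each direction): a sum of
#' Gaussian wells with distinct depths, periodized over a 3 x 3 block of
#' image cells so the landscape is smooth across the boundary.  Well centers
#' are drawn with a minimum mutual separation; registered minima are refined
#' from the planted centers by local descent on the true landscape.
#'
#' The realized configuration is a single probe atom above a four-atom
#' anchor plate (the plate pins the Kabsch superposition so that RMSD-based
#' deduplication distinguishes wells).
#'
#' @param n_minima number of planted wells.
#' @param seed RNG seed for the well placement.
#' @param cell in-plane periodic cell `c(a, b)` in Angstrom.
#' @param depth0 depth of the deepest well (eV, positive number).
#' @param depth_step depth difference between successive wells (eV).
#' @param width Gaussian well width (Angstrom).
#' @param min_sep minimum separation between well centers (Angstrom).
#' @return list with `objective` (a `surfbo_objective`), `space`,
#'   `minima` (data frame of refined locations and energies, deepest
#'   first), and `energy_fn(x)` (the bare landscape).
#' @export
make_planted_surface <- function(n_minima = 3, seed = 1,
                                 cell = 2 * surface_cell_dimensions(3.632),
                                 depth0 = 1.0, depth_step = 0.2,
                                 width = 0.8, min_sep = 2.5) {
  a <- cell[[1]]; b <- cell[[2]]
  depths <- depth0 - depth_step * (seq_len(n_minima) - 1)
  set.seed(seed)
  centers <- matrix(NA_real_, 0, 2)
  tries <- 0
  while (nrow(centers) < n_minima && tries < 10000) {
    tries <- tries + 1
    p <- c(stats::runif(1, 0, a), stats::runif(1, 0, b))
    ok <- TRUE
    for (i in seq_len(nrow(centers))) {
      d <- p - centers[i, ]
      d[1] <- d[1] - round(d[1] / a) * a
      d[2] <- d[2] - round(d[2] / b) * b
      if (sqrt(sum(d^2)) < min_sep) { ok <- FALSE; break }
    }
    if (ok) centers <- rbind(centers, p)
  }
  if (nrow(centers) < n_minima)
    stop("could not place wells with the requested separation")

  energy_fn <- function(x) {
    # wrap into the cell first so periodicity is exact, then sum a 3 x 3
    # block of image wells (farther images are negligible and identical
    # for every wrapped point)
    x <- c(x[1] %% a, x[2] %% b)
    E <- 0
    for (m in seq_len(n_minima)) {
      for (i in -1:1) for (j in -1:1) {
        d <- x - centers[m, ] - c(i * a, j * b)
        E <- E - depths[m] * exp(-sum(d^2) / (2 * width^2))
      }
    }
    E
  }

  space <- search_space_new(c("tx", "ty"), c(0, 0), c(a, b),
                            c(TRUE, TRUE),
                            c("translation_x", "translation_y"),
                            kind = "planted")
  # refine the registered minima on the true landscape
  minima <- do.call(rbind, lapply(seq_len(n_minima), function(m) {
    fit <- stats::optim(centers[m, ], energy_fn, method = "BFGS")
    x <- space_wrap(space, fit$par)
    data.frame(tx = x[1], ty = x[2], energy = fit$value)
  }))
  minima <- minima[order(minima$energy), ]
  rownames(minima) <- NULL

  anchors <- rbind(c(0, 0, 0), c(a, 0, 0), c(0, b, 0), c(a, b, 0))
  realize <- function(x) {
    x <- space_wrap(space, x)
    pos <- rbind(c(x[1], x[2], 2.0), anchors)
    s <- structure_new(c("O", rep("Cu", 4)), pos,
                       cell = diag(c(a, b, 20)),
                       pbc = c(FALSE, FALSE, FALSE),
                       tags = c("adsorbate", rep("substrate", 4)),
                       info = list(x = x))
    list(structure = s, ok = TRUE)
  }
  energy <- function(s) list(energy = energy_fn(s$info$x), forces = NULL)
  objective <- objective_new(realize, energy, space, reference = 0,
                             label = "planted-surface")
  list(objective = objective, space = space, minima = minima,
       energy_fn = energy_fn, centers = centers, depths = depths,
       cell = c(a, b))
}
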