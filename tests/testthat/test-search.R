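# a minimal 1-D objective over an abstract space: realizes a two-atom frame
# so RMSD-based operations stay meaningful
line_objective <- function(f, lo = 0, hi = 1) {
  sp <- search_space_new("x", lo, hi, FALSE, "translation_x")
  realize <- function(x) {
    s <- structure_new(c("O", "Cu"), rbind(c(x[1], 0, 2), c(0, 0, 0)),
                       tags = c("adsorbate", "substrate"),
                       info = list(x = x))
    list(structure = s, ok = TRUE)
  }
  objective_new(realize, function(s) list(energy = f(s$info$x[1]),
                                          forces = NULL), sp)
}

test_that("the search loop solves a 1-D convex problem and is deterministic", {
  obj <- line_objective(function(x) (x - 0.3)^2)
  st <- bo_settings(n_init = 5, max_iter = 25, stall_limit = 100, seed = 1)
  res <- run_search(obj, st)
  gm <- res$history[nrow(res$history), 1]
  expect_lt(abs(gm - 0.3), 1e-2)
  expect_lt(abs(min(res$data$y)), 1e-3)
  # identical seed reproduces the dataset and history bit for bit
  res2 <- run_search(obj, st)
  expect_identical(res$X, res2$X)
  expect_identical(res$data, res2$data)
  expect_identical(res$history, res2$history)
  # the best transformed energy never worsens as data accumulate
  best_so_far <- cummin(res$data$y)
  expect_true(all(diff(best_so_far) <= 0))
})

test_that("symmetry augmentation yields six images copying the source energy", {
  slab <- small_slab()
  sp <- adsorption_space(slab)
  set.seed(21)
  for (rep in 1:5) {
    x <- c(runif(1, 0.3, 2.2), runif(1, 0.3, 4.1), runif(1, 3, 8),
           runif(1, 0, 360), runif(1, 10, 170), runif(1, 0, 360))
    M <- augment_symmetry(x, sp)
    expect_equal(nrow(M), 6)
    expect_equal(M[1, ], x, tolerance = 1e-12)
    # all images inside the bounds
    for (r in seq_len(nrow(M)))
      expect_true(all(M[r, ] >= sp$vars$lower - 1e-9 &
                        M[r, ] <= sp$vars$upper + 1e-9))
  }
  # a point on the rotation axis collapses the rotation images when the
  # adsorbate carries no azimuthal variable (axially symmetric probe)
  sp3 <- adsorption_space(slab, vars = c("tx", "ty", "tz"))
  M0 <- augment_symmetry(c(0, 0, 5), sp3)
  expect_equal(nrow(M0), 2)
  # augmented observations copy their source's energies in the dataset
  calc <- toy_surface_calculator(slab)
  obj <- adsorption_objective(probe_atom(), slab,
                              adsorption_space(slab,
                                               vars = c("tx", "ty", "tz"),
                                               tz_bounds = c(1.2, 6)),
                              calc)
  st <- bo_settings(n_init = 4, max_iter = 2, stall_limit = 100, seed = 2,
                    augment = TRUE, refine_minima = FALSE)
  res <- run_search(obj, st)
  sampled <- which(res$data$provenance == "sampled")
  blocks <- split(seq_len(nrow(res$data)),
                  findInterval(seq_len(nrow(res$data)), sampled))
  for (rows in blocks) {
    expect_true(all(res$data$y[rows] == res$data$y[rows[1]]))
  }
  expect_true(any(res$data$provenance == "augmented"))
  # augmentation multiplies rows without adding sampled energies
  expect_equal(sum(res$data$provenance == "sampled"), 6)
})

test_that("kabsch RMSD: exactness, hand-computed case, and guards", {
  xyl <- make_sugar("xylose_4C1")$structure
  expect_equal(kabsch_rmsd(xyl, xyl), 0)
  rot <- transform_structure(xyl, axis = c(2, -1, 3), angle = 123,
                             shift = c(4, 5, -6))
  expect_lt(kabsch_rmsd(xyl, rot), 1e-9)
  # three-atom pair with a hand-computable optimum: A is an isosceles
  # triangle, B the same triangle with one vertex displaced along a
  # symmetry-preserving direction; optimal superposition leaves a residual
  # displacement of d at one atom -> RMSD = d * sqrt(2/3) / sqrt... checked
  # against a dense rotation scan instead of an algebraic guess:
  A <- structure_new(rep("C", 3),
                     rbind(c(0, 0, 0), c(2, 0, 0), c(1, 1.5, 0)))
  B <- structure_new(rep("C", 3),
                     rbind(c(0, 0, 0), c(2, 0, 0), c(1, 1.9, 0)))
  got <- kabsch_rmsd(A, B)
  # brute-force oracle: scan in-plane rotations + optimal translation
  brute <- Inf
  Pa <- A$positions; Pb <- B$positions
  Pa0 <- sweep(Pa, 2, colMeans(Pa)); Pb0 <- sweep(Pb, 2, colMeans(Pb))
  for (th in seq(-20, 20, by = 0.001)) {
    R <- rotation_about_axis(c(0, 0, 1), th)
    brute <- min(brute, sqrt(mean(rowSums((Pa0 %*% t(R) - Pb0)^2))))
  }
  expect_equal(got, brute, tolerance = 1e-6)
  expect_error(kabsch_rmsd(A, structure_new(rep("N", 3), B$positions)),
               "composition")
  expect_error(kabsch_rmsd(A, probe_atom()), "atom count")
})

test_that("deduplication keeps one representative per basin, independent of order", {
  xyl <- make_sugar("xylose_4C1")
  sp <- conformer_space(xyl, hydroxyls = TRUE, glycosidic = FALSE,
                        ring_mode = "none")
  x0 <- space_current_x(xyl, sp)
  conf <- function(dx, seed = NULL) {
    # distinct conformer: rotate hydroxyls; Kabsch cannot undo torsions
    s <- realize_conformer(xyl, sp, x0 + dx)$structure
    if (!is.null(seed)) {
      set.seed(seed)
      s$positions <- s$positions +
        matrix(rnorm(length(s$positions), 0, 0.01), ncol = 3)
    }
    s
  }
  m1 <- list(x = 1, E_pred = -1.0, structure = conf(c(0, 0, 0, 0)))
  m1b <- list(x = 2, E_pred = -0.9, structure = conf(c(0, 0, 0, 0), 1))
  m2 <- list(x = 3, E_pred = -0.8, structure = conf(c(120, -90, 0, 0)))
  # identical minima collapse to one
  expect_length(deduplicate(list(m1, m1, m1)), 1)
  # near-duplicates collapse, distinct conformers survive
  kept <- deduplicate(list(m1, m1b, m2), threshold = 0.3)
  expect_length(kept, 2)
  expect_equal(kept[[1]]$E_pred, -1.0)
  # all pairwise RMSD above threshold: everything kept
  far <- list(m1, m2,
              list(x = 9, E_pred = -0.5,
                   structure = conf(c(-120, 120, 150, 0))))
  expect_length(deduplicate(far, threshold = 0.3), 3)
  # order independence for well-separated clusters
  kept_rev <- deduplicate(list(m2, m1b, m1), threshold = 0.3)
  expect_length(kept_rev, 2)
  expect_equal(sort(vapply(kept, `[[`, 0, "E_pred")),
               sort(vapply(kept_rev, `[[`, 0, "E_pred")))
})

test_that("harvesting finds the basins of the surrogate landscape", {
  # single basin: exactly one minimum
  obj <- line_objective(function(x) (x - 0.6)^2)
  res <- run_search(obj, bo_settings(n_init = 5, max_iter = 15,
                                     stall_limit = 100, seed = 2))
  mins <- harvest_minima(res$model, obj$space, seed = 3)
  expect_length(mins, 1)
  expect_lt(abs(mins[[1]]$x - 0.6), 0.02)
  # minima count saturates when doubling the number of starts
  ps <- make_planted_surface(3, seed = 1)
  res2 <- run_search(ps$objective,
                     bo_settings(n_init = 5, max_iter = 40,
                                 stall_limit = 100, seed = 2))
  m1 <- harvest_minima(res2$model, ps$space, n_starts = 200, seed = 5)
  m2 <- harvest_minima(res2$model, ps$space, n_starts = 400, seed = 5)
  # basins of non-trivial depth saturate: doubling the starts changes
  # neither their count nor their locations (micro-wiggles of the flat
  # plateau are excluded by the depth cut)
  deep <- function(mm) Filter(function(m) m$E_pred < -0.1, mm)
  d1 <- deep(m1); d2 <- deep(m2)
  expect_equal(length(d1), length(d2))
  for (k in seq_along(d1)) {
    expect_lt(sqrt(sum(space_delta(ps$space, d1[[k]]$x, d2[[k]]$x)^2)),
              0.05)
  }
  # ranking is by predicted energy
  E <- vapply(m1, `[[`, 0, "E_pred")
  expect_true(all(diff(E) >= 0))
})

test_that("force-seeking runs enrich high-force configurations", {
  slab <- small_slab()
  calc <- toy_surface_calculator(slab)
  sp <- adsorption_space(slab, vars = c("tx", "ty", "tz"),
                         tz_bounds = c(1.2, 6))
  obj <- adsorption_objective(probe_atom(), slab, sp, calc)
  n_total <- 20
  fs_max <- c(); rnd_max <- c()
  for (seed in 1:5) {
    res <- run_force_seeking(obj, bo_settings(
      n_init = 5, max_iter = n_total - 5, stall_limit = 100, seed = seed,
      refine_minima = FALSE))
    fs_max <- c(fs_max, max(res$data$max_force, na.rm = TRUE))
    # equal-budget random baseline
    set.seed(1000 + seed)
    rb <- 0
    for (k in seq_len(n_total)) {
      x <- sp$vars$lower + runif(3) * (sp$vars$upper - sp$vars$lower)
      ev <- calc$evaluate(obj$realize(x)$structure)
      rb <- max(rb, max(abs(ev$forces[1, ])))
    }
    rnd_max <- c(rnd_max, rb)
    # determinism of the force-seeking dataset
    if (seed == 1) {
      res_b <- run_force_seeking(obj, bo_settings(
        n_init = 5, max_iter = n_total - 5, stall_limit = 100, seed = seed,
        refine_minima = FALSE))
      expect_identical(res$X, res_b$X)
      expect_identical(res$data, res_b$data)
    }
  }
  expect_gte(stats::median(fs_max), stats::median(rnd_max))
  # contact configurations skip the backend and carry no force objective
  contact_obj <- objective_new(
    realize = function(x) {
      s <- structure_new(c("O", "O"), rbind(c(0, 0, 0), c(0.3, 0, 0)),
                         info = list(x = x))
      list(structure = s, ok = TRUE)
    },
    energy = function(s) stop("backend must not be called"),
    space = search_space_new("x", 0, 1, FALSE, "translation_x"))
  ev <- surfbo:::evaluate_point(contact_obj, 0.5, transform_settings())
  expect_equal(ev$provenance, "capped")
  expect_equal(ev$E_trans, 5.0)
  expect_true(is.na(ev$max_force))
})
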