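test_that("radial descriptors: invariances, isolated atom, dimer closed form", {
  st <- mlip_settings(cutoff = 3.5, n_basis = 4, elements = c("Cu", "O"))
  # isolated atom: zero features
  expect_true(all(mlip_featurize(probe_atom(), st) == 0))
  # dimer closed form
  d <- 2.0
  s <- structure_new(c("O", "Cu"), rbind(c(0, 0, 0), c(d, 0, 0)))
  Phi <- mlip_featurize(s, st)
  mu <- seq(0, 3.5, length.out = 4)
  u <- d / 3.5
  g <- exp(-(d - mu)^2 / (2 * st$sigma^2)) * (1 - 3 * u^2 + 2 * u^3)
  expect_lt(max(abs(Phi[1, 1:4] - g)), 1e-12)   # O sees a Cu neighbour
  expect_lt(max(abs(Phi[2, 5:8] - g)), 1e-12)   # Cu sees an O neighbour
  expect_true(all(Phi[1, 5:8] == 0))
  # rigid rotation + translation invariance on a bigger frame
  slab <- small_slab()
  sys <- assemble(probe_atom(), slab, 2)
  sys$pbc <- c(FALSE, FALSE, FALSE)   # so the rigid motion test is exact
  Phi0 <- mlip_featurize(sys, st)
  Phi1 <- mlip_featurize(transform_structure(sys), st)
  expect_lt(max(abs(Phi0 - Phi1)), 1e-10)
  # permutation of atoms within an element permutes rows only
  perm <- c(1, seq(n_atoms(sys), 2))
  sys_p <- structure_subset(sys, perm)
  Phi2 <- mlip_featurize(sys_p, st)
  expect_lt(max(abs(Phi2 - Phi0[perm, ])), 1e-10)
})

test_that("training is exact on a linear-in-features backend and reports a held-out split", {
  st <- mlip_settings(cutoff = 3.5, n_basis = 6, elements = c("Cu", "O"),
                      lambda = 1e-10)
  slab <- small_slab(3, 3, 2)
  sp <- adsorption_space(slab, vars = c("tx", "ty", "tz"),
                         tz_bounds = c(1.2, 5))
  # synthetic backend that IS linear in the pooled descriptors
  set.seed(11)
  w_true <- rnorm(2 * 2 * 6, sd = 0.05)
  off_true <- c(Cu = -0.1, O = -0.4)
  frames <- list()
  for (k in 1:30) {
    x <- sp$vars$lower + runif(3) * (sp$vars$upper - sp$vars$lower)
    s <- realize_adsorption(probe_atom(), slab, sp, x)
    Phi <- mlip_featurize(s, st)
    pool <- surfbo:::mlip_pool(Phi, s$symbols, c("Cu", "O"), 6)
    s$energy <- sum(pool$v * w_true) + sum(pool$counts * off_true)
    frames[[k]] <- s
  }
  m <- mlip_train(frames, st, split = 0.9, seed = 2)
  expect_lt(m$metrics$train[["energy"]], 1e-6)
  expect_lt(m$metrics$validation[["energy"]], 1e-6)
  # the validation split is disjoint and actually held out
  expect_equal(m$metrics$n_train + m$metrics$n_validation, 30)
  expect_gt(m$metrics$n_validation, 0)
  expect_error(mlip_train(frames[1:5], st), "at least 10")
})

test_that("the learned potential generalizes on toy-backend frames", {
  slab <- small_slab()
  calc <- toy_surface_calculator(slab)
  sp <- adsorption_space(slab, vars = c("tx", "ty", "tz"),
                         tz_bounds = c(1.2, 5))
  set.seed(12)
  frames <- list()
  for (k in 1:60) {
    x <- sp$vars$lower + runif(3) * (sp$vars$upper - sp$vars$lower)
    s <- realize_adsorption(probe_atom(), slab, sp, x)
    ev <- calc$evaluate(s)
    s$energy <- ev$energy; s$forces <- ev$forces
    frames[[k]] <- s
  }
  m <- mlip_train(frames, mlip_settings(), seed = 5)
  expect_lt(m$metrics$validation[["energy"]],
            5 * m$metrics$train[["energy"]] + 1e-6)
  # size consistency: two far-separated copies = twice one copy
  one <- structure_new(c("O", "Cu"), rbind(c(0, 0, 0), c(2.2, 0, 0)))
  two <- structure_new(c("O", "Cu", "O", "Cu"),
                       rbind(c(0, 0, 0), c(2.2, 0, 0),
                             c(50, 0, 0), c(52.2, 0, 0)))
  e1 <- mlip_predict(m, one, forces = FALSE)$energy
  e2 <- mlip_predict(m, two, forces = FALSE)$energy
  expect_equal(e2, 2 * e1, tolerance = 1e-6)
  # analytic forces match central differences of the predicted energy
  mc <- mlip_calculator(m)
  s <- frames[[3]]
  pr <- mlip_predict(m, s)
  Fn <- numeric_forces(mc, s, atoms = 1)
  expect_lt(max(abs(Fn[1, ] - pr$forces[1, ])), 1e-4)
  # JSON round trip preserves predictions
  f <- tempfile(fileext = ".json")
  mlip_to_json(m, f)
  m2 <- mlip_from_json(f)
  expect_equal(mlip_predict(m2, s, forces = FALSE)$energy,
               pr$energy, tolerance = 1e-10)
})

test_that("training-data export writes exactly the sampled, non-capped frames", {
  slab <- small_slab()
  calc <- toy_surface_calculator(slab)
  sp <- adsorption_space(slab, vars = c("tx", "ty", "tz"),
                         tz_bounds = c(1.2, 6))
  obj <- adsorption_objective(probe_atom(), slab, sp, calc)
  st <- bo_settings(n_init = 5, max_iter = 8, stall_limit = 100, seed = 4,
                    augment = TRUE, keep_structures = TRUE,
                    refine_minima = FALSE)
  res <- run_search(obj, st)
  f <- tempfile(fileext = ".xyz")
  n <- export_training_data(res, f)
  expect_equal(n, sum(res$data$provenance == "sampled" &
                        !is.na(res$data$E_raw)))
  frames <- read_xyz(f, simplify = FALSE)
  expect_length(frames, n)
  # lossless numeric round trip of energies and forces
  sel <- which(res$data$provenance == "sampled" & !is.na(res$data$E_raw))
  for (k in seq_along(sel)) {
    expect_equal(frames[[k]]$energy, res$data$E_raw[sel[k]],
                 tolerance = 1e-12)
    expect_lt(max(abs(frames[[k]]$forces - res$forces[[sel[k]]])), 1e-7)
  }
})
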