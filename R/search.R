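# Active-learning structure search: the Bayesian-optimization loop over a
# reduced search space, surface-symmetry data augmentation, harvesting and
# Kabsch-RMSD deduplication of surrogate minima, and the force-seeking mode
# used to curate robust training data for surrogate potentials.

#' Define a search objective
#'
#' Couples a realizer (reduced vector -> structure) with an energy backend.
#'
#' @param realize `function(x) -> list(structure =, ok =)`.
#' @param energy `function(structure) -> list(energy =, forces =)`.
#' @param space the `surfbo_space` being searched.
#' @param reference reference energy (eV) subtracted from backend totals.
#' @param label short name.
#' @return object of class `surfbo_objective`.
#' @export
objective_new <- function(realize, energy, space, reference = 0,
                          label = "objective") {
  obj <- list(realize = realize, energy = energy, space = space,
              reference = reference, label = label)
  class(obj) <- "surfbo_objective"
  obj
}

#' Conformer-search objective
#'
#' @param sugar template plus annotations ([make_sugar()]).
#' @param space a [conformer_space()].
#' @param calc backend calculator.
#' @return a `surfbo_objective`.
#' @export
conformer_objective <- function(sugar, space, calc) {
  objective_new(
    realize = function(x) realize_conformer(sugar, space, x),
    energy = calc$evaluate,
    space = space, reference = calc$reference_energy,
    label = "conformer")
}

#' Rigid-adsorption search objective
#'
#' @param conformer rigid adsorbate building block.
#' @param slab substrate building block ([build_slab()]).
#' @param space an [adsorption_space()].
#' @param calc backend calculator.
#' @param defaults defaults for placement variables absent from the space.
#' @return a `surfbo_objective`.
#' @export
adsorption_objective <- function(conformer, slab, space, calc,
                                 defaults = c(tx = 0, ty = 0, tz = 5,
                                              alpha = 0, beta = 0,
                                              gamma = 0)) {
  objective_new(
    realize = function(x) {
      list(structure = realize_adsorption(conformer, slab, space, x,
                                          defaults),
           ok = TRUE)
    },
    energy = calc$evaluate,
    space = space, reference = calc$reference_energy,
    label = "adsorption")
}

#' Search settings
#'
#' @param n_init number of initial low-discrepancy points.
#' @param max_iter iteration budget after initialization.
#' @param stall_limit terminate once the predicted global-minimum location
#'   has not moved for this many consecutive iterations.
#' @param kappa exploration weight of the lower-confidence-bound
#'   acquisition: either a fixed number or `"elcb"` (default), the growing
#'   GP-UCB schedule `sqrt(2 log(t^(D/2 + 2) pi^2 / (3 delta)))` with
#'   `delta = 0.1`, which keeps exploring multi-basin landscapes instead of
#'   settling into the first deep well.
#' @param seed master seed; every random draw in the run derives from it.
#' @param transform a [transform_settings()].
#' @param noise GP noise variance (eV^2).
#' @param fit_every refit hyperparameters every this many iterations (the
#'   posterior itself is always updated with all data).
#' @param fit_starts multistart count for hyperparameter fits.
#' @param propose_starts acquisition multistart count (default `20 * D`).
#' @param tol_x stall tolerance as a fraction of each variable's range.
#' @param augment apply surface-symmetry augmentation to each sampled
#'   observation (adsorption searches on (111) surfaces).
#' @param aug_rotations include the 3-fold rotation images (valid when the
#'   space carries the azimuthal angle, or the adsorbate is axially
#'   symmetric).
#' @param keep_structures store realized structures and forces (needed for
#'   training-data export).
#' @param refine_minima after the loop terminates, verify the surrogate's
#'   harvested minima by evaluating any that lack a nearby sample and
#'   refitting, while the evaluation budget (`n_init + max_iter`) lasts.
#' @param refine_rounds,refine_k verification rounds and minima per round.
#' @param objective_mode `"energy"` (minimize transformed energy) or
#'   `"force"` (minimize the negative largest force component, the
#'   force-seeking mode).
#' @return settings list.
#' @export
bo_settings <- function(n_init = 5, max_iter = 100, stall_limit = 100,
                        kappa = "elcb", seed = 1,
                        transform = transform_settings(),
                        noise = 1e-6, fit_every = 5, fit_starts = 3,
                        propose_starts = NULL, tol_x = 0.01,
                        augment = FALSE, aug_rotations = TRUE,
                        keep_structures = FALSE,
                        refine_minima = TRUE, refine_rounds = 3,
                        refine_k = 8,
                        objective_mode = c("energy", "force")) {
  list(n_init = n_init, max_iter = max_iter, stall_limit = stall_limit,
       kappa = kappa, seed = seed, transform = transform, noise = noise,
       fit_every = fit_every, fit_starts = fit_starts,
       propose_starts = propose_starts, tol_x = tol_x, augment = augment,
       aug_rotations = aug_rotations, keep_structures = keep_structures,
       refine_minima = refine_minima, refine_rounds = refine_rounds,
       refine_k = refine_k,
       objective_mode = match.arg(objective_mode))
}

#' Surface-symmetry images of an observation
#'
#' Images of a rigid-body placement under the (111) surface symmetry group
#' used for data augmentation: the centring translation `(a/2, b/2)` and the
#' 3-fold rotation about the atop axis at the cell origin, i.e. the group
#' \{identity, t\} x \{C3^0, C3^1, C3^2\}.  Rotations act on `(tx, ty)` and
#' add 120 degrees to the azimuthal Euler angle; all images are wrapped into
#' the search cell and coincident images removed.
#'
#' @param x reduced vector (adsorption-mode).
#' @param space the [adsorption_space()] `x` lives in.
#' @param rotations include the 3-fold rotation images.
#' @param tol coincidence tolerance for collapsing duplicate images.
#' @return matrix of images; the first row is the input itself.
#' @export
augment_symmetry <- function(x, space, rotations = TRUE, tol = 1e-6) {
  v <- space$vars
  ix <- which(v$tag == "translation_x")
  iy <- which(v$tag == "translation_y")
  ig <- which(v$tag == "euler_gamma")
  if (!length(ix) || !length(iy)) return(matrix(x, nrow = 1))
  a <- v$upper[ix] - v$lower[ix]
  b <- v$upper[iy] - v$lower[iy]
  ks <- if (rotations) 0:2 else 0
  out <- list()
  for (k in ks) {
    R <- rot_z(120 * k)[1:2, 1:2]
    for (j in 0:1) {
      xi <- x
      t_xy <- as.numeric(R %*% c(x[ix], x[iy])) +
        j * c(a / 2, b / 2)
      xi[ix] <- wrap_period(t_xy[1], v$lower[ix], a)
      xi[iy] <- wrap_period(t_xy[2], v$lower[iy], b)
      if (length(ig)) xi[ig] <- wrap_period(x[ig] + 120 * k,
                                            v$lower[ig],
                                            v$upper[ig] - v$lower[ig])
      out[[length(out) + 1]] <- xi
    }
  }
  M <- do.call(rbind, out)
  # drop coincident images (periodic-aware), keeping the first occurrence
  keep <- rep(TRUE, nrow(M))
  for (i in seq_len(nrow(M))[-1]) {
    for (j in seq_len(i - 1)) {
      if (keep[j] && all(abs(space_delta(space, M[i, ], M[j, ])) < tol)) {
        keep[i] <- FALSE
        break
      }
    }
  }
  M[keep, , drop = FALSE]
}

# single evaluation of the objective at x, honouring the contact cutoff
evaluate_point <- function(objective, x, ts) {
  r <- objective$realize(x)
  s <- r$structure
  md <- if (!is.null(s) && n_atoms(s) >= 2) min_interatomic_distance(s)
        else Inf
  if (!isTRUE(r$ok) || md < ts$contact_cutoff) {
    return(list(structure = s, E_raw = NA_real_,
                E_trans = ts$cap_energy, min_dist = min(md, 0),
                max_force = NA_real_, forces = NULL,
                provenance = "capped"))
  }
  ev <- tryCatch(objective$energy(s), error = function(e) NULL)
  if (is.null(ev)) {
    return(list(structure = s, E_raw = NA_real_, E_trans = ts$cap_energy,
                min_dist = md, max_force = NA_real_, forces = NULL,
                provenance = "capped"))
  }
  E_rel <- ev$energy - objective$reference
  free <- !s$frozen
  maxf <- if (!is.null(ev$forces)) max(abs(ev$forces[free, ])) else NA_real_
  list(structure = s, E_raw = E_rel,
       E_trans = transform_energy(E_rel, md, ts),
       min_dist = md, max_force = maxf, forces = ev$forces,
       provenance = "sampled")
}

#' Run a Bayesian-optimization structure search
#'
#' Evaluates `n_init` low-discrepancy initial points, then iterates
#' \{fit surrogate, minimize acquisition, realize, evaluate backend,
#' transform, augment\} until the predicted global-minimum location has not
#' moved for `stall_limit` consecutive iterations or the iteration budget is
#' exhausted.  Fully reproducible for a fixed seed.
#'
#' @param objective a `surfbo_objective`.
#' @param settings a [bo_settings()].
#' @return object of class `surfbo_result`: the dataset (`X`, `data`), the
#'   final `model`, the per-iteration predicted-global-minimum `history`,
#'   and the `termination` reason.
#' @export
run_search <- function(objective, settings = bo_settings()) {
  space <- objective$space
  v <- space$vars
  D <- space_dim(space)
  ts <- settings$transform
  force_mode <- settings$objective_mode == "force"
  set.seed(settings$seed)
  U <- lhs::randomLHS(settings$n_init, D)
  X <- matrix(NA_real_, 0, D)
  data <- data.frame(E_raw = numeric(0), E_trans = numeric(0),
                     min_dist = numeric(0), max_force = numeric(0),
                     y = numeric(0), provenance = character(0),
                     iteration = integer(0))
  structures <- list(); forces <- list()

  add_obs <- function(x, ev, iter) {
    y <- if (force_mode) {
      if (is.na(ev$max_force)) 0 else -ev$max_force
    } else ev$E_trans
    rows <- matrix(x, nrow = 1)
    provs <- ev$provenance
    if (settings$augment && space$kind == "adsorption") {
      M <- augment_symmetry(x, space, rotations = settings$aug_rotations)
      if (nrow(M) > 1) {
        rows <- rbind(rows, M[-1, , drop = FALSE])
        provs <- c(provs, rep("augmented", nrow(M) - 1))
      }
    }
    for (r in seq_len(nrow(rows))) {
      X <<- rbind(X, rows[r, ])
      data <<- rbind(data, data.frame(
        E_raw = ev$E_raw, E_trans = ev$E_trans, min_dist = ev$min_dist,
        max_force = ev$max_force, y = y, provenance = provs[r],
        iteration = as.integer(iter), stringsAsFactors = FALSE))
      structures[nrow(data)] <<- list(
        if (settings$keep_structures && r == 1) ev$structure else NULL)
      forces[nrow(data)] <<- list(
        if (settings$keep_structures && r == 1) ev$forces else NULL)
    }
  }

  for (i in seq_len(settings$n_init)) {
    x <- as.numeric(v$lower + U[i, ] * (v$upper - v$lower))
    add_obs(x, evaluate_point(objective, x, ts), 0L)
  }

  model <- NULL
  history <- matrix(NA_real_, 0, D)
  hist_E <- numeric(0)
  stall <- 0L
  termination <- "max_iter"
  prev_arg <- NULL
  for (t in seq_len(settings$max_iter)) {
    if (is.null(model) || (t - 1) %% settings$fit_every == 0) {
      model <- gp_fit(X, data$y, space, noise = settings$noise,
                      n_starts = settings$fit_starts,
                      seed = settings$seed + 1000 + t)
    } else {
      model <- gp_refresh(model, X, data$y)
    }
    kappa_t <- if (identical(settings$kappa, "elcb")) {
      sqrt(2 * log(t^(D / 2 + 2) * pi^2 / (3 * 0.1)))
    } else settings$kappa
    x_next <- gp_propose_next(model, space, kappa = kappa_t,
                              seed = settings$seed + 2000 + t,
                              n_starts = settings$propose_starts)
    add_obs(x_next, evaluate_point(objective, x_next, ts), t)
    model <- gp_refresh(model, X, data$y)
    extra <- list(X[which.min(data$y), ])
    if (!is.null(prev_arg)) extra <- c(extra, list(prev_arg))
    am <- gp_posterior_argmin(model, space,
                              seed = settings$seed + 3000 + t,
                              n_starts = 5L * D, extra = extra)
    history <- rbind(history, am$x)
    hist_E <- c(hist_E, am$value)
    if (!is.null(prev_arg)) {
      moved <- abs(space_delta(space, am$x, prev_arg)) >
        settings$tol_x * (v$upper - v$lower)
      stall <- if (any(moved)) 0L else stall + 1L
      if (stall >= settings$stall_limit) {
        termination <- "stalled"
        prev_arg <- am$x
        break
      }
    }
    prev_arg <- am$x
  }
  # minima-verification phase: evaluate surrogate minima that lack a nearby
  # sample, within the remaining evaluation budget, and refit
  if (isTRUE(settings$refine_minima)) {
    budget <- settings$n_init + settings$max_iter
    used <- sum(data$provenance != "augmented")
    iter_ref <- settings$max_iter
    for (round in seq_len(settings$refine_rounds)) {
      if (used >= budget) break
      model <- gp_refresh(model, X, data$y)
      mins <- harvest_minima(model, space, n_starts = 30L * D,
                             seed = settings$seed + 4000 + round)
      mins <- mins[seq_len(min(length(mins), settings$refine_k))]
      newpts <- 0L
      for (mn in mins) {
        if (used >= budget) break
        rel <- t(apply(X, 1, function(r)
          abs(space_delta(space, mn$x, r)) / (v$upper - v$lower)))
        if (min(apply(rel, 1, max)) > 0.005) {
          iter_ref <- iter_ref + 1L
          add_obs(mn$x, evaluate_point(objective, mn$x, ts), iter_ref)
          used <- used + 1L
          newpts <- newpts + 1L
        }
      }
      if (newpts == 0L) break
    }
  }
  model <- gp_fit(X, data$y, space, noise = settings$noise,
                  n_starts = settings$fit_starts,
                  seed = settings$seed + 999)
  res <- list(X = X, data = data, model = model, space = space,
              history = history, history_E = hist_E,
              termination = termination, settings = settings,
              structures = structures, forces = forces,
              objective = objective)
  class(res) <- "surfbo_result"
  res
}

# recondition an existing fit on an enlarged dataset without re-optimizing
# hyperparameters
gp_refresh <- function(model, X, y) {
  n <- nrow(X)
  feats <- dim_features(X, X, model$periodic, model$period)
  K <- kernel_from_features(feats, model$periodic, model$sf2, model$ls) +
    model$noise * diag(n)
  cj <- chol_jitter(K)
  m0 <- mean(y)
  alpha <- chol_solve_refined(cj$L, K, y - m0)
  model$X <- X; model$y <- y; model$prior_mean <- m0
  model$L <- cj$L; model$alpha <- alpha; model$jitter <- cj$jitter
  model
}

#' @export
print.surfbo_result <- function(x, ...) {
  cat(sprintf(paste0("<surfbo_result: %d observations (%d sampled, ",
                     "%d augmented, %d capped), %s>\n"),
              nrow(x$X), sum(x$data$provenance == "sampled"),
              sum(x$data$provenance == "augmented"),
              sum(x$data$provenance == "capped"), x$termination))
  invisible(x)
}

#' Run a force-seeking search
#'
#' The identical active-learning loop, but the objective handed to the
#' surrogate is the negative largest force component instead of the energy:
#' proposals drift toward high-force regions of the landscape, enriching a
#' training set for surrogate potentials.  Contact-capped points carry no
#' forces and enter the surrogate at objective value zero.
#'
#' @param objective a `surfbo_objective` whose backend provides forces.
#' @param settings a [bo_settings()]; `objective_mode` is forced to
#'   `"force"`.
#' @return a `surfbo_result`.
#' @export
run_force_seeking <- function(objective, settings = bo_settings()) {
  settings$objective_mode <- "force"
  run_search(objective, settings)
}

#' Harvest local minima of the surrogate landscape
#'
#' Multistart local minimization of the posterior mean (default `100 * D`
#' low-discrepancy starts), clustering of the converged points
#' (periodic-aware), and ranking of cluster representatives by predicted
#' energy.
#'
#' @param model a fitted `surfbo_gp`.
#' @param space the search space.
#' @param n_starts number of descent starts.
#' @param seed RNG seed for the starts.
#' @param cluster_tol cluster radius as a fraction of each variable's range.
#' @param below_prior optionally keep only minima predicted below the GP
#'   prior mean (off by default: with heavily sampled basins the data mean
#'   can lie below genuinely shallow minima).
#' @param max_minima cap on the number of representatives returned, lowest
#'   predicted energies first (sparse high-dimensional surrogates exhibit
#'   many shallow micro-basins; only the lowest few are ever relaxed).
#' @return list of local minima, each `list(x, E_pred, rank)`, sorted by
#'   predicted energy.
#' @export
harvest_minima <- function(model, space, n_starts = NULL, seed = 1,
                           cluster_tol = 0.05, below_prior = FALSE,
                           max_minima = 20) {
  D <- space_dim(space)
  if (is.null(n_starts)) n_starts <- 100L * D
  v <- space$vars
  res <- multistart_minimize(function(x) acq_value_grad(model, x, 0)$value,
                             space, n_starts, seed = seed,
                             return_all = TRUE,
                             grad = function(x)
                               acq_value_grad(model, x, 0)$grad)
  ord <- order(vapply(res, `[[`, 0, "value"))
  if (below_prior) {
    ord <- ord[vapply(res[ord], `[[`, 0, "value") < model$prior_mean]
  }
  reps <- list()
  tolv <- cluster_tol * (v$upper - v$lower)
  for (i in ord) {
    if (length(reps) >= max_minima) break
    x <- res[[i]]$x
    dup <- FALSE
    for (r in reps) {
      if (all(abs(space_delta(space, x, r$x)) < tolv)) { dup <- TRUE; break }
    }
    if (!dup) reps[[length(reps) + 1]] <- list(x = x,
                                               E_pred = res[[i]]$value)
  }
  for (i in seq_along(reps)) reps[[i]]$rank <- i
  reps
}

#' Kabsch RMSD between two structures
#'
#' Minimum root-mean-square deviation over all proper rotations and
#' translations (Kabsch superposition).  Structures must have the same atom
#' count and element multiset in consistent order.
#'
#' @param A,B structures.
#' @param atoms optional atom subset used for both superposition and RMSD.
#' @return RMSD in Angstrom.
#' @export
kabsch_rmsd <- function(A, B, atoms = NULL) {
  if (n_atoms(A) != n_atoms(B))
    stop("structures differ in atom count")
  if (!identical(sort(A$symbols), sort(B$symbols)))
    stop("structures differ in composition")
  if (!all(A$symbols == B$symbols))
    stop("atom ordering differs between structures")
  if (is.null(atoms)) atoms <- seq_len(n_atoms(A))
  kabsch(A$positions[atoms, , drop = FALSE],
         B$positions[atoms, , drop = FALSE])$rmsd
}

#' RMSD between two adsorption configurations
#'
#' Superposes the full systems (the shared substrate pins the frame) and
#' reports the RMSD over adsorbate atoms, so the value reflects the
#' adsorbate displacement rather than being diluted by identical slab atoms.
#'
#' @param A,B adsorbate+slab structures with matching atom order.
#' @return RMSD over adsorbate atoms (Angstrom).
#' @export
adsorption_rmsd <- function(A, B) {
  k <- kabsch(A$positions, B$positions)
  P <- sweep(sweep(A$positions, 2, k$center_P) %*% t(k$R), 2,
             k$center_Q, "+")
  ads <- which(A$tags == "adsorbate")
  sqrt(mean(rowSums((P[ads, , drop = FALSE] -
                       B$positions[ads, , drop = FALSE])^2)))
}

#' Deduplicate harvested minima by structural RMSD
#'
#' Greedy pass in order of increasing predicted energy: a minimum is dropped
#' when its RMSD to any already-kept minimum falls below the threshold.
#' When `images_fn` is supplied (symmetry-equivalent images of a minimum,
#' e.g. from [augment_symmetry()]), the RMSD to a kept minimum is the
#' minimum over its images, so symmetry-equivalent copies collapse to one
#' representative.
#'
#' @param minima list of minima each carrying `structure` (and optionally
#'   `E_pred`).
#' @param threshold RMSD threshold in Angstrom (default 0.3).
#' @param rmsd_fn pairwise RMSD function (default [kabsch_rmsd()];
#'   use [adsorption_rmsd()] for adsorbate+slab systems).
#' @param images_fn optional `function(minimum) -> list of structures`.
#' @return the kept minima, re-ranked.
#' @export
deduplicate <- function(minima, threshold = 0.3, rmsd_fn = kabsch_rmsd,
                        images_fn = NULL) {
  if (!length(minima)) return(minima)
  Ep <- vapply(minima, function(m)
    if (!is.null(m$E_pred)) m$E_pred else NA_real_, 0)
  ord <- if (all(is.na(Ep))) seq_along(minima) else order(Ep)
  kept <- list()
  for (i in ord) {
    mi <- minima[[i]]
    dup <- FALSE
    for (km in kept) {
      imgs <- if (is.null(images_fn)) list(km$structure)
              else images_fn(km)
      d <- min(vapply(imgs, function(s) rmsd_fn(mi$structure, s), 0))
      if (d < threshold) { dup <- TRUE; break }
    }
    if (!dup) kept[[length(kept) + 1]] <- mi
  }
  for (i in seq_along(kept)) kept[[i]]$rank <- i
  kept
}

#' Realize harvested minima as structures
#'
#' @param objective the search objective (provides the realizer).
#' @param minima list from [harvest_minima()].
#' @return the minima with `structure` fields attached.
#' @export
realize_minima <- function(objective, minima) {
  lapply(minima, function(m) {
    r <- objective$realize(m$x)
    m$structure <- r$structure
    m$realized_ok <- r$ok
    m
  })
}

#' Symmetry-image generator for adsorption minima
#'
#' Returns a function mapping a minimum (with reduced vector `x`) to the
#' list of its realized symmetry images under the augmentation group, for
#' use as `images_fn` in [deduplicate()].
#'
#' @param objective an adsorption objective.
#' @param rotations include 3-fold rotation images.
#' @return `function(minimum) -> list of structures`.
#' @export
adsorption_images <- function(objective, rotations = TRUE) {
  function(minimum) {
    M <- augment_symmetry(minimum$x, objective$space, rotations = rotations)
    lapply(seq_len(nrow(M)), function(r)
      objective$realize(M[r, ])$structure)
  }
}
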