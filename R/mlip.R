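# Lightweight learned surrogate potential: per-atom Gaussian radial
# descriptors with a smooth cutoff, linear ridge regression of per-atom
# energy contributions with a joint energy + force objective.  This is the
# desk-scale stage of the workflow that turns search-generated data into a
# cheap calculator for a second search pass; a full equivariant-network
# potential can be plugged in through the same calculator contract.

#' Surrogate-potential descriptor and training settings
#'
#' @param cutoff radial interaction cutoff (Angstrom, default 3.5).
#' @param n_basis number of Gaussian basis centers per element channel.
#' @param sigma Gaussian width (Angstrom); default spaces the basis to
#'   overlap (`cutoff / n_basis`).
#' @param elements element channels; default taken from the training data.
#' @param lambda ridge regularization strength.
#' @param force_weight relative weight of the force loss (1 = the energy
#'   and force mean losses enter 1:1).
#' @param force_atoms which atoms contribute force rows: `"adsorbate"`
#'   (default; substrate is rigid in the toy model) or `"all"`.
#' @return settings list.
#' @export
mlip_settings <- function(cutoff = 3.5, n_basis = 8, sigma = NULL,
                          elements = NULL, lambda = 1e-6,
                          force_weight = 1, force_atoms = "adsorbate") {
  if (is.null(sigma)) sigma <- cutoff / n_basis
  list(cutoff = cutoff, n_basis = n_basis, sigma = sigma,
       elements = elements, lambda = lambda, force_weight = force_weight,
       force_atoms = force_atoms)
}

# C1 polynomial switching function and derivative: 1 at r=0, 0 at cutoff
fcut <- function(r, rc) {
  u <- r / rc
  ifelse(u < 1, 1 - 3 * u^2 + 2 * u^3, 0)
}
fcut_d <- function(r, rc) {
  u <- r / rc
  ifelse(u < 1, (-6 * u + 6 * u^2) / rc, 0)
}

# neighbour list under minimum image (orthogonal cells): returns i, j, r and
# displacement components for all pairs with r < cutoff
neighbour_pairs <- function(s, cutoff) {
  n <- n_atoms(s)
  P <- s$positions
  L <- sqrt(rowSums(s$cell^2))
  out_i <- integer(0); out_j <- integer(0)
  out_r <- numeric(0); out_D <- matrix(0, 0, 3)
  for (i in seq_len(n - 1L)) {
    D <- sweep(P[(i + 1L):n, , drop = FALSE], 2, P[i, ])
    for (k in which(s$pbc)) D[, k] <- D[, k] - round(D[, k] / L[k]) * L[k]
    r <- sqrt(rowSums(D * D))
    sel <- which(r < cutoff & r > 1e-8)
    if (length(sel)) {
      out_i <- c(out_i, rep(i, length(sel)))
      out_j <- c(out_j, i + sel)
      out_r <- c(out_r, r[sel])
      out_D <- rbind(out_D, D[sel, , drop = FALSE])
    }
  }
  list(i = out_i, j = out_j, r = out_r, D = out_D)
}

#' Per-atom radial descriptor features
#'
#' Gaussian-smeared radial distribution per neighbour-element channel within
#' the cutoff, smoothly switched off at the cutoff (C1), minimum-image
#' aware.  Invariant under rigid rotation, translation, and permutation of
#' atoms within an element.
#'
#' @param s a structure.
#' @param settings a [mlip_settings()] (with `elements` resolved).
#' @return N x (n_elements * n_basis) feature matrix.
#' @export
mlip_featurize <- function(s, settings) {
  elements <- settings$elements
  if (is.null(elements)) elements <- sort(unique(s$symbols))
  nb <- settings$n_basis
  mu <- seq(0, settings$cutoff, length.out = nb)
  n <- n_atoms(s)
  Phi <- matrix(0, n, length(elements) * nb)
  np <- neighbour_pairs(s, settings$cutoff)
  if (length(np$i)) {
    for (p in seq_along(np$i)) {
      i <- np$i[p]; j <- np$j[p]; r <- np$r[p]
      g <- exp(-(r - mu)^2 / (2 * settings$sigma^2)) *
        fcut(r, settings$cutoff)
      ci <- match(s$symbols[j], elements)
      cj <- match(s$symbols[i], elements)
      if (!is.na(ci))
        Phi[i, (ci - 1) * nb + seq_len(nb)] <-
          Phi[i, (ci - 1) * nb + seq_len(nb)] + g
      if (!is.na(cj))
        Phi[j, (cj - 1) * nb + seq_len(nb)] <-
          Phi[j, (cj - 1) * nb + seq_len(nb)] + g
    }
  }
  Phi
}

# gradient rows of the energy design vector: for one frame, returns the
# 3N x P matrix dPhi_sum/dR where Phi_sum pools per-atom features into the
# per-element weight blocks (used to build force rows, linear in weights)
mlip_design_grad <- function(s, settings, elements, atoms) {
  nb <- settings$n_basis
  mu <- seq(0, settings$cutoff, length.out = nb)
  P_dim <- length(elements) * (length(elements) * nb)
  np <- neighbour_pairs(s, settings$cutoff)
  G <- array(0, dim = c(length(atoms), 3, P_dim))
  amap <- match(seq_len(n_atoms(s)), atoms)
  blk <- function(ei, ej) ((ei - 1) * length(elements) + (ej - 1)) * nb
  if (length(np$i)) {
    for (p in seq_along(np$i)) {
      i <- np$i[p]; j <- np$j[p]; r <- np$r[p]
      u <- np$D[p, ] / r            # unit vector from i to j
      gauss <- exp(-(r - mu)^2 / (2 * settings$sigma^2))
      dg <- gauss * (-(r - mu) / settings$sigma^2) *
        fcut(r, settings$cutoff) +
        gauss * fcut_d(r, settings$cutoff)
      ei <- match(s$symbols[i], elements)
      ej <- match(s$symbols[j], elements)
      # feature of atom i (channel ej) and atom j (channel ei) both depend
      # on r; dr/dR_j = u, dr/dR_i = -u
      cols_i <- blk(ei, ej) + seq_len(nb)
      cols_j <- blk(ej, ei) + seq_len(nb)
      for (aa in c(i, j)) {
        ai <- amap[aa]
        if (is.na(ai)) next
        sgn <- if (aa == i) -1 else 1
        for (kk in 1:3) {
          G[ai, kk, cols_i] <- G[ai, kk, cols_i] + sgn * u[kk] * dg
          G[ai, kk, cols_j] <- G[ai, kk, cols_j] + sgn * u[kk] * dg
        }
      }
    }
  }
  G
}

# pool per-atom features into per-element weight blocks: one long vector
# per frame, ordered (element block) x (channel x basis), plus per-element
# atom counts for the offsets
mlip_pool <- function(Phi, symbols, elements, nb) {
  P <- length(elements) * length(elements) * nb
  v <- numeric(P)
  counts <- numeric(length(elements))
  for (ei in seq_along(elements)) {
    rows <- which(symbols == elements[ei])
    counts[ei] <- length(rows)
    if (!length(rows)) next
    block <- ((ei - 1) * length(elements) * nb) + seq_len(length(elements) * nb)
    v[block] <- colSums(Phi[rows, , drop = FALSE])
  }
  list(v = v, counts = counts)
}

#' Train the surrogate potential
#'
#' Linear ridge regression of per-atom energy contributions on the radial
#' descriptors, with per-element energy offsets and a joint
#' energy-plus-force objective (least squares; the energy and force mean
#' losses are weighted 1:1 by default).  The frame set is split into
#' training and validation (90/10 by frame, seeded); mean absolute errors
#' are reported for both.
#'
#' @param frames list of structures, each with `energy` (eV) and, where
#'   available, `forces` attached.
#' @param settings a [mlip_settings()].
#' @param split training fraction of the frame split.
#' @param seed RNG seed for the split.
#' @return object of class `surfbo_mlip` with fields `weights`, `offsets`,
#'   `settings`, `elements` and `metrics`.
#' @export
mlip_train <- function(frames, settings = mlip_settings(), split = 0.9,
                       seed = 1) {
  if (length(frames) < 10)
    stop("need at least 10 training frames")
  elements <- settings$elements
  if (is.null(elements))
    elements <- sort(unique(unlist(lapply(frames, `[[`, "symbols"))))
  settings$elements <- elements
  nb <- settings$n_basis
  P <- length(elements) * length(elements) * nb
  nf <- length(frames)
  set.seed(seed)
  idx_train <- sort(sample(nf, max(2, floor(split * nf))))
  idx_val <- setdiff(seq_len(nf), idx_train)

  build_rows <- function(ids, with_forces = TRUE) {
    A <- list(); b <- list(); kind <- list()
    for (fi in ids) {
      fr <- frames[[fi]]
      Phi <- mlip_featurize(fr, settings)
      pool <- mlip_pool(Phi, fr$symbols, elements, nb)
      nat <- n_atoms(fr)
      A[[length(A) + 1]] <- c(pool$v, pool$counts) / nat
      b[[length(b) + 1]] <- fr$energy / nat
      kind[[length(kind) + 1]] <- "E"
      if (with_forces && !is.null(fr$forces)) {
        atoms <- if (settings$force_atoms == "adsorbate" &&
                     any(fr$tags == "adsorbate"))
          which(fr$tags == "adsorbate") else seq_len(nat)
        G <- mlip_design_grad(fr, settings, elements, atoms)
        for (ai in seq_along(atoms)) for (kk in 1:3) {
          A[[length(A) + 1]] <- c(-G[ai, kk, ], numeric(length(elements)))
          b[[length(b) + 1]] <- fr$forces[atoms[ai], kk]
          kind[[length(kind) + 1]] <- "F"
        }
      }
    }
    list(A = do.call(rbind, A), b = unlist(b), kind = unlist(kind))
  }

  tr <- build_rows(idx_train)
  isE <- tr$kind == "E"
  wE <- 1 / max(1, sum(isE))
  wF <- settings$force_weight / max(1, sum(!isE))
  w <- ifelse(isE, sqrt(wE), sqrt(wF))
  Aw <- tr$A * w
  bw <- tr$b * w
  M <- crossprod(Aw) + settings$lambda * diag(ncol(Aw))
  theta <- solve(M, crossprod(Aw, bw))
  model <- list(weights = theta[seq_len(P)],
                offsets = theta[P + seq_along(elements)],
                elements = elements, settings = settings)
  class(model) <- "surfbo_mlip"

  mae <- function(ids) {
    if (!length(ids)) return(c(energy = NA_real_, force = NA_real_))
    eerr <- c(); ferr <- c()
    for (fi in ids) {
      fr <- frames[[fi]]
      pr <- mlip_predict(model, fr)
      eerr <- c(eerr, abs(pr$energy - fr$energy) / n_atoms(fr))
      if (!is.null(fr$forces)) {
        atoms <- if (settings$force_atoms == "adsorbate" &&
                     any(fr$tags == "adsorbate"))
          which(fr$tags == "adsorbate") else seq_len(n_atoms(fr))
        ferr <- c(ferr, abs(pr$forces[atoms, ] -
                              fr$forces[atoms, , drop = FALSE]))
      }
    }
    c(energy = mean(eerr),
      force = if (length(ferr)) mean(ferr) else NA_real_)
  }
  model$metrics <- list(train = mae(idx_train), validation = mae(idx_val),
                        n_train = length(idx_train),
                        n_validation = length(idx_val))
  model
}

#' @export
print.surfbo_mlip <- function(x, ...) {
  cat(sprintf(paste0("<surfbo_mlip: %d channels x %d basis | train MAE ",
                     "%.4g eV/atom, %.4g eV/A | val MAE %.4g eV/atom>\n"),
              length(x$elements), x$settings$n_basis,
              x$metrics$train[["energy"]], x$metrics$train[["force"]],
              x$metrics$validation[["energy"]]))
  invisible(x)
}

#' Predict energy and forces with the surrogate potential
#'
#' @param model a `surfbo_mlip`.
#' @param s a structure.
#' @param forces also compute forces (analytic).
#' @return list with `energy` (eV) and `forces` (N x 3).
#' @export
mlip_predict <- function(model, s, forces = TRUE) {
  st <- model$settings
  nb <- st$n_basis
  Phi <- mlip_featurize(s, st)
  pool <- mlip_pool(Phi, s$symbols, model$elements, nb)
  E <- sum(pool$v * model$weights) + sum(pool$counts * model$offsets)
  Fm <- NULL
  if (forces) {
    atoms <- seq_len(n_atoms(s))
    G <- mlip_design_grad(s, st, model$elements, atoms)
    Fm <- matrix(0, n_atoms(s), 3)
    for (kk in 1:3) Fm[, kk] <- -G[, kk, ] %*% model$weights
  }
  list(energy = E, forces = Fm)
}

#' Wrap a trained surrogate potential as a calculator
#'
#' @param model a `surfbo_mlip`.
#' @param reference_energy reference zero (eV) for relative energies.
#' @return a `surfbo_calculator`.
#' @export
mlip_calculator <- function(model, reference_energy = 0) {
  calculator_new(function(s) mlip_predict(model, s),
                 reference_energy, "mlip-lite")
}

#' Export search data as a training archive
#'
#' Writes one extended-XYZ frame per sampled, non-capped observation of a
#' search result, with energies and forces attached: the training archive
#' for surrogate-potential fitting (lossless numeric round trip through
#' [read_xyz()]).
#'
#' @param result a `surfbo_result` run with `keep_structures = TRUE`.
#' @param path output file.
#' @param raw write raw backend energies (default) rather than transformed.
#' @return number of frames written, invisibly.
#' @export
export_training_data <- function(result, path, raw = TRUE) {
  sel <- which(result$data$provenance == "sampled" &
                 !is.na(result$data$E_raw))
  frames <- list()
  for (k in sel) {
    s <- result$structures[[k]]
    if (is.null(s)) next
    s$energy <- if (raw) result$data$E_raw[k] else result$data$E_trans[k]
    s$forces <- result$forces[[k]]
    frames[[length(frames) + 1]] <- s
  }
  if (!length(frames))
    stop("no stored structures: run the search with keep_structures = TRUE")
  write_xyz(frames, path)
  invisible(length(frames))
}

#' Serialize a surrogate-potential model to JSON
#'
#' @param model a `surfbo_mlip`.
#' @param path output file.
#' @return the path, invisibly.
#' @export
mlip_to_json <- function(model, path) {
  obj <- list(kind = "surfbo_mlip",
              elements = model$elements,
              cutoff = model$settings$cutoff,
              n_basis = model$settings$n_basis,
              sigma = model$settings$sigma,
              weights = model$weights,
              offsets = model$offsets,
              metrics = model$metrics)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load a surrogate-potential model from JSON
#' @param path JSON file written by [mlip_to_json()].
#' @return a `surfbo_mlip`.
#' @export
mlip_from_json <- function(path) {
  o <- jsonlite::read_json(path, simplifyVector = TRUE)
  st <- mlip_settings(cutoff = o$cutoff, n_basis = o$n_basis,
                      sigma = o$sigma, elements = o$elements)
  model <- list(weights = as.numeric(o$weights),
                offsets = as.numeric(o$offsets),
                elements = o$elements, settings = st,
                metrics = o$metrics)
  class(model) <- "surfbo_mlip"
  model
}
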