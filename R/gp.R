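# Gaussian-process surrogate over a search space: product kernel of
# squared-exponential (non-periodic dimensions) and standard periodic
# (periodic dimensions) components, hyperparameters by maximizing the log
# marginal likelihood with analytic gradients, lower-confidence-bound
# acquisition for active sampling.

# per-dimension distance features between rows of X1 and X2:
# squared differences for SE dims, sin^2(pi d / p) for periodic dims
dim_features <- function(X1, X2, periodic, period) {
  D <- ncol(X1)
  out <- vector("list", D)
  for (k in seq_len(D)) {
    d <- outer(X1[, k], X2[, k], "-")
    if (periodic[k]) {
      out[[k]] <- sin(pi * d / period[k])^2
    } else {
      out[[k]] <- d^2
    }
  }
  out
}

kernel_from_features <- function(feats, periodic, sf2, ls) {
  expo <- 0
  for (k in seq_along(feats)) {
    expo <- expo - (if (periodic[k]) 2 else 0.5) * feats[[k]] / ls[k]^2
  }
  sf2 * exp(expo)
}

# solve K x = b via Cholesky with two steps of iterative refinement, which
# recovers interpolation accuracy when K is ill-conditioned (tiny noise)
chol_solve_refined <- function(L, K, b) {
  x <- backsolve(L, forwardsolve(t(L), b))
  for (it in 1:2) {
    r <- b - K %*% x
    x <- x + backsolve(L, forwardsolve(t(L), r))
  }
  as.numeric(x)
}

chol_jitter <- function(K) {
  scale <- mean(diag(K))
  for (j in c(0, 1e-10, 1e-8, 1e-6, 1e-4)) {
    L <- tryCatch(chol(K + j * scale * diag(nrow(K))), error = function(e) NULL)
    if (!is.null(L)) return(list(L = L, jitter = j * scale))
  }
  stop("kernel matrix is numerically singular even with jitter")
}

#' Fit a Gaussian-process surrogate
#'
#' Product kernel over dimensions (squared-exponential for bounded,
#' standard-periodic for periodic variables) with signal variance, one
#' lengthscale per dimension, and optional noise variance, all chosen by
#' multistart bounded maximization of the log marginal likelihood with
#' analytic gradients.  The prior mean is the mean of the observations.
#'
#' @param X n x D matrix of inputs.
#' @param y numeric response (transformed energies, eV).
#' @param space the `surfbo_space` the inputs live in (bounds and
#'   periodicity).
#' @param noise fixed noise variance (eV^2) unless `optimize_noise`.
#' @param optimize_noise also optimize the noise variance.
#' @param n_starts number of multistart optimizations.
#' @param seed RNG seed for the start points.
#' @param max_opt_iter optimizer iteration cap per start.
#' @return object of class `surfbo_gp`.
#' @export
gp_fit <- function(X, y, space, noise = 1e-8, optimize_noise = FALSE,
                   n_starts = 3, seed = 1, max_opt_iter = 60) {
  X <- as.matrix(X)
  n <- nrow(X); D <- ncol(X)
  if (n < 2) stop("need at least two observations to fit a GP")
  v <- space$vars
  stopifnot(D == nrow(v))
  periodic <- v$periodic
  period <- v$upper - v$lower
  range_d <- v$upper - v$lower
  m0 <- mean(y)
  yc <- y - m0
  sd_y <- stats::sd(yc)
  if (!is.finite(sd_y) || sd_y < 1e-12) sd_y <- 1e-6
  feats <- dim_features(X, X, periodic, period)

  neg_lml <- function(theta, want_grad = FALSE) {
    sf2 <- exp(theta[1])
    ls <- exp(theta[1 + seq_len(D)])
    nz <- if (optimize_noise) exp(theta[D + 2]) else noise
    Kf <- kernel_from_features(feats, periodic, sf2, ls)
    K <- Kf + nz * diag(n)
    cj <- tryCatch(chol_jitter(K), error = function(e) NULL)
    if (is.null(cj)) return(list(value = 1e10, grad = rep(0, length(theta))))
    L <- cj$L
    alpha <- backsolve(L, forwardsolve(t(L), yc))
    val <- 0.5 * sum(yc * alpha) + sum(log(diag(L))) + 0.5 * n * log(2 * pi)
    if (!want_grad) return(list(value = val))
    Kinv <- chol2inv(L)
    W <- alpha %*% t(alpha) - Kinv      # d(lml)/dK = 0.5 * W
    g <- numeric(length(theta))
    g[1] <- -0.5 * sum(W * Kf)
    for (k in seq_len(D)) {
      fac <- (if (periodic[k]) 4 else 1) * feats[[k]] / ls[k]^2
      g[1 + k] <- -0.5 * sum(W * (Kf * fac))
    }
    if (optimize_noise) g[D + 2] <- -0.5 * sum(diag(W)) * nz
    list(value = val, grad = g)
  }
  fn <- function(th) neg_lml(th)$value
  gr <- function(th) neg_lml(th, want_grad = TRUE)$grad

  ls_lo <- log(pmax(0.02 * range_d, 1e-6))
  ls_hi <- log(2 * range_d)
  lower <- c(log(sd_y^2) - 9, ls_lo)
  upper <- c(log(sd_y^2) + 6, ls_hi)
  if (optimize_noise) {
    lower <- c(lower, log(1e-10))
    upper <- c(upper, log(sd_y^2 + 1e-12))
  }
  set.seed(seed)
  starts <- list(c(log(sd_y^2), log(0.2 * range_d),
                   if (optimize_noise) log(noise + 1e-10)))
  if (n_starts > 1) {
    U <- lhs::randomLHS(n_starts - 1, length(lower))
    for (i in seq_len(n_starts - 1)) {
      starts[[i + 1]] <- lower + U[i, ] * (upper - lower)
    }
  }
  best <- NULL
  for (st in starts) {
    fit <- tryCatch(
      stats::optim(pmin(pmax(st, lower), upper), fn, gr, method = "L-BFGS-B",
                   lower = lower, upper = upper,
                   control = list(maxit = max_opt_iter)),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$value < best$value)) best <- fit
  }
  if (is.null(best)) stop("hyperparameter optimization failed")
  th <- best$par
  sf2 <- exp(th[1]); ls <- exp(th[1 + seq_len(D)])
  nz <- if (optimize_noise) exp(th[D + 2]) else noise
  K <- kernel_from_features(feats, periodic, sf2, ls) + nz * diag(n)
  cj <- chol_jitter(K)
  alpha <- chol_solve_refined(cj$L, K, yc)
  model <- list(X = X, y = y, prior_mean = m0, sf2 = sf2, ls = ls,
                noise = nz, jitter = cj$jitter, L = cj$L, alpha = alpha,
                lml = -best$value, periodic = periodic, period = period,
                vars = v)
  class(model) <- "surfbo_gp"
  model
}

#' @export
print.surfbo_gp <- function(x, ...) {
  cat(sprintf("<surfbo_gp: n=%d D=%d sf=%.4g ls=[%s] noise=%.3g lml=%.3f>\n",
              nrow(x$X), ncol(x$X), sqrt(x$sf2),
              paste(signif(x$ls, 3), collapse = ", "),
              x$noise, x$lml))
  invisible(x)
}

#' Log marginal likelihood of a fitted model at arbitrary hyperparameters
#'
#' Utility for likelihood-surface checks: evaluates the log marginal
#' likelihood of the model's training data under the given hyperparameters.
#'
#' @param model a `surfbo_gp`.
#' @param sf2,ls,noise hyperparameters to evaluate at (defaults: fitted).
#' @return scalar log marginal likelihood.
#' @export
gp_lml <- function(model, sf2 = model$sf2, ls = model$ls,
                   noise = model$noise) {
  n <- nrow(model$X)
  feats <- dim_features(model$X, model$X, model$periodic, model$period)
  K <- kernel_from_features(feats, model$periodic, sf2, ls) + noise * diag(n)
  cj <- chol_jitter(K)
  yc <- model$y - model$prior_mean
  alpha <- backsolve(cj$L, forwardsolve(t(cj$L), yc))
  -0.5 * sum(yc * alpha) - sum(log(diag(cj$L))) - 0.5 * n * log(2 * pi)
}

#' GP posterior mean and standard deviation
#'
#' @param model a `surfbo_gp`.
#' @param Xstar query point (vector) or matrix of query points (rows).
#' @return list with `mean` and `sd` vectors (latent function, without
#'   observation noise).
#' @export
gp_posterior <- function(model, Xstar) {
  if (is.null(dim(Xstar))) Xstar <- matrix(Xstar, nrow = 1)
  Xstar <- as.matrix(Xstar)
  feats <- dim_features(Xstar, model$X, model$periodic, model$period)
  Ks <- kernel_from_features(feats, model$periodic, model$sf2, model$ls)
  mu <- model$prior_mean + as.numeric(Ks %*% model$alpha)
  Vh <- forwardsolve(t(model$L), t(Ks))
  var <- pmax(model$sf2 - colSums(Vh^2), 0)
  list(mean = mu, sd = sqrt(var))
}

#' Lower-confidence-bound acquisition
#'
#' `mean - kappa * sd`: the exploratory acquisition minimized to choose the
#' next configuration to evaluate.
#'
#' @param model a `surfbo_gp`.
#' @param x query point or matrix.
#' @param kappa exploration weight (>= 0).
#' @return acquisition values.
#' @export
gp_acquisition <- function(model, x, kappa = 2) {
  p <- gp_posterior(model, x)
  p$mean - kappa * p$sd
}

# posterior mean/sd and the acquisition with analytic gradients at a single
# point; used to drive the bounded local optimizers efficiently
acq_value_grad <- function(model, x, kappa) {
  X <- model$X
  n <- nrow(X)
  D <- length(x)
  expo <- numeric(n)
  dterm <- matrix(0, D, n)
  for (k in seq_len(D)) {
    d <- x[k] - X[, k]
    if (model$periodic[k]) {
      p <- model$period[k]
      expo <- expo - 2 * sin(pi * d / p)^2 / model$ls[k]^2
      dterm[k, ] <- -(2 * pi / (p * model$ls[k]^2)) * sin(2 * pi * d / p)
    } else {
      expo <- expo - 0.5 * d^2 / model$ls[k]^2
      dterm[k, ] <- -d / model$ls[k]^2
    }
  }
  ks <- model$sf2 * exp(expo)
  dks <- sweep(dterm, 2, ks, "*")       # D x n
  mu <- model$prior_mean + sum(ks * model$alpha)
  dmu <- as.numeric(dks %*% model$alpha)
  v <- forwardsolve(t(model$L), ks)
  w <- backsolve(model$L, v)            # K^-1 k*
  var <- max(model$sf2 - sum(v^2), 0)
  sd <- sqrt(var)
  if (kappa == 0 || sd < 1e-10) {
    return(list(value = mu - kappa * sd, grad = dmu))
  }
  dsd <- as.numeric(-(dks %*% w)) / sd
  list(value = mu - kappa * sd, grad = dmu - kappa * dsd)
}

# multistart bounded local minimization of f over the space; returns the
# best (x, value).  Start points: low-discrepancy LHS plus any `extra`.
multistart_minimize <- function(f, space, n_starts, seed = NULL,
                                extra = NULL, maxit = 80,
                                return_all = FALSE, grad = NULL) {
  v <- space$vars
  D <- nrow(v)
  if (!is.null(seed)) set.seed(seed)
  U <- lhs::randomLHS(n_starts, D)
  starts <- lapply(seq_len(n_starts), function(i) {
    v$lower + U[i, ] * (v$upper - v$lower)
  })
  starts <- c(starts, extra)
  fwrap <- function(x) f(space_wrap(space, x))
  gwrap <- if (is.null(grad)) NULL else {
    function(x) grad(space_wrap(space, x))
  }
  res <- lapply(starts, function(x0) {
    fit <- tryCatch(
      stats::optim(x0, fwrap, gwrap, method = "L-BFGS-B",
                   lower = v$lower, upper = v$upper,
                   control = list(maxit = maxit)),
      error = function(e) NULL)
    if (is.null(fit)) list(x = x0, value = fwrap(x0))
    else list(x = space_wrap(space, fit$par), value = fit$value)
  })
  if (return_all) return(res)
  res[[which.min(vapply(res, `[[`, 0, "value"))]]
}

#' Propose the next configuration to evaluate
#'
#' Multistart bounded local minimization of the lower-confidence-bound
#' acquisition over the search space (low-discrepancy start points, default
#' `20 * D` starts; periodic variables wrapped).
#'
#' @param model a `surfbo_gp`.
#' @param space the search space.
#' @param kappa exploration weight.
#' @param seed RNG seed for the start points.
#' @param n_starts number of local starts (default `20 * D`).
#' @return proposed input vector.
#' @export
gp_propose_next <- function(model, space, kappa = 2, seed = NULL,
                            n_starts = NULL) {
  D <- space_dim(space)
  if (is.null(n_starts)) n_starts <- 20L * D
  best <- multistart_minimize(
    function(x) acq_value_grad(model, x, kappa)$value,
    space, n_starts, seed = seed,
    grad = function(x) acq_value_grad(model, x, kappa)$grad)
  best$x
}

# argmin of the posterior mean (kappa = 0), warm-started at `extra` points
gp_posterior_argmin <- function(model, space, seed = NULL, n_starts = NULL,
                                extra = NULL) {
  D <- space_dim(space)
  if (is.null(n_starts)) n_starts <- 10L * D
  multistart_minimize(function(x) acq_value_grad(model, x, 0)$value,
                      space, n_starts, seed = seed, extra = extra,
                      grad = function(x) acq_value_grad(model, x, 0)$grad)
}

#' Serialize a GP model to JSON
#'
#' Writes hyperparameters, bounds and a digest of the training data (not the
#' data itself) to a documented JSON schema.
#'
#' @param model a `surfbo_gp`.
#' @param path output file.
#' @return the path, invisibly.
#' @export
gp_to_json <- function(model, path) {
  obj <- list(
    kind = "surfbo_gp",
    n = nrow(model$X), D = ncol(model$X),
    prior_mean = model$prior_mean,
    signal_variance = model$sf2,
    lengthscales = model$ls,
    noise_variance = model$noise,
    log_marginal_likelihood = model$lml,
    periodic = model$periodic,
    variable_labels = model$vars$label,
    lower = model$vars$lower, upper = model$vars$upper,
    data_digest = list(n = nrow(model$X),
                       x_mean = colMeans(model$X),
                       y_mean = mean(model$y), y_min = min(model$y)))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
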