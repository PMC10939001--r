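# independent textbook GP posterior for cross-checking: direct dense solve,
# no Cholesky sharing with the implementation
reference_posterior <- function(X, y, Xs, sf2, ls, noise, periodic, period,
                                m0) {
  kfun <- function(a, b) {
    e <- 0
    for (k in seq_along(ls)) {
      d <- a[k] - b[k]
      e <- e - if (periodic[k]) 2 * sin(pi * d / period[k])^2 / ls[k]^2
               else 0.5 * d^2 / ls[k]^2
    }
    sf2 * exp(e)
  }
  n <- nrow(X)
  K <- outer(seq_len(n), seq_len(n),
             Vectorize(function(i, j) kfun(X[i, ], X[j, ])))
  Ks <- outer(seq_len(nrow(Xs)), seq_len(n),
              Vectorize(function(i, j) kfun(Xs[i, ], X[j, ])))
  Ki <- solve(K + noise * diag(n))
  mu <- m0 + Ks %*% Ki %*% (y - m0)
  var <- sf2 - rowSums((Ks %*% Ki) * Ks)
  list(mean = as.numeric(mu), sd = sqrt(pmax(var, 0)))
}

test_that("posterior matches an independent closed-form implementation", {
  sp <- search_space_new(c("u", "v"), c(0, 0), c(2, 360), c(FALSE, TRUE),
                         c("translation_x", "dihedral"))
  set.seed(5)
  X <- cbind(runif(25, 0, 2), runif(25, 0, 360))
  y <- sin(2 * X[, 1]) + cos(pi * X[, 2] / 180)
  # pin well-conditioned hyperparameters so the comparison tests the
  # posterior formulas, not the conditioning of a fitted kernel matrix
  m <- gp_fit(X, y, sp, noise = 1e-5, seed = 2, n_starts = 1,
              max_opt_iter = 1)
  m$sf2 <- 1.0
  m$ls <- c(0.5, 90)
  m$noise <- 1e-4
  m <- surfbo:::gp_refresh(m, X, y)
  expect_equal(m$jitter, 0)
  grid <- as.matrix(expand.grid(seq(0, 2, length.out = 12),
                                seq(0, 360, length.out = 12)))
  p <- gp_posterior(m, grid)
  ref <- reference_posterior(X, y, grid, m$sf2, m$ls, m$noise,
                             sp$vars$periodic,
                             sp$vars$upper - sp$vars$lower, m$prior_mean)
  expect_lt(max(abs(p$mean - ref$mean)), 1e-8)
  expect_lt(max(abs(p$sd - ref$sd)), 1e-8)
})

test_that("noise-free posterior interpolates and reverts to the prior", {
  sp <- search_space_new("x", 0, 1, FALSE, "translation_x")
  set.seed(1)
  X <- matrix(runif(10), ncol = 1)
  y <- sin(5 * X[, 1])
  m <- gp_fit(X, y, sp, noise = 1e-10, seed = 1)
  p <- gp_posterior(m, X)
  expect_lt(max(abs(p$mean - y)), 1e-6)
  expect_lt(max(p$sd), 1e-4)
  # far from all data (lengthscale far below the gap): prior reversion
  m$ls <- 0.005
  m <- surfbo:::gp_refresh(m, X, y)
  far <- matrix(min(X) / 2, 1, 1)
  p0 <- gp_posterior(m, far)
  expect_equal(p0$mean, m$prior_mean, tolerance = 1e-4)
  expect_equal(p0$sd, sqrt(m$sf2), tolerance = 1e-3)
})

test_that("periodic kernel component is exactly periodic", {
  sp <- search_space_new("g", 0, 360, TRUE, "euler_gamma")
  X <- matrix(c(10, 100, 250), ncol = 1)
  y <- c(0.2, -0.1, 0.4)
  m <- gp_fit(X, y, sp, noise = 1e-8, seed = 1, n_starts = 1)
  p1 <- gp_posterior(m, matrix(33, 1, 1))
  p2 <- gp_posterior(m, matrix(33 + 360, 1, 1))
  expect_equal(p1$mean, p2$mean, tolerance = 1e-12)
  expect_equal(p1$sd, p2$sd, tolerance = 1e-12)
})

test_that("fit handles degenerate inputs and is order-invariant", {
  sp <- search_space_new("x", 0, 1, FALSE, "translation_x")
  # duplicated inputs with equal responses succeed via jitter
  X <- matrix(c(0.2, 0.2, 0.7, 0.9), ncol = 1)
  y <- c(1, 1, 2, 1.5)
  m <- gp_fit(X, y, sp, noise = 1e-10, seed = 1)
  expect_s3_class(m, "surfbo_gp")
  # constant response: posterior mean is the constant
  yc <- rep(2.5, 4)
  mc <- gp_fit(matrix(c(0.1, 0.4, 0.6, 0.9), ncol = 1), yc, sp,
               noise = 1e-10, seed = 1)
  pc <- gp_posterior(mc, matrix(c(0.25, 0.5), ncol = 1))
  expect_lt(max(abs(pc$mean - 2.5)), 1e-6)
  # reordering the training data leaves the posterior unchanged
  set.seed(3)
  X2 <- matrix(runif(20), ncol = 1)
  y2 <- sin(5 * X2[, 1])
  m1 <- gp_fit(X2, y2, sp, noise = 1e-8, seed = 4)
  perm <- sample(20)
  m2 <- gp_fit(X2[perm, , drop = FALSE], y2[perm], sp, noise = 1e-8,
               seed = 4)
  q <- matrix(seq(0, 1, length.out = 7), ncol = 1)
  expect_lt(max(abs(gp_posterior(m1, q)$mean - gp_posterior(m2, q)$mean)),
            1e-6)
})

test_that("hyperparameter fitting recovers a known lengthscale within factor 2", {
  sp <- search_space_new("x", 0, 10, FALSE, "translation_x")
  n <- 200
  ls_true <- 1.2; sf_true <- 1.0; noise_true <- 1e-4
  set.seed(8)
  X <- matrix(sort(runif(n, 0, 10)), ncol = 1)
  K <- sf_true * exp(-0.5 * outer(X[, 1], X[, 1], "-")^2 / ls_true^2) +
    noise_true * diag(n)
  y <- as.numeric(t(chol(K)) %*% rnorm(n))
  m <- gp_fit(X, y, sp, optimize_noise = TRUE, seed = 3, n_starts = 4)
  expect_gt(m$ls, ls_true / 2)
  expect_lt(m$ls, ls_true * 2)
})

test_that("the fitted optimum beats random hyperparameter draws", {
  sp <- search_space_new("x", 0, 1, FALSE, "translation_x")
  set.seed(10)
  X <- matrix(runif(30), ncol = 1)
  y <- sin(6 * X[, 1]) + 0.3 * X[, 1]
  m <- gp_fit(X, y, sp, noise = 1e-6, seed = 1)
  lml_fit <- gp_lml(m)
  for (k in 1:10) {
    lml_rnd <- gp_lml(m, sf2 = exp(runif(1, -4, 2)),
                      ls = exp(runif(1, log(0.02), log(2))))
    expect_gte(lml_fit, lml_rnd - 1e-6)
  }
})

test_that("acquisition is a lower confidence bound with grid-verified argmin", {
  sp <- search_space_new("x", 0, 1, FALSE, "translation_x")
  set.seed(2)
  X <- matrix(runif(12), ncol = 1)
  y <- (X[, 1] - 0.4)^2
  m <- gp_fit(X, y, sp, noise = 1e-8, seed = 1)
  q <- matrix(seq(0, 1, length.out = 41), ncol = 1)
  # kappa = 0 equals the posterior mean
  expect_equal(gp_acquisition(m, q, kappa = 0), gp_posterior(m, q)$mean)
  # pointwise non-increasing in kappa
  a1 <- gp_acquisition(m, q, kappa = 1)
  a2 <- gp_acquisition(m, q, kappa = 3)
  expect_true(all(a2 <= a1 + 1e-12))
  # multistart proposal matches a dense grid scan
  for (kap in c(0.5, 2)) {
    dense <- matrix(seq(0, 1, length.out = 2001), ncol = 1)
    av <- gp_acquisition(m, dense, kappa = kap)
    x_star <- gp_propose_next(m, sp, kappa = kap, seed = 6)
    expect_lte(gp_acquisition(m, matrix(x_star, 1, 1), kappa = kap),
               min(av) + 1e-6)
  }
  # single-basin posterior: proposal near the analytic minimum
  x0 <- gp_propose_next(m, sp, kappa = 0, seed = 6)
  expect_lt(abs(x0 - 0.4), 1e-2)
  expect_true(x0 >= 0 && x0 <= 1)
})

test_that("model serialization writes the documented schema", {
  sp <- search_space_new("x", 0, 1, FALSE, "translation_x")
  set.seed(2)
  X <- matrix(runif(8), ncol = 1)
  m <- gp_fit(X, X[, 1]^2, sp, seed = 1)
  f <- tempfile(fileext = ".json")
  gp_to_json(m, f)
  o <- jsonlite::read_json(f, simplifyVector = TRUE)
  expect_equal(o$kind, "surfbo_gp")
  expect_equal(o$n, 8)
  expect_equal(o$signal_variance, m$sf2, tolerance = 1e-12)
  expect_equal(as.numeric(o$lengthscales), as.numeric(m$ls),
               tolerance = 1e-12)
})
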