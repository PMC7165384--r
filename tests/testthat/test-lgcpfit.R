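test_that("model_data validates alignment and flags zero-offset cases", {
  fm <- flat_model(4)
  expect_error(model_data(rep(0, 10), fm$E, cbind(rep(1, fm$K)), fm$A),
               "align")
  expect_error(model_data(rep(-1, fm$K), fm$E, cbind(rep(1, fm$K)), fm$A),
               "non-negative integers")
  E0 <- fm$E; E0[1] <- 0
  y <- rep(1, fm$K)
  expect_warning(md <- model_data(y, E0, cbind(rep(1, fm$K)), fm$A),
                 "zero expected")
  expect_equal(md$flagged, 1L)
})

test_that("flat counts give a unit baseline risk and a shrunken field", {
  fm <- flat_model(10, E_per_cell = 50)
  y <- round(fm$E)
  md <- model_data(y, fm$E, matrix(1, fm$K, 1,
                                   dimnames = list(NULL, "(Intercept)")), fm$A)
  fit <- fit_lgcp(md, fm$mesh)
  draws <- posterior_samples(fit, 2000, seed = 1)
  rr0 <- median(exp(draws$beta[, 1]))
  expect_lt(abs(rr0 - 1), 0.02)
  hs <- hyper_summary(fit)
  expect_lt(hs$sigma2["50%"], pc_prior_sigma()$median^2)
})

test_that("scaling all offsets shifts the baseline by -log(c) and nothing else", {
  grid <- make_grid(10, 10, 1)
  mesh <- build_mesh(grid, 1.25, 5)
  A <- make_projector(mesh, grid$cells)
  K <- nrow(grid$cells)
  set.seed(21)
  E <- rep(200, K)
  x <- as.numeric(scale(rnorm(K)))
  X <- cbind("(Intercept)" = 1, x = x)
  z <- as.numeric(A %*% sample_gaussian_field(mesh, 0.3, 5, seed = 2))
  y <- rpois(K, E * exp(0.2 * x + z - mean(z)))
  f1 <- fit_lgcp(model_data(y, E, X, A), mesh)
  f2 <- fit_lgcp(model_data(y, 2 * E, X, A), mesh)
  M <- f1$M
  mmean <- function(f, j) sum(f$theta$weight *
                                vapply(f$modes, function(m) m[M + j], 1))
  level <- function(f) sum(f$theta$weight * vapply(f$modes, function(m)
    m[M + 1] + mean(as.numeric(A %*% m[1:M])), 1))
  # with identifiable data the refined grid holds essentially all the
  # posterior mass away from its edges
  expect_lt(f1$edge_mass, 0.05)
  # the identified baseline (intercept + field mean) shifts exactly
  expect_lt(abs(level(f2) - (level(f1) - log(2))), 1e-4)
  # the intercept absorbs almost all of it (a small remainder leaks into
  # the field's constant direction at weakly identified long ranges)
  expect_lt(abs(mmean(f2, 1) - (mmean(f1, 1) - log(2))), 0.05)
  expect_lt(abs(mmean(f2, 2) - mmean(f1, 2)), 1e-4)
  expect_lt(max(abs(f1$theta$weight - f2$theta$weight)), 0.005)
})

test_that("posterior draws are seed-reproducible and internally consistent", {
  fm <- flat_model(6, E_per_cell = 20)
  y <- rpois(fm$K, fm$E)
  md <- model_data(y, fm$E, matrix(1, fm$K, 1), fm$A)
  fit <- fit_lgcp(md, fm$mesh)
  d1 <- posterior_samples(fit, 500, seed = 7)
  d2 <- posterior_samples(fit, 500, seed = 7)
  expect_identical(d1$beta, d2$beta)
  expect_identical(d1$Z_cells, d2$Z_cells)
  # sample mean of beta matches the mixture posterior mean within 3 SE
  dbig <- posterior_samples(fit, 10000, seed = 8)
  mixture_mean <- sum(vapply(seq_len(nrow(fit$theta)), function(t)
    fit$theta$weight[t] * fit$modes[[t]][fit$M + 1], numeric(1)))
  se <- sd(dbig$beta[, 1]) / sqrt(10000)
  expect_lt(abs(mean(dbig$beta[, 1]) - mixture_mean), 3 * se)
})

test_that("a single-point hyper grid yields exactly Gaussian draws", {
  fm <- flat_model(6, E_per_cell = 20)
  set.seed(5)
  y <- rpois(fm$K, fm$E)
  md <- model_data(y, fm$E, matrix(1, fm$K, 1), fm$A)
  fit <- fit_lgcp(md, fm$mesh, settings = fit_settings(grid_n = 1))
  expect_equal(nrow(fit$theta), 1L)
  d <- posterior_samples(fit, 5000, seed = 9)
  expect_gt(shapiro.test(d$beta[sample.int(5000, 3000), 1])$p.value, 0.001)
})

test_that("degenerate all-zero data are rejected", {
  fm <- flat_model(4)
  md <- model_data(rep(0, fm$K), rep(0, fm$K), matrix(1, fm$K, 1), fm$A)
  expect_error(fit_lgcp(md, fm$mesh), "nothing to fit")
})

test_that("conditional modes satisfy the score equation", {
  fm <- flat_model(6, E_per_cell = 25)
  set.seed(3)
  y <- rpois(fm$K, fm$E)
  md <- model_data(y, fm$E, matrix(1, fm$K, 1), fm$A)
  fit <- fit_lgcp(md, fm$mesh)
  # re-evaluate the score at the weight-carrying modes: either the
  # gradient meets the absolute tolerance or the affine-invariant Newton
  # decrement shows the mode is converged to floating-point accuracy
  # (points with near-singular precision scales)
  B <- methods::cbind2(fm$A, Matrix::Matrix(md$design, sparse = TRUE))
  for (t in order(fit$theta$weight, decreasing = TRUE)[1:3]) {
    Q <- spde_precision(fm$mesh, fit$theta$sigma[t], fit$theta$rho[t])
    P <- Matrix::bdiag(Q, Matrix::Diagonal(1, 1 / prior_spec()$beta_var))
    u <- fit$modes[[t]]
    eta <- as.numeric(B %*% u)
    g <- as.numeric(Matrix::t(B) %*% (y - fm$E * exp(eta))) -
      as.numeric(P %*% u)
    nd <- sum(g * as.numeric(Matrix::solve(fit$Hs[[t]], g)))
    expect_true(max(abs(g)) < 1e-6 || nd < 1e-9)
  }
})

test_that("data simulated without a field shrink sigma below its prior median", {
  fm <- flat_model(10, E_per_cell = 40)
  set.seed(31)
  y <- rpois(fm$K, fm$E)              # sigma = 0 truth
  md <- model_data(y, fm$E, matrix(1, fm$K, 1), fm$A)
  fit <- fit_lgcp(md, fm$mesh)
  hs <- hyper_summary(fit)
  expect_lt(hs$sigma2["50%"], pc_prior_sigma()$median^2)
})
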