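fake_draws <- function(beta, Z, design = NULL) {
  structure(list(beta = beta, Z_cells = Z,
                 design = if (is.null(design))
                   matrix(1, ncol(Z), ncol(beta)) else design),
            class = "posterior_draws")
}

test_that("rr map of a null field is identically 1", {
  d <- fake_draws(matrix(0, 10, 1), matrix(0, 10, 4))
  m <- rr_map(d)
  expect_equal(m$rr, rep(1, 4))
  expect_equal(unname(attr(m, "range")[c("min", "max")]), c(1, 1))
})

test_that("even-sample medians average the central pair", {
  Z <- rbind(matrix(-0.2, 5, 3), matrix(0.2, 5, 3))
  d <- fake_draws(matrix(0, 10, 1), Z)
  m <- rr_map(d)
  expect_equal(m$rr, rep((exp(-0.2) + exp(0.2)) / 2, 3))
})

test_that("cellwise medians agree with an independent quantile routine", {
  set.seed(6)
  Z <- matrix(rnorm(200 * 7), 200, 7)
  d <- fake_draws(matrix(0, 200, 1), Z)
  m <- rr_map(d)
  oracle <- apply(exp(Z), 2, function(v) {
    s <- sort(v)
    (s[100] + s[101]) / 2
  })
  expect_equal(m$rr, oracle, tolerance = 1e-12)
})

test_that("exceedance probabilities handle strictness and thresholds", {
  d <- fake_draws(matrix(0, 4, 1), matrix(log(1.5), 4, 2))
  expect_equal(exceedance_map(d)$prob, c(1, 1))
  d0 <- fake_draws(matrix(0, 4, 1), matrix(0, 4, 2))
  expect_equal(exceedance_map(d0)$prob, c(0, 0))   # strict inequality
  expect_error(exceedance_map(d0, threshold = 0), "positive")
  set.seed(2)
  dn <- fake_draws(matrix(0, 1e4, 1), matrix(rnorm(1e4), ncol = 1))
  expect_lt(abs(exceedance_map(dn)$prob - 0.5), 0.02)
})

test_that("exceedance is symmetric under field reflection", {
  set.seed(3)
  Z <- matrix(rnorm(500 * 5, sd = 0.4), 500, 5)
  t <- 1.2
  p1 <- exceedance_map(fake_draws(matrix(0, 500, 1), Z), threshold = t)$prob
  # P(RR > t) = 1 - P(1/RR >= 1/t); ties have measure zero here
  p2 <- 1 - exceedance_map(fake_draws(matrix(0, 500, 1), -Z),
                           threshold = 1 / t)$prob -
    colMeans(exp(-Z) == 1 / t)
  expect_equal(p1, p2, tolerance = 1e-12)
})

test_that("fixed-effect table transforms draws monotonically", {
  # 401 draws puts the 2.5% quantile exactly on an order statistic, so
  # the monotone-map identity holds without interpolation effects
  b <- cbind("(Intercept)" = rep(0, 401), x = rnorm(401, log(1.17), 0.01))
  tab <- fixed_effects_table(fake_draws(b, matrix(0, 401, 2)))
  expect_equal(tab$rr[1], 1)
  expect_equal(tab$lo[1], 1)
  expect_lt(abs(tab$rr[2] - 1.17), 0.02)
  # exp of the percentile equals the percentile of the exp
  expect_equal(tab$lo[2], exp(quantile(b[, "x"], 0.025, names = FALSE)),
               tolerance = 1e-12)
})

test_that("Bayesian R2 has the two degenerate limits and stays in [0, 1]", {
  X <- cbind(1, c(0, 1, 2))
  # constant linear predictor across units -> R2 = 0
  d0 <- fake_draws(cbind(rnorm(20), 0), matrix(rnorm(60), 20, 3), design = X)
  expect_true(all(bayesian_r2(d0)$draws == 0))
  # no field -> R2 = 1
  d1 <- fake_draws(cbind(0, rnorm(20, 1, 0.1)), matrix(0, 20, 3), design = X)
  expect_true(all(bayesian_r2(d1)$draws == 1))
  set.seed(9)
  d <- fake_draws(cbind(rnorm(50), rnorm(50)), matrix(rnorm(150), 50, 3),
                  design = X)
  r2 <- bayesian_r2(d)
  expect_true(all(r2$draws >= 0 & r2$draws <= 1))
})

test_that("R2 matches a hand computation on 3 units and 2 draws", {
  X <- cbind(1, c(0, 1, 2))
  beta <- rbind(c(0, 1), c(0, 0.5))
  Z <- rbind(c(0, 0, 0), c(1, 2, 4))
  r2 <- bayesian_r2(fake_draws(beta, Z, design = X))
  # draw 1: V(Xb) = 1, V(Z) = 0 -> 1; draw 2: 0.25 / (0.25 + 7/3) = 3/31
  expect_equal(r2$draws, c(1, 3 / 31), tolerance = 1e-12)
})

test_that("R2 is invariant to constant shifts of field and intercept", {
  set.seed(4)
  X <- cbind(1, rnorm(6))
  d <- fake_draws(cbind(rnorm(30), rnorm(30)), matrix(rnorm(180), 30, 6),
                  design = X)
  r2a <- bayesian_r2(d)$draws
  d$Z_cells <- d$Z_cells + 5
  d$beta[, 1] <- d$beta[, 1] - 2
  expect_equal(bayesian_r2(d)$draws, r2a, tolerance = 1e-9)
})

test_that("both-zero variance draws are defined as 0 and flagged", {
  X <- cbind(1, c(0, 0, 0))
  d <- fake_draws(cbind(0, 1), matrix(0, 1, 3), design = X)
  r2 <- bayesian_r2(d)
  expect_equal(r2$draws, 0)
  expect_equal(r2$flagged, 1)
})
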