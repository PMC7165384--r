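test_that("constant census density propagates to every year unchanged", {
  g <- make_grid(4, 4, 1)
  cfg <- small_scenario()
  p <- simulate_population(g, cfg, constant_density = 100)
  expect_true(all(p == 100))
})

test_that("the default panel spans 3 age groups and 31 years", {
  g <- make_grid(10, 10, 1)
  p <- simulate_population(g, small_scenario())
  expect_equal(dim(p)[1:2], c(3L, 31L))
  expect_equal(dimnames(p)[[1]], c("0-4", "5-9", "10-15"))
  expect_equal(dimnames(p)[[2]], as.character(1985:2015))
  # strictly positive national totals per stratum
  expect_true(all(apply(p, c(1, 2), sum) > 0))
})

test_that("generators are reproducible under the scenario seed", {
  g <- make_grid(6, 6, 1)
  p1 <- simulate_population(g, small_scenario(seed = 5))
  p2 <- simulate_population(g, small_scenario(seed = 5))
  p3 <- simulate_population(g, small_scenario(seed = 6))
  expect_identical(p1, p2)
  expect_false(identical(p1, p3))
  c1 <- simulate_covariates(g, small_scenario(seed = 5))
  c2 <- simulate_covariates(g, small_scenario(seed = 5))
  expect_identical(c1$design, c2$design)
})

test_that("config errors are caught", {
  expect_error(scenario_config(census_years = c(1950)), "subset")
  expect_error(scenario_config(target_total_cases = 0), "positive")
  g <- make_grid(6, 6, 1)
  expect_error(simulate_covariates(g, small_scenario(), n_language = 1),
               "2 levels")
})

test_that("continuous design columns are centred and SD-scaled", {
  g <- make_grid(10, 10, 1)
  cv <- simulate_covariates(g, small_scenario())
  for (nm in c("no2", "radiation", "sep", "regyears")) {
    expect_lt(abs(mean(cv$design[, nm])), 1e-9)
    expect_lt(abs(sd(cv$design[, nm]) - 1), 1e-9)
  }
  expect_true(all(cv$design[, "(Intercept)"] == 1))
})

test_that("language expands to 2 indicators with German as reference", {
  g <- make_grid(10, 10, 1)
  cv <- simulate_covariates(g, small_scenario())
  expect_true(all(c("lang_French", "lang_Italian") %in% colnames(cv$design)))
  expect_false("lang_German" %in% colnames(cv$design))
  expect_true(all(cv$design[, "lang_French"] %in% c(0, 1)))
  expect_equal(cv$meta$categorical$language$reference, "German")
})

test_that("doubling raw SDs changes metadata but not the scaled design", {
  g <- make_grid(10, 10, 1)
  cfg1 <- small_scenario(seed = 9)
  sds2 <- cfg1$covariate_sds * 2
  cfg2 <- small_scenario(seed = 9, covariate_sds = sds2)
  cv1 <- simulate_covariates(g, cfg1)
  cv2 <- simulate_covariates(g, cfg2)
  expect_equal(cv1$design, cv2$design, tolerance = 1e-12)
  expect_equal(cv2$meta$continuous$raw_sd, 2 * cv1$meta$continuous$raw_sd,
               tolerance = 1e-9)
})

test_that("cells with zero intensity never receive cases", {
  g <- make_grid(2, 2, 1)
  cfg <- small_scenario()
  E <- structure(data.frame(k = 1:4, E = c(0, 5, 5, 5)),
                 class = c("expected_surface", "data.frame"))
  cs <- simulate_cases(E, rr = 1, cfg, g, seed = 1)
  expect_false(any(cs$k == 1))
  expect_true(all(cs$x >= 0 & cs$x <= 2 & cs$y >= 0 & cs$y <= 2))
  expect_error(simulate_cases(structure(data.frame(k = 1, E = -1),
                                        class = c("expected_surface", "data.frame")),
                              1, cfg, make_grid(1, 1, 1)), "negative")
})

test_that("cell case counts are Poisson with mean E * rr", {
  g <- make_grid(2, 2, 1)
  cfg <- small_scenario()
  E <- structure(data.frame(k = 1:4, E = c(1, 2, 4, 8)),
                 class = c("expected_surface", "data.frame"))
  rr <- c(2, 1, 0.5, 1)
  tot <- matrix(0, 1000, 4)
  for (r in seq_len(1000)) {
    cs <- simulate_cases(E, rr, cfg, g, seed = 1000 + r)
    tot[r, ] <- tabulate(cs$k, 4)
  }
  mu <- E$E * rr
  se <- sqrt(mu / 1000)
  expect_true(all(abs(colMeans(tot) - mu) < 3 * se))
})

test_that("geocode error classes are 1-4 with ~94% below 100 m", {
  g <- make_grid(10, 10, 1)
  cfg <- small_scenario(target_total_cases = 5000)
  E <- structure(data.frame(k = seq_len(100), E = rep(50, 100)),
                 class = c("expected_surface", "data.frame"))
  cs <- simulate_cases(E, 1, cfg, g, seed = 2)
  expect_true(all(cs$error_class %in% 1:4))
  expect_lt(abs(mean(cs$error_class <= 2) - 0.94), 0.02)
})

test_that("the default scenario yields about 5947 cases", {
  inputs <- lgcpmap:::simulate_inputs(experiment_config(seed = 3))
  n <- nrow(inputs$cases)
  expect_lt(abs(n - 5947), 4 * sqrt(5947))
  nb <- nrow(inputs$cases_birth)
  expect_lt(abs(nb - 4198), 4 * sqrt(4198))
})
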