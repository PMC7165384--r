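census_array <- function(values, census_years, K = 1, ages = "0-4") {
  # values: matrix [census, cell] or vector per census
  v <- matrix(values, nrow = length(census_years))
  arr <- array(NA_real_, dim = c(length(ages), length(census_years), ncol(v)),
               dimnames = list(ages, as.character(census_years),
                               seq_len(ncol(v))))
  for (i in seq_along(ages)) arr[i, , ] <- v
  arr
}

test_that("intercensal years interpolate linearly, census years pass through", {
  cp <- census_array(c(100, 200), c(1990, 2000))
  p <- interpolate_population(cp, 1985:2005)
  expect_equal(p[1, "1995", 1], 150)
  expect_equal(p[1, "1990", 1], 100)
  expect_equal(p[1, "2000", 1], 200)
  expect_equal(p[1, "1992", 1], 120)
})

test_that("constant censuses give a constant panel", {
  cp <- census_array(c(70, 70, 70), c(1990, 2000, 2010))
  p <- interpolate_population(cp, 1985:2015)
  expect_true(all(p == 70))
})

test_that("years outside the census span are held at the nearest census", {
  cp <- census_array(c(100, 200), c(1990, 2000))
  p <- interpolate_population(cp, 1985:2005)
  expect_equal(p[1, "1985", 1], 100)
  expect_equal(p[1, "2005", 1], 200)
})

test_that("interpolation matches an independently coded 1-d rule", {
  set.seed(8)
  cy <- c(1990, 2000, 2010, 2012)
  vals <- matrix(runif(length(cy) * 5, 10, 500), length(cy), 5)
  cp <- census_array(vals, cy)
  p <- interpolate_population(cp, 1985:2015)
  for (k in 1:5) {
    oracle <- approx(cy, vals[, k], xout = 1985:2015, rule = 2)$y
    expect_equal(as.numeric(p[1, , k]), oracle, tolerance = 1e-12)
  }
})

test_that("an empty census panel is rejected", {
  cp <- census_array(100, 1990)[, 0, , drop = FALSE]
  expect_error(interpolate_population(cp, 1985:2015), "census")
})

test_that("national rates divide case counts by national person-years", {
  cp <- census_array(c(10000, 10000), c(1990, 2000), ages = "0-4")
  panel <- interpolate_population(cp, 1990:1991)
  panel <- array(rep(panel, 3), dim = c(1, 2, 3),
                 dimnames = list("0-4", c("1990", "1991"), 1:3))
  panel[1, , ] <- 10000
  cases <- data.frame(age_group = rep("0-4", 3), year = rep(1990, 3))
  q <- national_rates(cases, panel)
  expect_equal(q["0-4", "1990"], 3 / 30000)
  expect_equal(q["0-4", "1991"], 0)
})

test_that("no cases means all rates zero; zero-pop stratum with cases errors", {
  panel <- array(100, dim = c(2, 2, 2),
                 dimnames = list(c("0-4", "5-9"), c("1990", "1991"), 1:2))
  q <- national_rates(data.frame(age_group = character(), year = integer()),
                      panel)
  expect_true(all(q == 0))
  panel[1, 1, ] <- 0
  expect_error(national_rates(data.frame(age_group = "0-4", year = 1990),
                              panel), "zero national population")
})

test_that("rate-population identity recovers the total case count", {
  g <- make_grid(6, 6, 1)
  cfg <- small_scenario(seed = 3)
  panel <- simulate_population(g, cfg)
  E0 <- structure(data.frame(k = 1:36, E = rep(5, 36)),
                  class = c("expected_surface", "data.frame"))
  cases <- simulate_cases(E0, 1, cfg, g, panel = panel,
                          rates = national_rates(
                            simulate_cases(E0, 1, cfg, g, seed = 2), panel),
                          seed = 4)
  q <- national_rates(cases, panel)
  natpop <- apply(panel, c(1, 2), sum)
  expect_equal(sum(q * natpop), nrow(cases), tolerance = 1e-9)
})

test_that("expected counts follow the one-term example", {
  panel <- array(c(1000, 3000), dim = c(1, 1, 2),
                 dimnames = list("0-4", "1990", 1:2))
  q <- structure(matrix(0.001, 1, 1, dimnames = list("0-4", "1990")),
                 class = c("rate_table", "matrix"))
  E <- expected_cases(q, panel)
  expect_equal(E$E, c(1, 3))
})

test_that("internally derived standardisation conserves the case total", {
  g <- make_grid(8, 8, 1)
  cfg <- small_scenario(seed = 12)
  panel <- simulate_population(g, cfg)
  E0 <- structure(data.frame(k = seq_len(64), E = rep(4, 64)),
                  class = c("expected_surface", "data.frame"))
  cases <- simulate_cases(E0, 1, cfg, g, panel = panel,
                          rates = NULL, seed = 5)
  q <- national_rates(cases, panel)
  E <- expected_cases(q, panel)
  expect_equal(sum(E$E), nrow(cases), tolerance = 1e-9)
})

test_that("zero birth rates give a zero expected surface", {
  panel <- array(500, dim = c(1, 3, 4),
                 dimnames = list("<1", 1990:1992, 1:4))
  q <- structure(matrix(0, 1, 3, dimnames = list("<1", 1990:1992)),
                 class = c("rate_table", "matrix"))
  E <- expected_cases(q, panel, analysis = "birth")
  expect_true(all(E$E == 0))
})

test_that("index mismatch between rates and panel is a structural error", {
  panel <- array(1, dim = c(1, 2, 2),
                 dimnames = list("0-4", c("1990", "1991"), 1:2))
  q <- structure(matrix(0.1, 1, 1, dimnames = list("0-4", "1990")),
                 class = c("rate_table", "matrix"))
  expect_error(expected_cases(q, panel), "differ")
})

test_that("increasing a population entry raises E and lowers recomputed rates", {
  panel <- array(runif(12, 50, 150), dim = c(2, 2, 3),
                 dimnames = list(c("0-4", "5-9"), c("1990", "1991"), 1:3))
  q <- structure(matrix(0.01, 2, 2,
                        dimnames = list(c("0-4", "5-9"), c("1990", "1991"))),
                 class = c("rate_table", "matrix"))
  E1 <- expected_cases(q, panel)$E
  panel2 <- panel
  panel2[1, 1, 2] <- panel2[1, 1, 2] + 100
  E2 <- expected_cases(q, panel2)$E
  expect_true(all(E2 >= E1))
  expect_gt(E2[2], E1[2])
  cases <- data.frame(age_group = rep("0-4", 5), year = rep(1990, 5))
  expect_lt(national_rates(cases, panel2)["0-4", "1990"],
            national_rates(cases, panel)["0-4", "1990"])
})

test_that("the under-1 stratum is one fifth of the youngest age group", {
  panel <- array(100, dim = c(3, 2, 2),
                 dimnames = list(c("0-4", "5-9", "10-15"),
                                 c("1990", "1991"), 1:2))
  u <- under1_panel(panel)
  expect_equal(dim(u), c(1L, 2L, 2L))
  expect_true(all(u == 20))
  expect_equal(dimnames(u)[[1]], "<1")
})
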