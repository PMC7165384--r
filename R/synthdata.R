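# Synthetic registry generator: population panels, covariate surfaces,
# latent risk fields and case locations with the statistical structure
# the downstream analysis assumes.

# derived stage seeds, kept below 2^31
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 7919 + offset * 104729) %% 2147483629)
}

# one smooth random surface over the grid cells: a Matern GRF on a coarse
# mesh projected to cell centroids (uses the caller's RNG state)
smooth_surface <- function(grid, rho = NULL, sigma = 1) {
  ext <- max(diff(range(grid$window[, 1])), diff(range(grid$window[, 2])))
  if (is.null(rho)) rho <- ext / 3
  mesh <- build_mesh(grid, node_spacing = ext / 12, buffer = ext / 3)
  z <- sample_gaussian_field(mesh, sigma = sigma, rho = rho, n = 1)
  A <- make_projector(mesh, grid$cells)
  as.numeric(A %*% z)
}

# partition cells into n contiguous (convex) regions: nearest of n random
# seed points; regions relabelled by decreasing size
voronoi_partition <- function(grid, n) {
  if (n < 2) stop("categorical partitions need at least 2 levels", call. = FALSE)
  xr <- range(grid$window[, 1]); yr <- range(grid$window[, 2])
  sx <- stats::runif(n, xr[1] + 0.1 * diff(xr), xr[2] - 0.1 * diff(xr))
  sy <- stats::runif(n, yr[1] + 0.1 * diff(yr), yr[2] - 0.1 * diff(yr))
  d2 <- outer(grid$cells$x, sx, "-")^2 + outer(grid$cells$y, sy, "-")^2
  lab <- max.col(-d2)
  sizes <- tabulate(lab, n)
  match(lab, order(sizes, decreasing = TRUE))
}

#' Simulate a population panel of person-years
#'
#' Draws census-year population layers from a smooth spatial density —
#' an exponentiated Matern random surface scaled so each age group's
#' national total matches the configured value in expectation, with
#' stochastic rounding to integers — and fills intercensal years by the
#' linear interpolation used for standardisation
#' ([interpolate_population()]; constant extrapolation outside the census
#' span).
#'
#' @param grid a [make_grid()] object.
#' @param cfg a [scenario_config()].
#' @param constant_density if non-NULL, every census cell receives this
#'   constant count per age group instead (no rounding noise) — useful
#'   for analytic checks.
#' @return array \[age group, year, cell\] of person-years, with the cell
#'   table attached as attribute \code{cells}.
#' @export
simulate_population <- function(grid, cfg, constant_density = NULL) {
  if (nrow(grid$cells) < 1L) stop("grid has no cells", call. = FALSE)
  if (!all(cfg$census_years %in% cfg$years))
    stop("census_years must lie within years", call. = FALSE)
  K <- nrow(grid$cells)
  nc <- length(cfg$census_years)
  na <- length(cfg$age_groups)
  cens <- array(0, dim = c(na, nc, K),
                dimnames = list(cfg$age_groups, as.character(cfg$census_years),
                                seq_len(K)))
  if (!is.null(constant_density)) {
    cens[] <- constant_density
  } else {
    set.seed(derive_seed(cfg$seed, 1L))
    base <- smooth_surface(grid, sigma = 0.8)
    for (ci in seq_len(nc)) {
      pert <- smooth_surface(grid, sigma = 0.15)
      for (ai in seq_len(na)) {
        dens <- exp(base + pert)
        target <- dens / sum(dens) * cfg$pop_per_agegroup
        cens[ai, ci, ] <- floor(target) +
          stats::rbinom(K, 1L, target - floor(target))
      }
    }
  }
  out <- interpolate_population(cens, cfg$years)
  attr(out, "cells") <- grid$cells
  out
}

#' Simulate covariate surfaces and build the SD-scaled design matrix
#'
#' Continuous covariates are smooth low-frequency random fields, stored
#' in raw units with the configured SDs, then centred and scaled to
#' sample SD 1 for the design. The registry-years covariate is piecewise
#' constant over a canton-like Voronoi partition. Categorical covariates
#' partition the window into contiguous (convex) regions: 3 language
#' regions (reference "German", the largest) and 3 urbanisation levels
#' (reference "rural", the largest). Indicators are reference-coded.
#'
#' @param grid a [make_grid()] object.
#' @param cfg a [scenario_config()].
#' @param n_language,n_urban number of levels for the two categorical
#'   covariates (>= 2).
#' @param n_cantons number of canton-like regions for the registry-years
#'   surface.
#' @return object of class \code{covariate_set}: list with \code{design}
#'   (K x p matrix, first column intercept), \code{raw} (data.frame of
#'   raw surfaces and factors), \code{meta} (per-column metadata: type,
#'   reference level, configured and realised raw SD, verbatim unit
#'   labels).
#' @export
simulate_covariates <- function(grid, cfg, n_language = 3, n_urban = 3,
                                n_cantons = 9) {
  if (n_language < 2 || n_urban < 2)
    stop("categorical covariates need at least 2 levels", call. = FALSE)
  set.seed(derive_seed(cfg$seed, 2L))
  K <- nrow(grid$cells)
  centres <- c(no2 = 20, radiation = 100, sep = 60, regyears = 15)
  raw <- data.frame(row.names = seq_len(K))
  for (nm in names(cfg$covariate_sds)) {
    if (nm == "regyears") {
      canton <- voronoi_partition(grid, n_cantons)
      v <- stats::runif(n_cantons, 0, diff(range(cfg$years)))
      f <- v[canton]
    } else {
      f <- smooth_surface(grid)
    }
    fstd <- (f - mean(f)) / stats::sd(f)
    ctr <- if (nm %in% names(centres)) centres[[nm]] else 0
    raw[[nm]] <- ctr + cfg$covariate_sds[[nm]] * fstd
  }
  lang_levels <- c("German", "French", "Italian", paste0("L", seq_len(max(0, n_language - 3))))
  urb_levels <- c("rural", "semiurban", "urban", paste0("U", seq_len(max(0, n_urban - 3))))
  raw$language <- factor(lang_levels[voronoi_partition(grid, n_language)],
                         levels = lang_levels[seq_len(n_language)])
  raw$urbanisation <- factor(urb_levels[voronoi_partition(grid, n_urban)],
                             levels = urb_levels[seq_len(n_urban)])
  cont <- names(cfg$covariate_sds)
  scaled <- vapply(cont, function(nm) as.numeric(scale(raw[[nm]])), numeric(K))
  mm_lang <- stats::model.matrix(~language, raw)[, -1, drop = FALSE]
  colnames(mm_lang) <- paste0("lang_", levels(raw$language)[-1])
  mm_urb <- stats::model.matrix(~urbanisation, raw)[, -1, drop = FALSE]
  colnames(mm_urb) <- paste0("urb_", levels(raw$urbanisation)[-1])
  design <- cbind("(Intercept)" = 1, scaled, mm_lang, mm_urb)
  meta <- list(
    continuous = data.frame(
      name = cont,
      cfg_sd = as.numeric(cfg$covariate_sds[cont]),
      raw_sd = vapply(cont, function(nm) stats::sd(raw[[nm]]), numeric(1)),
      row.names = NULL),
    categorical = list(language = list(reference = levels(raw$language)[1]),
                       urbanisation = list(reference = levels(raw$urbanisation)[1])),
    indicator_columns = c(colnames(mm_lang), colnames(mm_urb)),
    labels = c(no2 = cfg$no2_sd_label, radiation = "nSv/h",
               sep = "units", regyears = "years"))
  structure(list(design = design, raw = raw, meta = meta),
            class = "covariate_set")
}

#' Simulate case locations from expected counts and a relative-risk field
#'
#' Per cell, the number of cases is Poisson with mean \eqn{E_k r_k}; each
#' case is placed uniformly within its cell. Age group and year of
#' diagnosis are drawn proportional to \eqn{q_{ij} P_{ijk}} within the
#' cell when rates and panel are supplied (uniform over strata
#' otherwise). A diagnostic group and a geocoding margin-of-error class
#' (1: < 50 m, ..., 4: > 500 m; about 94\% in classes 1-2) are attached
#' for fixture realism; neither is used by the fitting code.
#'
#' @param expected an [expected_cases()] surface (column \code{E}).
#' @param rr per-cell relative risks (> 0), length K or scalar.
#' @param cfg a [scenario_config()].
#' @param grid the [make_grid()] the surface is indexed by.
#' @param panel,rates optional population panel and rate table for
#'   within-cell stratum assignment.
#' @param seed optional integer; defaults to a seed derived from the
#'   scenario seed.
#' @return data.frame of class \code{case_set} with columns \code{x},
#'   \code{y} (km), \code{age_group}, \code{year}, \code{group},
#'   \code{error_class}, \code{k} (source cell).
#' @export
simulate_cases <- function(expected, rr, cfg, grid,
                           panel = NULL, rates = NULL, seed = NULL) {
  E <- expected$E
  if (any(E < 0)) stop("negative expected counts", call. = FALSE)
  rr <- rep_len(rr, length(E))
  if (any(rr <= 0)) stop("relative risks must be positive", call. = FALSE)
  set.seed(if (is.null(seed)) derive_seed(cfg$seed, 3L) else seed)
  counts <- stats::rpois(length(E), E * rr)
  k <- rep(seq_along(E), counts)
  n <- length(k)
  half <- grid$cell_km / 2
  x <- grid$cells$x[k] + stats::runif(n, -half, half)
  y <- grid$cells$y[k] + stats::runif(n, -half, half)
  if (!is.null(panel) && !is.null(rates)) {
    ages <- dimnames(panel)[[1]]
    yrs <- as.integer(dimnames(panel)[[2]])
    ai <- integer(n); yi <- integer(n)
    for (kk in unique(k)) {
      sel <- which(k == kk)
      w <- as.vector(rates * matrix(panel[, , kk], nrow = dim(panel)[1]))
      if (sum(w) <= 0) w <- rep(1, length(w))
      s <- sample.int(length(w), length(sel), replace = TRUE, prob = w)
      ai[sel] <- (s - 1L) %% length(ages) + 1L
      yi[sel] <- (s - 1L) %/% length(ages) + 1L
    }
    age_group <- ages[ai]
    year <- yrs[yi]
  } else {
    age_group <- sample(cfg$age_groups, n, replace = TRUE)
    year <- sample(cfg$years, n, replace = TRUE)
  }
  group <- sample(c("leukaemia", "lymphoma", "CNS", "other"), n,
                  replace = TRUE, prob = c(0.32, 0.13, 0.22, 0.33))
  error_class <- sample(1:4, n, replace = TRUE,
                        prob = c(0.80, 0.14, 0.05, 0.01))
  structure(data.frame(x = x, y = y, age_group = age_group, year = year,
                       group = group, error_class = error_class, k = k),
            class = c("case_set", "data.frame"))
}

#' Bin case locations to grid cells
#'
#' @param cases a case table with columns \code{x}, \code{y}.
#' @param grid a [make_grid()] object.
#' @return integer vector of case counts per cell (length K).
#' @export
bin_cases <- function(cases, grid) {
  tabulate(cell_index(grid, cases$x, cases$y), nbins = nrow(grid$cells))
}
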