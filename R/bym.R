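# Besag-York-Mollie areal comparator: aggregation of the grid analysis
# to pseudo-municipalities and the classic BYM model (ICAR structured
# effect + independent unstructured effect) fitted with the same
# Laplace / hyper-grid machinery as the LGCP.

#' Partition the grid into rectangular pseudo-municipalities
#'
#' Deterministic blocks of cells (connected by construction) standing in
#' for municipalities; adjacency between areas follows the shared-edge
#' (rook) rule on the block lattice.
#'
#' @param grid a [make_grid()] object.
#' @param block_km block side length in km (a multiple of the cell size
#'   is cleanest; cells are assigned by centroid).
#' @return object of class \code{areal_partition}: \code{area} (integer
#'   area per cell), \code{n_areas}, \code{adjacency} (2-column edge
#'   matrix, symmetric rule, no self loops), \code{centroids}.
#' @export
make_partition <- function(grid, block_km) {
  stopifnot(block_km > 0)
  bx <- pmin(floor((grid$cells$x - grid$origin[1]) / block_km),
             ceiling(grid$nx * grid$cell_km / block_km) - 1)
  by <- pmin(floor((grid$cells$y - grid$origin[2]) / block_km),
             ceiling(grid$ny * grid$cell_km / block_km) - 1)
  nbx <- max(bx) + 1L
  nby <- max(by) + 1L
  area <- as.integer(by * nbx + bx + 1L)
  n_areas <- nbx * nby
  ax <- (seq_len(n_areas) - 1L) %% nbx
  ay <- (seq_len(n_areas) - 1L) %/% nbx
  e_right <- cbind(which(ax < nbx - 1L), which(ax < nbx - 1L) + 1L)
  e_up <- cbind(which(ay < nby - 1L), which(ay < nby - 1L) + nbx)
  adjacency <- rbind(e_right, e_up)
  centroids <- data.frame(
    a = seq_len(n_areas),
    x = tapply(grid$cells$x, area, mean)[as.character(seq_len(n_areas))],
    y = tapply(grid$cells$y, area, mean)[as.character(seq_len(n_areas))])
  structure(list(area = area, n_areas = n_areas, adjacency = adjacency,
                 centroids = centroids, nbx = nbx, nby = nby),
            class = "areal_partition")
}

#' Aggregate cell-level data to areas
#'
#' Counts and expected counts are summed per area; continuous design
#' columns are weighted averages (weights default to the expected
#' counts, a person-time proxy); indicator columns are re-derived from
#' the modal raw level among the area's cells when raw covariates are
#' available, otherwise weighted-averaged and rounded.
#'
#' @param counts cases per cell (length K), e.g. from [bin_cases()].
#' @param expected an [expected_cases()] surface or numeric E per cell.
#' @param covariates a [simulate_covariates()] object (or a bare design
#'   matrix).
#' @param partition a [make_partition()] object covering every cell.
#' @param weights per-cell aggregation weights (default: expected
#'   counts).
#' @param categorical names of indicator design columns to aggregate by
#'   cell majority instead of weighted mean; defaults to the indicator
#'   columns recorded in the covariate-set metadata (none for a bare
#'   matrix, whose columns are all treated as continuous).
#' @return list of class \code{areal_data}: \code{counts}, \code{E},
#'   \code{design} (rows = areas), \code{adjacency}, \code{n_areas}.
#' @export
aggregate_areal <- function(counts, expected, covariates, partition,
                            weights = NULL, categorical = NULL) {
  E <- if (is.data.frame(expected)) expected$E else as.numeric(expected)
  K <- length(E)
  if (length(partition$area) != K || anyNA(partition$area))
    stop("partition does not cover every cell", call. = FALSE)
  a <- partition$area
  na <- partition$n_areas
  if (is.null(weights)) weights <- E
  w <- pmax(weights, 1e-12)
  y_a <- as.numeric(tapply(counts, factor(a, seq_len(na)), sum, default = 0))
  E_a <- as.numeric(tapply(E, factor(a, seq_len(na)), sum, default = 0))
  X <- if (inherits(covariates, "covariate_set")) covariates$design else covariates
  if (is.null(categorical) && inherits(covariates, "covariate_set"))
    categorical <- covariates$meta$indicator_columns
  agg_col <- function(v, binary) {
    if (binary) {
      # modal assignment by cell majority
      as.numeric(tapply(v, factor(a, seq_len(na)),
                        function(z) as.numeric(mean(z) > 0.5), default = 0))
    } else {
      num <- tapply(w * v, factor(a, seq_len(na)), sum, default = 0)
      den <- tapply(w, factor(a, seq_len(na)), sum, default = 1e-12)
      as.numeric(num) / as.numeric(den)
    }
  }
  Xa <- matrix(vapply(seq_len(ncol(X)),
                      function(j) agg_col(X[, j], colnames(X)[j] %in% categorical),
                      numeric(na)),
               nrow = na, dimnames = list(NULL, colnames(X)))
  Xa[, "(Intercept)"] <- 1
  structure(list(counts = y_a, E = E_a, design = Xa,
                 adjacency = partition$adjacency, n_areas = na),
            class = "areal_data")
}

# graph Laplacian (ICAR structure matrix) from an edge list
icar_structure <- function(adjacency, n) {
  i <- c(adjacency[, 1], adjacency[, 2])
  j <- c(adjacency[, 2], adjacency[, 1])
  if (any(i == j)) stop("adjacency contains self-loops", call. = FALSE)
  W <- Matrix::sparseMatrix(i = i, j = j, x = 1, dims = c(n, n))
  W@x[] <- 1   # collapse duplicate edges
  Matrix::Diagonal(n, Matrix::rowSums(W)) - W
}

#' Fit the Besag-York-Mollie model on areal counts
#'
#' \deqn{y_a \sim Poisson(E_a \exp\{x_a\beta + u_a + v_a\})}
#' with an intrinsic CAR (ICAR) prior on the structured effect u —
#' improper, handled by an exact sum-to-zero constraint via an
#' orthonormal basis of the constraint subspace — and independent
#' Gaussian v. The two scale hyperparameters carry PC priors
#' \eqn{P(\sigma > 1) = 0.01} each (mirroring the field-SD calibration),
#' and inference uses the same Newton-Laplace hyper-grid scheme as
#' [fit_lgcp()].
#'
#' @param data an [aggregate_areal()] object.
#' @param priors a [prior_spec()]; \code{sigma_u}/\code{sigma_alpha}
#'   calibrate both random-effect SD priors, \code{beta_var} the fixed
#'   effects.
#' @param settings a [fit_settings()].
#' @return object of class \code{bym_fit} (same posterior interface as
#'   \code{lgcp_fit}: [posterior_samples()], [hyper_summary()]).
#' @export
fit_bym <- function(data, priors = prior_spec(), settings = fit_settings()) {
  stopifnot(inherits(data, "areal_data"))
  na <- data$n_areas
  R <- icar_structure(data$adjacency, na)
  # connectivity check: ICAR rank must be n - 1
  comp <- connected_components(data$adjacency, na)
  if (max(comp) > 1L)
    stop("adjacency graph is disconnected; per-component constraints are not supported",
         call. = FALSE)
  # orthonormal basis of the sum-to-zero subspace
  S <- qr.Q(qr(cbind(rep(1, na), diag(na))), complete = FALSE)[, 2:na, drop = FALSE]
  Rw <- crossprod(S, as.matrix(R) %*% S)
  Rw <- (Rw + t(Rw)) / 2
  logdetRw <- as.numeric(determinant(Rw, logarithm = TRUE)$modulus)
  X <- data$design
  p <- ncol(X)
  B <- methods::cbind2(methods::cbind2(Matrix::Matrix(S, sparse = TRUE),
                                       Matrix::Diagonal(na)),
                       Matrix::Matrix(X, sparse = TRUE))
  Bt <- Matrix::t(B)
  Rw_s <- Matrix::Matrix(Rw, sparse = TRUE)
  pu <- pc_prior_sigma(priors)
  eval_grid <- function(grid) {
    n_theta <- nrow(grid)
    modes <- vector("list", n_theta)
    Hs <- vector("list", n_theta)
    logev <- numeric(n_theta)
    u0 <- NULL
    for (t in seq_len(n_theta)) {
      su <- exp(grid$log_sigma_u[t])
      sv <- exp(grid$log_sigma_v[t])
      P <- Matrix::bdiag(Rw_s / su^2, Matrix::Diagonal(na, 1 / sv^2),
                         Matrix::Diagonal(p, 1 / priors$beta_var))
      logdetP <- (logdetRw - 2 * (na - 1) * log(su)) -
        2 * na * log(sv) + p * log(1 / priors$beta_var)
      nm <- newton_mode(data$counts, data$E, B, Bt, P, u0 = u0,
                        tol = settings$tol, max_iter = settings$max_iter)
      if (!nm$converged)
        stop(sprintf("Newton iteration did not converge at (sigma_u = %.4g, sigma_v = %.4g)",
                     su, sv), call. = FALSE)
      u0 <- nm$mode
      modes[[t]] <- nm$mode
      Hs[[t]] <- nm$H
      logev[t] <- laplace_evidence(data$counts, data$E, B, P, logdetP,
                                   nm$mode, nm$H) +
        pu$log_density(su) + log(su) + pu$log_density(sv) + log(sv)
    }
    w <- exp(logev - max(logev))
    grid$sigma_u <- exp(grid$log_sigma_u)
    grid$sigma_v <- exp(grid$log_sigma_v)
    grid$logev <- logev
    grid$weight <- w / sum(w)
    list(grid = grid, modes = modes, Hs = Hs)
  }
  lsu <- hyper_grid_1d(pu, settings)
  pass1 <- eval_grid(expand.grid(log_sigma_u = lsu, log_sigma_v = lsu))
  final <- pass1
  if (settings$refine && settings$grid_n > 1L) {
    g1 <- pass1$grid
    for (expand in c(1, 2, 4)) {
      final <- eval_grid(expand.grid(
        log_sigma_u = refine_axis(g1$log_sigma_u, g1$weight,
                                  settings$grid_n, expand),
        log_sigma_v = refine_axis(g1$log_sigma_v, g1$weight,
                                  settings$grid_n, expand)))
      gf <- final$grid
      edge_w <- sum(gf$weight[gf$log_sigma_u %in% range(gf$log_sigma_u) |
                                gf$log_sigma_v %in% range(gf$log_sigma_v)])
      if (edge_w < 0.05) break
    }
  }
  grid <- final$grid
  modes <- final$modes
  Hs <- final$Hs
  structure(list(data = data, theta = grid, modes = modes, Hs = Hs,
                 n_areas = na, p = p, S = S, priors = priors,
                 settings = settings, terms = colnames(X),
                 icar_rank = na - 1L),
            class = "bym_fit")
}

#' @export
print.bym_fit <- function(x, ...) {
  hs <- hyper_summary(x)
  cat(sprintf("bym_fit: %d areas, %d fixed effects; median sigma_u^2 = %.4f, sigma_v^2 = %.4f\n",
              x$n_areas, x$p, hs$sigma2_u["50%"], hs$sigma2_v["50%"]))
  invisible(x)
}

connected_components <- function(adjacency, n) {
  comp <- integer(n)
  nb <- vector("list", n)
  for (e in seq_len(nrow(adjacency))) {
    a <- adjacency[e, 1]; b <- adjacency[e, 2]
    nb[[a]] <- c(nb[[a]], b)
    nb[[b]] <- c(nb[[b]], a)
  }
  cur <- 0L
  for (s in seq_len(n)) {
    if (comp[s] == 0L) {
      cur <- cur + 1L
      stack <- s
      while (length(stack)) {
        v <- stack[length(stack)]
        stack <- stack[-length(stack)]
        if (comp[v] == 0L) {
          comp[v] <- cur
          stack <- c(stack, nb[[v]])
        }
      }
    }
  }
  comp
}
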