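#' Model data for the discretised log-Gaussian Cox process
#'
#' The continuous LGCP likelihood is approximated at the analysis
#' resolution by cell-level Poisson counts with the standardised expected
#' count \eqn{E_k} as offset: case coordinates are binned to cells and
#' \eqn{y_k \sim Poisson(E_k \exp\{X_k\beta + Z(s_k)\})}. Cells with
#' \eqn{E_k = 0} are retained (their Poisson mean is 0); a positive count
#' in such a cell raises a warning and is flagged.
#'
#' @param counts non-negative integer cases per cell (length K).
#' @param offset expected counts \eqn{E_k} (length K, >= 0), e.g. the
#'   \code{E} column of [expected_cases()].
#' @param design K x p design matrix, first column the intercept; use
#'   \code{cbind(1)} replicated for the intercept-only ("unadjusted")
#'   model.
#' @param projector sparse projector from mesh nodes to the K cell
#'   centroids ([make_projector()]).
#' @return list of class \code{model_data}.
#' @export
model_data <- function(counts, offset, design, projector) {
  K <- length(counts)
  if (is.null(dim(design))) design <- matrix(design, ncol = 1)
  if (length(offset) != K || nrow(design) != K || nrow(projector) != K)
    stop("counts, offset, design and projector must align on cells",
         call. = FALSE)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers", call. = FALSE)
  if (any(offset < 0)) stop("offsets must be non-negative", call. = FALSE)
  flagged <- which(offset == 0 & counts > 0)
  if (length(flagged))
    warning(sprintf("%d cell(s) have cases but zero expected count",
                    length(flagged)))
  if (is.null(colnames(design)))
    colnames(design) <- c("(Intercept)",
                          paste0("x", seq_len(ncol(design) - 1)))[seq_len(ncol(design))]
  structure(list(counts = as.numeric(counts), offset = as.numeric(offset),
                 design = design, projector = projector, flagged = flagged),
            class = "model_data")
}

#' Fit the log-Gaussian Cox process by Laplace approximation on a
#' hyperparameter grid
#'
#' A simplified integrated-nested-Laplace scheme: for each point of a
#' deterministic grid over \eqn{(\log\sigma, \log\rho)} the joint
#' Gaussian (Laplace) approximation of the latent block \eqn{(Z, \beta)}
#' given the counts is found by Newton iteration with step-halving, the
#' Laplace evidence is accumulated with the PC-prior density of the
#' hyperparameters, and the grid weights are normalised. All posterior
#' summaries and maps are mixtures over the grid.
#'
#' @param data a [model_data()] object.
#' @param mesh the [build_mesh()] triangulation the projector refers to.
#' @param priors a [prior_spec()].
#' @param settings a [fit_settings()].
#' @param range_median optional prior median range (km) overriding the
#'   \code{priors} calibration; used by the sensitivity scan.
#' @return object of class \code{lgcp_fit}: the data, mesh, a
#'   \code{theta} table (grid points, log-evidence, weights), per-point
#'   conditional modes and precisions, and bookkeeping (M nodes, p fixed
#'   effects, priors, settings).
#' @export
fit_lgcp <- function(data, mesh, priors = prior_spec(),
                     settings = fit_settings(), range_median = NULL) {
  stopifnot(inherits(data, "model_data"))
  if (all(data$counts == 0) && all(data$offset == 0))
    stop("all counts and offsets are zero: nothing to fit", call. = FALSE)
  A <- data$projector
  X <- data$design
  M <- ncol(A)
  p <- ncol(X)
  B <- methods::cbind2(A, Matrix::Matrix(X, sparse = TRUE))
  Bt <- Matrix::t(B)
  ps <- pc_prior_sigma(priors)
  pr <- pc_prior_range(priors, median = range_median)
  Pbeta <- Matrix::Diagonal(p, 1 / priors$beta_var)
  eval_grid <- function(grid) {
    n_theta <- nrow(grid)
    modes <- vector("list", n_theta)
    Hs <- vector("list", n_theta)
    logev <- numeric(n_theta)
    u0 <- NULL
    for (t in seq_len(n_theta)) {
      sigma <- exp(grid$log_sigma[t])
      rho <- exp(grid$log_rho[t])
      Q <- spde_precision(mesh, sigma, rho)
      P <- Matrix::bdiag(Q, Pbeta)
      logdetP <- sparse_logdet(Q) + p * log(1 / priors$beta_var)
      nm <- newton_mode(data$counts, data$offset, B, Bt, P, u0 = u0,
                        tol = settings$tol, max_iter = settings$max_iter)
      if (!nm$converged)
        stop(sprintf("Newton iteration did not converge at (sigma = %.4g, rho = %.4g); gradient norm %.2e",
                     sigma, rho, nm$grad_norm), call. = FALSE)
      u0 <- nm$mode
      modes[[t]] <- nm$mode
      Hs[[t]] <- nm$H
      # evidence plus hyperprior density on the log scale (Jacobian theta)
      logev[t] <- laplace_evidence(data$counts, data$offset, B, P, logdetP,
                                   nm$mode, nm$H) +
        ps$log_density(sigma) + log(sigma) +
        pr$log_density(rho) + log(rho)
    }
    w <- exp(logev - max(logev))
    grid$sigma <- exp(grid$log_sigma)
    grid$rho <- exp(grid$log_rho)
    grid$logev <- logev
    grid$weight <- w / sum(w)
    list(grid = grid, modes = modes, Hs = Hs)
  }
  pass1 <- eval_grid(expand.grid(log_sigma = hyper_grid_1d(ps, settings),
                                 log_rho = hyper_grid_1d(pr, settings)))
  final <- pass1
  if (settings$refine && settings$grid_n > 1L) {
    g1 <- pass1$grid
    # widen (at most twice) if the refined window still clips the
    # posterior, i.e. its edges carry non-negligible mass
    for (expand in c(1, 2, 4)) {
      final <- eval_grid(expand.grid(
        log_sigma = refine_axis(g1$log_sigma, g1$weight, settings$grid_n,
                                expand),
        log_rho = refine_axis(g1$log_rho, g1$weight, settings$grid_n,
                              expand)))
      gf <- final$grid
      edge_w <- sum(gf$weight[gf$log_sigma %in% range(gf$log_sigma) |
                                gf$log_rho %in% range(gf$log_rho)])
      if (edge_w < 0.05) break
    }
  }
  grid <- final$grid
  modes <- final$modes
  Hs <- final$Hs
  w <- grid$weight
  edge <- grid$log_sigma %in% range(grid$log_sigma) |
    grid$log_rho %in% range(grid$log_rho)
  structure(list(data = data, mesh = mesh, theta = grid,
                 modes = modes, Hs = Hs, M = M, p = p,
                 priors = priors, settings = settings,
                 range_median = if (is.null(range_median)) pr$median else range_median,
                 edge_mass = sum(w[edge]),
                 terms = colnames(X)),
            class = "lgcp_fit")
}

#' @export
print.lgcp_fit <- function(x, ...) {
  hs <- hyper_summary(x)
  cat(sprintf("lgcp_fit: %d cells, %d mesh nodes, %d fixed effects, %d hyper grid points\n",
              length(x$data$counts), x$M, x$p, nrow(x$theta)))
  cat(sprintf("  posterior median sigma^2 = %.4f, range = %.1f km (edge mass %.3f)\n",
              hs$sigma2["50%"], hs$rho["50%"], x$edge_mass))
  invisible(x)
}

#' Posterior summaries of the field hyperparameters
#'
#' Weighted quantiles of \eqn{\sigma^2} and \eqn{\rho} over the
#' hyperparameter grid (median and 95\% equal-tailed interval).
#'
#' @param fit an [fit_lgcp()] or [fit_bym()] object.
#' @return list with numeric vectors \code{sigma2} and \code{rho} (LGCP)
#'   or \code{sigma2_u} and \code{sigma2_v} (BYM), each with the 2.5, 50
#'   and 97.5 percentiles.
#' @export
hyper_summary <- function(fit) {
  th <- fit$theta
  pq <- c(0.025, 0.5, 0.975)
  nmq <- c("2.5%", "50%", "97.5%")
  if (inherits(fit, "bym_fit")) {
    out <- list(
      sigma2_u = stats::setNames(weighted_quantile(th$sigma_u^2, th$weight, pq), nmq),
      sigma2_v = stats::setNames(weighted_quantile(th$sigma_v^2, th$weight, pq), nmq))
  } else {
    out <- list(
      sigma2 = stats::setNames(weighted_quantile(th$sigma^2, th$weight, pq), nmq),
      rho = stats::setNames(weighted_quantile(th$rho, th$weight, pq), nmq))
  }
  out
}
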