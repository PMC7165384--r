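#' Joint posterior draws from a fitted model
#'
#' Draws hyperparameters from the grid weights, then the latent block
#' from the corresponding Gaussian (Laplace) conditional via its sparse
#' Cholesky factor. Deterministic under a fixed seed.
#'
#' @param fit an [fit_lgcp()] or [fit_bym()] object.
#' @param n number of draws (> 0).
#' @param seed optional integer seed.
#' @return object of class \code{posterior_draws}: list with matrices
#'   \code{beta} (n x p) and \code{Z_cells} (n x K; for BYM fits the
#'   combined area effect u + v, plus \code{u} and \code{v} separately),
#'   hyperparameter draws, and the sampled grid indices.
#' @export
posterior_samples <- function(fit, n, seed = NULL) {
  if (!is.numeric(n) || n <= 0) stop("n must be positive", call. = FALSE)
  UseMethod("posterior_samples")
}

# draw m samples from N(mode, H^{-1}) given the Laplace precision H
gaussian_conditional_draws <- function(mode, H, m) {
  ch <- Matrix::Cholesky(H, LDL = FALSE, perm = TRUE)
  z <- matrix(stats::rnorm(length(mode) * m), length(mode), m)
  y <- Matrix::solve(ch, z, system = "Lt")
  sweep(as.matrix(Matrix::solve(ch, y, system = "Pt")), 1, mode, "+")
}

#' @export
posterior_samples.lgcp_fit <- function(fit, n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- as.integer(n)
  idx <- sample.int(nrow(fit$theta), n, replace = TRUE,
                    prob = fit$theta$weight)
  U <- matrix(0, fit$M + fit$p, n)
  for (t in unique(idx)) {
    sel <- which(idx == t)
    U[, sel] <- gaussian_conditional_draws(fit$modes[[t]], fit$Hs[[t]],
                                           length(sel))
  }
  Zn <- U[seq_len(fit$M), , drop = FALSE]
  beta <- t(U[fit$M + seq_len(fit$p), , drop = FALSE])
  colnames(beta) <- fit$terms
  Z_cells <- t(as.matrix(fit$data$projector %*% Zn))
  structure(list(beta = beta, Z_cells = Z_cells,
                 sigma = fit$theta$sigma[idx], rho = fit$theta$rho[idx],
                 theta_index = idx, design = fit$data$design),
            class = "posterior_draws")
}

#' @export
posterior_samples.bym_fit <- function(fit, n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- as.integer(n)
  idx <- sample.int(nrow(fit$theta), n, replace = TRUE,
                    prob = fit$theta$weight)
  na <- fit$n_areas
  d <- (na - 1L) + na + fit$p
  U <- matrix(0, d, n)
  for (t in unique(idx)) {
    sel <- which(idx == t)
    U[, sel] <- gaussian_conditional_draws(fit$modes[[t]], fit$Hs[[t]],
                                           length(sel))
  }
  w <- U[seq_len(na - 1L), , drop = FALSE]
  u <- as.matrix(fit$S %*% w)                     # sum-to-zero by construction
  v <- U[(na - 1L) + seq_len(na), , drop = FALSE]
  beta <- t(U[(na - 1L) + na + seq_len(fit$p), , drop = FALSE])
  colnames(beta) <- fit$terms
  structure(list(beta = beta, Z_cells = t(u + v), u = t(u), v = t(v),
                 sigma_u = fit$theta$sigma_u[idx],
                 sigma_v = fit$theta$sigma_v[idx],
                 theta_index = idx, design = fit$data$design),
            class = "posterior_draws")
}
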