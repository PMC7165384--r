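# brute-force random-walk Metropolis oracle for small latent-Gaussian
# Poisson models; deliberately independent of the package's Laplace code

rw_metropolis <- function(log_post, init, n_iter, step, burn = n_iter %/% 5,
                          seed = 1, prop_chol = NULL) {
  # prop_chol: upper Cholesky factor R (R'R = precision) shaping the
  # symmetric proposal; the Metropolis correction keeps the target exact
  set.seed(seed)
  d <- length(init)
  chain <- matrix(NA_real_, n_iter, d)
  u <- init
  lp <- log_post(u)
  acc <- 0L
  for (it in seq_len(n_iter)) {
    z <- stats::rnorm(d)
    prop <- if (is.null(prop_chol)) u + step * z
            else u + step * backsolve(prop_chol, z)
    lp_prop <- log_post(prop)
    if (is.finite(lp_prop) && log(stats::runif(1)) < lp_prop - lp) {
      u <- prop
      lp <- lp_prop
      acc <- acc + 1L
    }
    chain[it, ] <- u
  }
  list(chain = chain[(burn + 1):n_iter, , drop = FALSE],
       accept = acc / n_iter)
}

# Monte-Carlo standard error by batch means
batch_se <- function(x, n_batch = 50) {
  m <- length(x) %/% n_batch
  bm <- colMeans(matrix(x[seq_len(m * n_batch)], m, n_batch))
  stats::sd(bm) / sqrt(n_batch)
}
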