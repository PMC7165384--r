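# Posterior functionals: relative-risk maps, exceedance maps, fixed
# effect tables and the Bayesian R-squared variance-explained summary.

#' Posterior median relative-risk map
#'
#' Cell-wise posterior median of the spatial relative risk
#' \eqn{\exp\{Z(s_k)\}} relative to the national level. The map reflects
#' the latent field only; a total-predicted-risk variant including the
#' centred covariate contribution is available via
#' \code{include_covariates = TRUE} and is reported separately from the
#' standard map.
#'
#' @param draws a [posterior_samples()] object.
#' @param cells optional data.frame with columns \code{k}, \code{x},
#'   \code{y} to attach coordinates.
#' @param include_covariates if TRUE, map
#'   \eqn{\exp\{X\beta - \overline{X\beta} + Z\}} instead.
#' @return data.frame (k\[, x, y\], rr) of class \code{risk_map} with
#'   attribute \code{range} = c(min, max, median) over cells.
#' @export
rr_map <- function(draws, cells = NULL, include_covariates = FALSE) {
  if (is.null(draws$Z_cells) || nrow(draws$Z_cells) == 0)
    stop("draws contain no field samples", call. = FALSE)
  logrr <- draws$Z_cells
  if (include_covariates) {
    xb <- draws$beta %*% t(draws$design)
    logrr <- logrr + xb - rowMeans(xb)
  }
  rr <- apply(exp(logrr), 2, stats::median)
  out <- data.frame(k = seq_along(rr), rr = rr)
  if (!is.null(cells)) {
    out$x <- cells$x
    out$y <- cells$y
    out <- out[, c("k", "x", "y", "rr")]
  }
  structure(out, range = c(min = min(rr), max = max(rr),
                           median = stats::median(rr)),
            class = c("risk_map", "data.frame"))
}

#' Posterior exceedance-probability map
#'
#' Per cell, the posterior probability that the relative risk strictly
#' exceeds \code{threshold} (default 1): the fraction of draws with
#' \eqn{\exp\{Z(s_k)\} > t}. Cells above the highlight level (default
#' 0.80) are flagged, matching the display convention of exceedance maps.
#'
#' @param draws a [posterior_samples()] object.
#' @param cells optional coordinates as in [rr_map()].
#' @param threshold RR threshold (> 0).
#' @param highlight probability above which a cell is flagged.
#' @return data.frame (k\[, x, y\], prob, highlighted) of class
#'   \code{exceedance_map}.
#' @export
exceedance_map <- function(draws, cells = NULL, threshold = 1,
                           highlight = 0.80) {
  if (threshold <= 0) stop("threshold must be positive", call. = FALSE)
  prob <- colMeans(exp(draws$Z_cells) > threshold)
  out <- data.frame(k = seq_along(prob), prob = prob,
                    highlighted = prob > highlight)
  if (!is.null(cells)) {
    out$x <- cells$x
    out$y <- cells$y
    out <- out[, c("k", "x", "y", "prob", "highlighted")]
  }
  structure(out, threshold = threshold, highlight = highlight,
            class = c("exceedance_map", "data.frame"))
}

#' Fixed-effect table on the relative-risk scale
#'
#' Posterior median and 95\% equal-tailed credibility interval of
#' \eqn{\exp\{\beta_i\}} per design column. For SD-scaled continuous
#' covariates this is the multiplicative change in risk at a fixed
#' location per 1 SD increase of the covariate; for indicator columns it
#' is the risk relative to the reference level.
#'
#' @param draws a [posterior_samples()] object.
#' @param meta optional covariate metadata (\code{meta} element of
#'   [simulate_covariates()]) used to label rows.
#' @return data.frame with columns term, rr, lo, hi, scale.
#' @export
fixed_effects_table <- function(draws, meta = NULL) {
  if (is.null(draws$beta) || nrow(draws$beta) == 0)
    stop("draws contain no fixed effects", call. = FALSE)
  qs <- apply(exp(draws$beta), 2, stats::quantile,
              probs = c(0.5, 0.025, 0.975))
  terms <- colnames(draws$beta)
  scale <- rep("level vs reference", length(terms))
  scale[terms == "(Intercept)"] <- "baseline"
  if (!is.null(meta))
    scale[terms %in% meta$continuous$name] <- "per 1 SD"
  else
    scale[!grepl("^\\(Intercept\\)$|^lang_|^urb_", terms)] <- "per 1 SD"
  data.frame(term = terms, rr = qs[1, ], lo = qs[2, ], hi = qs[3, ],
             scale = scale, row.names = NULL)
}

#' Bayesian R-squared: spatial variance explained by the covariates
#'
#' Per posterior draw, \eqn{R^2 = V(X\beta) / (V(X\beta) + V(Z))} where
#' \eqn{V(\cdot)} is the variance over the K spatial units (grid cells,
#' or areas for an areal fit). Every draw lies in \[0, 1\]; draws where
#' both variances vanish are defined as 0 and flagged.
#'
#' @param draws a [posterior_samples()] object.
#' @param design optional K x p design matrix; defaults to the design
#'   stored with the draws.
#' @return object of class \code{r2_summary}: list with \code{draws},
#'   \code{median}, \code{ci} (95\% equal-tailed), \code{flagged} (count
#'   of degenerate draws).
#' @export
bayesian_r2 <- function(draws, design = NULL) {
  if (is.null(design)) design <- draws$design
  n <- nrow(draws$beta)
  xb <- draws$beta %*% t(design)
  vb <- apply(xb, 1, stats::var)
  vz <- apply(draws$Z_cells, 1, stats::var)
  flagged <- vb == 0 & vz == 0
  r2 <- ifelse(flagged, 0, vb / (vb + vz))
  structure(list(draws = r2, median = stats::median(r2),
                 ci = stats::quantile(r2, c(0.025, 0.975)),
                 flagged = sum(flagged)),
            class = "r2_summary")
}

#' @export
print.r2_summary <- function(x, ...) {
  cat(sprintf("Bayesian R^2: %.3f (95%% CI %.3f-%.3f)%s\n",
              x$median, x$ci[1], x$ci[2],
              if (x$flagged) sprintf(" [%d degenerate draws]", x$flagged) else ""))
  invisible(x)
}
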