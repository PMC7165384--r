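#' Interpolate a census-year population panel to all study years
#'
#' Person-year counts \eqn{P_{ijk}} (age group i, year j, cell k) are
#' observed at census years only; values at intermediate years are linear
#' interpolations, per (i, k), between the two bracketing censuses. Years
#' before the first or after the last census are held constant at the
#' nearest census (constant extrapolation avoids negative populations).
#' Census years pass through unchanged.
#'
#' @param census_panel 3-d array \[age group, census year, cell\] with
#'   dimnames; the year dimnames must be the census years.
#' @param years integer vector of target years.
#' @return 3-d array \[age group, year, cell\] over all \code{years},
#'   carrying forward any attributes of \code{census_panel} (e.g. the
#'   cell table).
#' @export
interpolate_population <- function(census_panel, years) {
  cy <- as.integer(dimnames(census_panel)[[2]])
  if (length(cy) < 1L || any(is.na(cy)))
    stop("census panel must have at least one census year", call. = FALSE)
  o <- order(cy)
  cy <- cy[o]
  census_panel <- census_panel[, o, , drop = FALSE]
  dn <- dimnames(census_panel)
  out <- array(0, dim = c(dim(census_panel)[1], length(years), dim(census_panel)[3]),
               dimnames = list(dn[[1]], as.character(years), dn[[3]]))
  for (jj in seq_along(years)) {
    y <- years[jj]
    if (y <= cy[1]) {
      out[, jj, ] <- census_panel[, 1, ]
    } else if (y >= cy[length(cy)]) {
      out[, jj, ] <- census_panel[, length(cy), ]
    } else {
      hi <- findInterval(y, cy, left.open = TRUE) + 1L
      lo <- hi - 1L
      w <- (y - cy[lo]) / (cy[hi] - cy[lo])
      out[, jj, ] <- (1 - w) * census_panel[, lo, ] + w * census_panel[, hi, ]
    }
  }
  for (a in setdiff(names(attributes(census_panel)), c("dim", "dimnames")))
    attr(out, a) <- attr(census_panel, a)
  out
}

#' Nationwide incidence rates by age group and year
#'
#' \eqn{q_{ij} = } (cases in age group i diagnosed in year j) /
#' \eqn{\sum_k P_{ijk}}, the national person-years in that stratum.
#' Strata with no cases get rate 0 (including empty-population strata);
#' cases falling in a stratum with zero national population are an
#' inconsistency and raise an error.
#'
#' @param cases a case table (data.frame with columns \code{age_group},
#'   \code{year}; see [simulate_cases()]).
#' @param panel population array \[age group, year, cell\].
#' @return matrix of rates \[age group, year\], class \code{rate_table}.
#' @export
national_rates <- function(cases, panel) {
  ages <- dimnames(panel)[[1]]
  yrs <- dimnames(panel)[[2]]
  natpop <- apply(panel, c(1, 2), sum)
  counts <- matrix(0, length(ages), length(yrs), dimnames = list(ages, yrs))
  if (nrow(cases) > 0) {
    ai <- match(as.character(cases$age_group), ages)
    yi <- match(as.character(cases$year), yrs)
    if (any(is.na(ai)) || any(is.na(yi)))
      stop("case stratum not present in the population panel", call. = FALSE)
    tab <- table(factor(ai, seq_along(ages)), factor(yi, seq_along(yrs)))
    counts[] <- as.numeric(tab)
  }
  if (any(counts > 0 & natpop == 0))
    stop("cases observed in a stratum with zero national population",
         call. = FALSE)
  q <- ifelse(natpop > 0, counts / natpop, 0)
  structure(q, class = c("rate_table", "matrix"))
}

#' Indirectly standardised expected counts per spatial unit
#'
#' Applies national stratum-specific rates to local stratum populations:
#' \eqn{E_k = \sum_i \sum_j q_{ij} P_{ijk}}. For the birth analysis the
#' panel and rates refer to the single under-1-year stratum, so the sum
#' runs over years only. When rates were derived from the same cases and
#' panel, \eqn{\sum_k E_k} equals the total case count exactly.
#'
#' @param rates a [national_rates()] matrix (strata must match the panel).
#' @param panel population array \[age group, year, cell\].
#' @param analysis \code{"diagnosis"} (all strata) or \code{"birth"}
#'   (under-1 stratum only; the panel/rates are expected to contain just
#'   that stratum, e.g. from [under1_panel()]).
#' @param grid optional [make_grid()]; if supplied, cell centroid
#'   coordinates are attached.
#' @return data.frame with columns \code{k}, \code{E} (plus \code{x},
#'   \code{y} if \code{grid} given), class \code{expected_surface}.
#' @export
expected_cases <- function(rates, panel, analysis = c("diagnosis", "birth"),
                           grid = NULL) {
  analysis <- match.arg(analysis)
  if (!identical(dim(rates), dim(panel)[1:2]) ||
      !identical(dimnames(rates)[[1]], dimnames(panel)[[1]]) ||
      !identical(dimnames(rates)[[2]], dimnames(panel)[[2]]))
    stop("rates and panel index sets differ", call. = FALSE)
  K <- dim(panel)[3]
  E <- numeric(K)
  for (i in seq_len(dim(panel)[1])) {
    Pj <- matrix(panel[i, , ], nrow = dim(panel)[2], ncol = K)
    E <- E + as.numeric(crossprod(Pj, rates[i, ]))
  }
  out <- data.frame(k = seq_len(K), E = E)
  if (!is.null(grid)) {
    out$x <- grid$cells$x
    out$y <- grid$cells$y
    out <- out[, c("k", "x", "y", "E")]
  }
  structure(out, analysis = analysis, class = c("expected_surface", "data.frame"))
}

#' Under-1-year population stratum for the birth analysis
#'
#' Derives the person-years of children aged under 1 from the youngest
#' age-group layer, assuming a uniform age distribution within the 0-4
#' group (one fifth of its person-years).
#'
#' @param panel population array with first age layer spanning 5 single
#'   years of age.
#' @return array \[1, year, cell\] with age dimname \code{"<1"}.
#' @export
under1_panel <- function(panel) {
  u <- panel[1, , , drop = FALSE] / 5
  dimnames(u)[[1]] <- "<1"
  for (a in setdiff(names(attributes(panel)), c("dim", "dimnames")))
    attr(u, a) <- attr(panel, a)
  u
}
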