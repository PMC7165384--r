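---
title: "Point-process disease mapping with lgcpmap: models, priors and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Point-process disease mapping with lgcpmap}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lgcpmap)
```

## The problem

Rare-disease registries — the motivating case is a nationwide childhood-cancer
registry with roughly 6000 cases over three decades — record exact residential
geocodes. Direct small-area rates from such data are dominated by sampling
noise, and aggregating to administrative units discards the location
information and makes results depend on the unit choice. `lgcpmap` implements
the point-process alternative: a log-Gaussian Cox process (LGCP) over the
observation window, standardised for population structure, with covariate
effects and a smooth latent risk field, and turns the fit into posterior
relative-risk maps, exceedance-probability maps, covariate effect tables and
a variance-explained summary. Because registry microdata of this kind are
confidential, the package ships a synthetic registry generator with the same
statistical structure, so every stage is testable end to end.

## Indirect standardisation

Person-years $P_{ijk}$ (age group $i \in \{0\!-\!4, 5\!-\!9, 10\!-\!15\}$,
year $j \in 1985\ldots 2015$, grid cell $k$) are available at census years
(1990, 2000, 2010–2015) and interpolated linearly in between, per age group
and cell; outside the census span the nearest census is carried constant
(linear extrapolation could go negative, and one-sided trends in a sparse
census design are poorly identified). Nationwide rates
$q_{ij} = \text{cases}_{ij} / \sum_k P_{ijk}$ give expected counts

$$E_k = \sum_i \sum_j q_{ij} \, P_{ijk},$$

the offset of every model. When the rates come from the same cases and panel,
$\sum_k E_k$ equals the total case count exactly — the conservation identity
the tests assert to $10^{-9}$. A birth-cohort analysis uses the same
machinery restricted to the under-1-year stratum (taken as one fifth of the
0–4 person-years, i.e. a uniform age distribution within the group). Strata
with zero cases and zero population get $q_{ij} = 0$ rather than `NaN`.

## The model

Case locations follow an inhomogeneous Poisson process with intensity
$e(s)\,r(s)$, where $e(s)$ is the expected-count intensity (approximated per
cell by $E_k$) and the log relative risk is

$$\log r(s) = X(s)\beta + Z(s),$$

with SD-scaled covariates $X(s)$ and a zero-mean Gaussian random field
$Z(s)$ with Matérn covariance, smoothness fixed at $\nu = 1$. For fitting,
the likelihood is discretised to cell-level counts
$y_k \sim \text{Poisson}(E_k e^{\eta_k})$ at the 1 km² analysis resolution —
consistent with the cell-wise offset construction; case coordinates are
binned to cells.

**Range convention.** The package defines the range $\rho$ as the distance at
which the Matérn correlation falls to 0.10, and calibrates the scale
$\kappa$ by root-finding so that $c(\rho) = (\kappa\rho)K_1(\kappa\rho) =
0.10$ holds exactly ($\kappa\rho \approx 3.214$). The common convention
$\rho = \sqrt{8\nu}/\kappa$ puts the correlation at about 0.139 instead; the
equivalent conventional range is recorded on every precision matrix
(`matern_range_conventional()`), so results can be compared with software
using that convention.

**SPDE representation.** $Z$ is approximated by a piecewise-linear
finite-element expansion $Z_*(s) = \sum_{i=1}^M \psi_i(s) Z_i$ on a
structured triangular lattice covering the window plus a buffer. The weights
form a Gauss–Markov random field with sparse precision
$Q = \tau^2(\kappa^4 C + 2\kappa^2 G + G C^{-1} G)$, with lumped (diagonal)
mass matrix $C$ and stiffness matrix $G$, and
$\tau = 1/(\sqrt{4\pi}\,\kappa\sigma)$ so the stationary variance is
$\sigma^2$. A structured lattice (instead of constrained Delaunay
refinement) keeps the mesh deterministic and is adequate at the window
geometries the package targets; the finite-element variance error scales
like $(\kappa h)^2$ and stays under a few percent for node spacings
$h \lesssim 0.13\,\rho$. The buffer default is 1.5 times the prior median
range; the tests verify that boundary variance inflation decreases
monotonically as the buffer grows.

**Priors.** Penalised-complexity priors shrink toward the flat-risk base
model: $\sigma$ is exponential with rate $-\log(0.01)/1 \approx 4.605$, so
$P(\sigma > 1) = 0.01$; the 2-d Matérn range has
$\pi(\rho) = (\lambda/\rho^2)e^{-\lambda/\rho}$ with
$\lambda = -60\log(0.5)$, so $P(\rho < 60\,\text{km}) = 0.5$. Fixed effects
get $\beta \sim N(0, 10I)$, reading the 10 as a variance. The prior
specification `PCprior(0.01, 1)` is read as (tail probability, threshold);
the opposite order would make the $\sigma$ statement vacuous
($P(\sigma > 0.01)=1$).

## Inference

Inference is a simplified integrated-nested-Laplace scheme. For each point
$\theta = (\log\sigma, \log\rho)$ of a deterministic grid, the joint
Gaussian (Laplace) approximation of the latent block $(Z, \beta)$ given the
counts is located by Newton iteration (step-halving line search, gradient
tolerance $10^{-6}$, at most 50 iterations, with an affine-invariant
Newton-decrement stop for corner points whose objective is floating-point
limited), and the Laplace evidence plus the PC-prior density yields a grid
weight. The grid is laid out in two passes: a 7×7 exploration grid centred
at the prior medians spanning ±3 prior SDs of the log-hyperparameters
(both have SD $\pi/\sqrt6$ exactly), then a second 7×7 grid recentred on
the first pass's posterior mean with half-width three posterior SDs,
floored at one exploration-grid spacing and doubled (at most twice) while
the refined window's edges still hold ≥ 5% of the posterior mass — so a
first pass that collapses onto a single grid point cannot clip the
continuous posterior mode. The second pass is what lets the integration
resolve the hyperparameter posterior rather than the prior; without it,
credibility intervals for fixed effects were noticeably too narrow when the
true range fell between exploration points. Full INLA's nested marginal
corrections are out of scope; the Laplace approximation is validated
against a brute-force Metropolis oracle on small instances (posterior
means within Monte-Carlo error) and against an importance-sampling check
of the evidence.

$\beta$ is absorbed into the latent Gaussian block rather than marginalised
separately. Cells with $E_k = 0$ are retained (Poisson mean 0), keeping the
cell index rectangular; a positive count in such a cell is flagged.

Posterior functionals are computed from joint draws: a grid point is drawn
from the weights, then $(Z, \beta)$ from the corresponding Gaussian
conditional via its sparse Cholesky factor. All draws are reproducible
under a seed.

Two behaviours of this model are worth knowing. First, with no spatial
signal the posterior of $\sigma^2$ shrinks toward 0 — the PC prior's base
model — which is the expected diagnosis of "no residual spatial variation".
Second, the intercept and the field's spatially constant direction are only
jointly identified: multiplying all offsets by $c$ shifts the identified
baseline ($\beta_0$ plus the field mean) by exactly $-\log c$, but at
weakly identified long-range hyperparameter points a few percent of the
shift can leak into the field's constant direction. The tests assert the
identified combination tightly and $\beta_0$ itself with a looser bound.

## Posterior outputs

* **Relative-risk maps**: cell-wise posterior median of $\exp\{Z(s_k)\}$
  (mean-of-central-pair convention for even draw counts), with the
  (min, max) range over cells reported. Both unadjusted and adjusted fits
  map $\exp\{Z\}$ only; a separate total-predicted-risk variant
  $\exp\{X\beta - \overline{X\beta} + Z\}$ is available but kept clearly
  apart, since published unadjusted/adjusted map ranges refer to the field
  component.
* **Exceedance maps**: per cell, the fraction of draws with RR strictly
  above the threshold (default 1); cells above 0.80 are flagged, following
  the usual display convention.
* **Fixed effects**: posterior median and 95% equal-tailed CI of
  $\exp\{\beta_i\}$ — per 1 SD for scaled continuous covariates, versus the
  reference level for indicators.
* **Bayesian $R^2$**: per draw,
  $R^2 = V(X\beta) / (V(X\beta) + V(Z))$ with $V(\cdot)$ the variance over
  the $K$ spatial units (grid cells; areas for BYM fits). Every draw lies
  in $[0,1]$; draws with both variances zero are defined as 0 and flagged.

## The BYM comparator

For consistency with areal disease mapping, counts, offsets and covariates
are aggregated to pseudo-municipalities (deterministic rectangular blocks
of cells, adjacency by shared edge) and fitted with the classic
Besag–York–Mollié model: $y_a \sim \text{Poisson}(E_a e^{x_a\beta + u_a +
v_a})$ with an intrinsic-CAR structured effect $u$ and independent Gaussian
$v$. The ICAR prior is improper (rank $n-1$); the sum-to-zero constraint is
imposed exactly by parameterising $u$ in an orthonormal basis of the
constraint subspace. Both scale hyperparameters carry PC priors
($P(\sigma > 1) = 0.01$), and the same Newton–Laplace hyper-grid machinery
does the fitting. The additive $u + v$ parameterisation (rather than the
scaled BYM2 reparameterisation) is the declared assumption; continuous
covariates aggregate by person-time-weighted mean and indicators by cell
majority. On shared synthetic data with a real spatial signal, the
area-level posterior median RRs of the two models agree in rank
(Spearman > 0.8) and fixed effects agree in sign.

## The synthetic registry generator

The generator emulates the study structure the analysis assumes: three age
groups over 1985–2015 with censuses in 1990, 2000 and 2010–2015; about 5947
cases at diagnosis and 4198 in the birth cohort (the configured expected
totals are hit exactly in expectation by normalising the simulated risk
surface); continuous covariate surfaces as smooth random fields stored in
raw units with SDs matching the published surfaces (radiation 60.2 nSv/h,
SEP 8.7, registry-years 11.6; the NO₂ SD is printed as "77.7 μg/m³ × 10",
an ambiguous unit that is stored verbatim as metadata — the generator uses
77.7 for raw scaling, and the SD-scaled design is invariant to that choice
by construction); a registry-years surface piecewise constant over a
canton-like Voronoi partition; and categorical surfaces partitioning the
window into three contiguous language regions (reference "German", the
largest) and three urbanisation levels (reference "rural"). Population
census layers are exponentiated smooth surfaces scaled to the configured
national totals with stochastic rounding. Case counts are Poisson with mean
$E_k r_k$; each case is placed uniformly within its cell (the
maximum-entropy choice consistent with a cell-wise offset), assigned
(age, year) proportional to $q_{ij}P_{ijk}$ within the cell, a diagnostic
group, and a geocoding error class (~94% within 100 m) that downstream code
never uses — fixture realism only.

Defaults chosen where the emulated study prints no value, fixed once: a
50 × 50 km window of 1 km cells (a desk-scale surrogate; no attempt at real
geography), national child population 4.3 × 10⁵ per age group (so the flat
incidence rate lands near 1.5 per 10⁴ person-years, realistic for childhood
cancer), true field SD 0.15 (variance ≈ 0.02, the order of published
estimates), true range 20 km (spatial structure resolvable within the
window), and true covariate effects near published adjusted estimates
(e.g. RR 1.08 per SD for the radiation surrogate, 1.18 for the
French-speaking region indicator).

What the generator does **not** emulate — and what passing tests therefore
do not show about real data: real geography and population clustering,
real exposure surfaces (only SD-matched surrogates), registry
under-ascertainment and its spatial correlates, geocoding error affecting
positions (classes are simulated but positions are exact), and any
space–time interaction.

## Problem sizes and numerical choices

The package's own validation runs at desk scale, chosen as the smallest
sizes at which each property is meaningfully tested: the parameter-recovery
simulation uses a 30 × 30 km grid, one SD-scaled covariate with true log-RR
0.15, ~6000 expected cases, a 196-node mesh (3 km spacing, 4.5 km buffer)
and 100 replicates; the Metropolis oracles run on 4-cell / 4-area instances
with 2 × 10⁵ iterations and Hessian-preconditioned proposals; field-moment
checks use 2000–5000 draws with pair averaging over the mesh interior.
Expected counts large enough that the $O(1/n)$ Laplace mode-versus-mean gap
is negligible relative to Monte-Carlo error are used where the oracle
comparison is to posterior means. Ties in exceedance probabilities are
measure-zero events and ignored; medians use R's default
mean-of-central-pair convention.

## Interface

The package is an analysis library: `run_experiment()` executes the whole
pipeline (simulate → standardise → fit unadjusted/adjusted ×
diagnosis/birth → post-process → BYM) from one `experiment_config()`, with
every stage seed derived from the master seed, and `sensitivity_scan()`
refits the adjusted model across range-prior medians (default 1, 10, 60,
120, 240 km — each refit's prior is recalibrated so its median equals the
requested value). Artefacts are flat files (CSV, GeoJSON, YAML) written to
a configurable output directory; no shell entry point is provided because
the expected user drives the analysis from R.

## Known limitations

* The hyperparameter posterior is a discrete 7×7 mixture; quantiles of
  $\sigma^2$ and $\rho$ are correspondingly coarse.
* No nested Laplace corrections: fixed-effect marginals are Gaussian
  mixtures; at very low counts the mode-mean gap of order $1/n$ is visible.
* Frequentist coverage of credibility intervals at fixed true
  hyperparameters is close to, but not guaranteed at, the nominal level
  when a covariate shares its spatial scale with the latent field
  (~90–96% observed for 95% intervals across seeds).
* No spatiotemporal modelling, no anisotropy, no $\nu \ne 1$, and no
  per-component constraints for disconnected areal graphs.
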