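---
title: "Robust variance estimation for Poisson count regression: models, simulation design and numerical choices"
author: "robustpois"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Robust variance estimation for Poisson count regression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(robustpois)
```

## The model and its assumptions

`robustpois` addresses a specific decoupling in count regression. For a
taxon's read count $y_i$ in sample $i$ with covariates $X_i$ and optional
log-scale offset $o_i$, the mean model is log-linear:

$$\log \mu_i = o_i + X_i^\top \beta, \qquad \mu_i = E(y_i).$$

If this mean structure is correct, the Poisson maximum-likelihood estimator
$\hat\beta$ — the solution of the score equations
$X^\top(y - \mu) = 0$ — is consistent *regardless of the true variance of
$y_i$*: it is a quasi-likelihood estimator. What breaks under variance
misspecification is only the model-based covariance $(X^\top W X)^{-1}$,
$W = \mathrm{diag}(\mu)$, which assumes $\mathrm{Var}(y_i) = \mu_i$.
Microbiome counts violate that assumption routinely, usually in the
direction $\mathrm{Var}(y_i) \gg \mu_i$, which makes model-based Wald tests
anti-conservative — the naive type I error can reach 80% or more under
heavy overdispersion while the nominal level is 5%.

The package therefore keeps the Poisson point estimates and swaps in a
covariance estimator that is consistent under an arbitrary variance law:

* **HC3 sandwich.** With response residuals $e_i = y_i - \hat\mu_i$ and
  leverages $h_{ii}$, the diagonal of $H = X(X^\top W X)^{-1} X^\top W$,

  $$\widehat{\mathrm{Cov}}(\hat\beta) =
    (X^\top W X)^{-1} \; X^\top \mathrm{diag}\!\left\{
    \left(\frac{e_i}{1 - h_{ii}}\right)^{\!2}\right\} X \;
    (X^\top W X)^{-1}.$$

  The outer factors (the "bread") are the inverse information; the middle
  (the "meat") estimates $X^\top \mathrm{Var}(y) X$ empirically. The
  $(1-h_{ii})^{-2}$ scaling is the HC3 small-sample correction: squared
  residuals are biased downward at high-leverage points, and HC3 inflates
  them accordingly, which matters at the modest sample sizes typical of
  microbiome studies. Setting the correction to zero recovers the plain
  HC0 sandwich; since $0 < h_{ii} < 1$, HC3 standard errors dominate HC0
  elementwise, a property the tests assert.

* **Case-resampling bootstrap.** Whole rows $(y_i, X_i, o_i)$ are resampled
  with replacement; the model is refitted on each of $B$ resamples; the
  empirical covariance (denominator $B-1$) of the $B$ coefficient vectors
  estimates $\mathrm{Cov}(\hat\beta)$. Resampling cases rather than
  residuals keeps the method free of any variance-model assumption.
  Intervals are Wald-type using the bootstrap standard error — the
  procedure estimates a covariance, not quantiles — so no percentile or
  BCa machinery is involved.

Both estimate the same asymptotic covariance; the tests check they agree
within ~10% at $B = 4000$ on a fixed overdispersed dataset. The sandwich is
hundreds of times cheaper; the bootstrap generalises to settings without a
closed-form sandwich.

Two comparator baselines are included. The **quasi-Poisson** model assumes
$\mathrm{Var}(Y) = \phi\mu$ and scales the model covariance by the Pearson
estimate $\hat\phi = \sum_i e_i^2/\hat\mu_i/(n-p)$; it is well calibrated
when the variance really is proportional to the mean, but under a quadratic
variance law it averages the dispersion across the mean range — too much
where $\mu$ is small, too little where $\mu$ is large — which inflates its
standard errors and costs power when effects are large. The **negative
binomial** (NB2, $\mathrm{Var} = \mu + \mu^2/r$) is a full likelihood model
fitted by alternating Fisher scoring for $\beta$ with one-dimensional
profile maximisation in $\log r$; it is efficient when its variance law is
right and miscalibrated when not (e.g. underdispersed data).

## Inference conventions

Wald statistics use a standard normal reference for the model-based
Poisson, sandwich, bootstrap and negative binomial estimators, and a
$t_{n-p}$ reference for quasi-Poisson, matching the long-standing software
conventions for those estimators (GLM z-tests vs quasi-likelihood t-tests).
At $n = 200$, $t_{198}$ and the normal are nearly indistinguishable, so
this choice does not drive any of the calibration results. Rejection at
level $\alpha$ is equivalent to the $(1-\alpha)$ interval excluding zero,
which ties the type I error and coverage columns of the benchmark together
exactly: for a null parameter, rejection rate $= 1 -$ coverage.

Multiplicity across taxa is handled by Benjamini–Hochberg step-up
adjustment (`stats::p.adjust`), applied across the taxa tested for one
exposure. Note that BH adjustment is *not* idempotent for distinct adjusted
values — re-adjusting already-adjusted p-values multiplies by $m/\mathrm{rank}$
again — so adjusted values must be computed once from the raw p-values.

## The simulation engine

The calibration study draws single-taxon datasets of size $n = 200$ with a
fixed balanced binary covariate (exactly 100 zeros and 100 ones — a fixed
design matches the stated exact 50/50 split and removes the possibility of
a degenerate replicate) and responses from five generators sharing the mean
$\mu_i = \exp(\beta_0 + \beta_1 x_i)$ with $\beta_0 = 2$ and
$\beta_1 \in \{0, 0.1, 1.5\}$ (no, small, large effect):

| family | law | Var at $\mu$ | dispersion regime |
|---|---|---|---|
| `gamma_misspec` | Gamma$(k=\mu^{1.5}, \theta=\mu^{-0.5})$ | $\mu^{0.5}$ | under-dispersed ($\mu > 1$) |
| `poisson` | Poisson$(\mu)$ | $\mu$ | correctly specified |
| `pareto` | Pareto I$(\gamma = 5, x_m = 0.8\mu)$ | $\mu^2/15$ | heavy-tailed |
| `od_poisson` | NB with size $= \mu$ | $2\mu$ | mildly over-dispersed |
| `negbin` | NB with size $= 0.1$ | $10\mu^2 + \mu$ | heavily over-dispersed |

Gamma and Pareto draws are continuous and deliberately *not* rounded:
rounding would break the stated variance laws, and the Poisson quasi-score
is well defined for any real $y \ge 0$. The Pareto sampler uses the inverse
CDF $x_m U^{-1/\gamma}$. The `od_poisson` family uses a per-observation NB
size equal to $\mu_i$, which gives $\mathrm{Var} = \mu + \mu^2/\mu = 2\mu$
exactly. Moment tests assert each family's mean and variance at $10^5$
draws within four Monte-Carlo standard errors.

Each benchmark cell runs 500 replicates; per-replicate seeds are derived
deterministically from the cell seed (and cell seeds from the master seed),
so any replicate is reproducible in isolation and parallel execution cannot
reorder streams. Replicate-level metrics follow the standard definitions:
bias, empirical standard error (SEE, the $N-1$ sample SD of the estimates),
mean estimated standard error (SEM), MSE, coverage of the 95% interval, and
the rejection rate at $\alpha = 0.05$. The identity
$\mathrm{MSE} = \mathrm{bias}^2 + \mathrm{SEE}^2 (N-1)/N$ is asserted as an
algebraic property. Because all Poisson-based methods share the identical
point estimates within a replicate — and the NB2 MLE coincides with the
Poisson quasi-MLE on a saturated two-group design — the bias/SEE/MSE rows
of any benchmark table are constant across methods, which is a useful
structural self-check.

```{r cell, eval = FALSE}
# one benchmark cell: heavy overdispersion, null effect
cell <- run_cell("negbin", beta0 = 2, beta1 = 0,
                 methods = c("poisson_naive", "sandwich_hc3"),
                 n = 200, n_reps = 500, seed = 1)
cell[cell$parameter == "x", c("method", "see", "sem", "cp", "rejection_rate")]
```

## The multi-taxon generator

The differential-abundance pipeline is exercised on a fully parametric
multi-taxon generator: $T$ taxa $\times$ $S$ samples of negative binomial
counts with mean $d_s\, c_t \exp(b_t x_s)$, a uniform$(0,1)$ covariate
$x_s$, log-normal baselines $c_t$ across taxa, log-normal depth factors
$d_s$ across samples, and slope $b_t$ equal to `effect` for a chosen
fraction of taxa (the signal set, returned as truth labels) and zero
otherwise. Template-resampling simulators that mimic a specific real
dataset need that dataset; this generator instead reproduces the design's
*structure* — 400 samples, 100 taxa, 10%/30% signal densities, sparsity,
overdispersion and uneven depth. Defaults chosen once: NB size 0.5 (strong
overdispersion of the kind that defeats naive Poisson inference), baseline
meanlog 3 / sdlog 1.5 (abundances spanning several orders of magnitude with
a realistic zero fraction), depth sdlog 0.3 (moderate library-size
variation), effect 1 (a detectable log-fold change at these sample sizes).

What passing tests on this generator do and do not show: they demonstrate
that the pipeline controls false discoveries and ranks signal taxa
correctly under log-normal-NB data with independent taxa; they do not
demonstrate robustness to taxon-taxon correlation, zero inflation beyond
what NB sparsity produces, or compositional effects, none of which the
generator emulates. Results on real microbiome data depend on those
features.

## The per-taxon pipeline

`fit_all_taxa()` fits each retained taxon's counts on the exposure and
adjustment covariates with offset $\log(\text{library size})$ — total-sum
scaling, so coefficients act on relative abundance. Library sizes are the
column sums of the *unfiltered* count matrix: the offset should reflect
total sequencing depth, not the depth of the taxa that happened to survive
filtering. Taxa with prevalence (fraction of samples with a nonzero count)
below the threshold are dropped before fitting; 5% and 10% are typical
thresholds. A doubling of all counts shifts every offset by $\log 2$ and
leaves estimates and p-values unchanged — the TSS-invariance property the
tests assert.

Taxa that are all-zero across samples cannot be fitted (the intercept
initialisation is the log of the mean response) and are expected to be
removed by any positive prevalence threshold; taxa that are zero in only
one exposure group are still fitted, and complete-separation failures
surface as non-converged `NA` rows, which are excluded from the BH family
rather than silently dropped.

## Numerical choices

* **IRLS.** The update is the standard Fisher-scoring increment
  $\beta_{k+1} = \beta_k + (X^\top W_k X)^{-1} X^\top (y - \mu_k)$,
  initialised with the intercept at $\log \bar y$ (offset-centred) and
  other coefficients at zero; convergence when
  $\lVert \beta_{k+1} - \beta_k \rVert_2 < 10^{-8}$, at most 50 iterations.
  A step-halving guard handles overshoot into non-finite means. At
  convergence the score residual $\lVert X^\top(y-\hat\mu)\rVert_\infty$ is
  below $10^{-6}$ on all well-conditioned test fits.
* **Leverages.** Computed from the printed non-symmetric GLM form
  $X(X^\top W X)^{-1}X^\top W$; its diagonal equals that of the symmetric
  $W^{1/2}$ form, and $\mathrm{trace}(H) = p$ to $10^{-8}$ is asserted on
  every fit. An exact-leverage point ($h_{ii} = 1$) makes HC3 divide by
  zero and raises an error naming the observation.
* **Bootstrap degeneracy.** A resample whose design collapses (e.g. one
  covariate level vanishes) or whose response is all zero is discarded and
  redrawn, with the count recorded; more than 10% degenerate draws aborts
  the estimator. On the fixed balanced design of the benchmark this path
  is never hit; it matters for small or unbalanced real datasets.
* **Quasi-Poisson dispersion** uses the Pearson estimator with $n-p$
  denominator, the quasi-likelihood convention.
* **NB boundary.** If the profile likelihood pushes the size $r$ beyond
  $10^8$ (equidispersion boundary), the fit falls back to the Poisson
  model-based covariance with a warning. Non-integer responses are accepted
  with a warning, evaluating the gamma-function log-likelihood at real $y$
  as a quasi-likelihood — the behaviour needed for the continuous Gamma and
  Pareto simulation arms.
* **Problem sizes in the shipped tests.** The acceptance tests run the
  non-bootstrap cells at the full 500-replicate scale and the bootstrap
  cells at a reduced $B = 200$ smoke scale with a correspondingly wider
  tolerance; `scripts/acceptance.R` runs the bootstrap cells at the full
  $B = 1000$. These sizes were chosen to keep the whole suite within a
  desk-scale run while leaving Monte-Carlo error well inside the asserted
  tolerances.

## Known limitations

* The framework assumes the log-linear mean is correctly specified;
  robust covariances do not repair a wrong mean model.
* Observations are assumed independent: no longitudinal or clustered
  correlation structure (a GEE-style working-correlation sandwich would be
  the natural extension).
* Zero inflation beyond what the count law produces is not modelled;
  heavily zero-inflated taxa are better handled by prevalence filtering or
  zero-inflated mixtures.
* The `simulate()` method draws from the working Poisson law at the fitted
  means, so simulated counts under-disperse relative to overdispersed data;
  it is a convenience, not a parametric bootstrap of the true law.
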