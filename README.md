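# robustpois

Robust variance estimation for Poisson regression of microbiome abundance
counts.

## The problem

Differential abundance analysis asks, taxon by taxon, whether microbial read
counts are associated with an exposure or condition. Microbiome counts are
right-skewed and heteroscedastic: the variance of a taxon's counts usually
grows faster (sometimes slower) than its mean, so the Poisson law
Var(Y) = E(Y) is almost always wrong. The key observation this package
builds on is that the two halves of the inference problem fail differently:

* the **point estimates** of a Poisson log-linear regression,
  log μᵢ = oᵢ + Xᵢᵀβ, stay consistent as long as the log-linear *mean* is
  right, whatever the variance law;
* the **model-based standard errors** (XᵀWX)⁻¹ do not — they understate the
  sampling variability under overdispersion (inflating the type I error)
  and overstate it under underdispersion (wasting power).

`robustpois` therefore fits the mean by Poisson iteratively reweighted least
squares (IRLS) and replaces the covariance of β̂ with a robust estimate:

* **HC3 sandwich**:
  Cov(β̂) = (XᵀWX)⁻¹ Xᵀ diag{(eᵢ/(1−hᵢᵢ))²} X (XᵀWX)⁻¹,
  with response residuals eᵢ = yᵢ − μ̂ᵢ, working weights W = diag(μ̂) and
  hat-matrix leverages hᵢᵢ; the (1−hᵢᵢ)⁻² factor is the small-sample HC3
  correction;
* **case-resampling bootstrap**: rows of (y, X, offset) are resampled with
  replacement, the model refitted B times (default 1000), and the empirical
  covariance of the B coefficient vectors used.

The model-based Poisson, quasi-Poisson (Pearson-dispersion-scaled, t(n−p)
reference) and negative binomial NB2 maximum-likelihood estimators are
included as comparators, a five-distribution simulation engine reproduces
the calibration study that validates the approach, and a per-taxon pipeline
applies it to count tables with log-library-size (total-sum-scaling)
offsets, prevalence filtering and Benjamini–Hochberg adjustment.

## A worked example

Counts with quadratic overdispersion (negative binomial, Var = 10μ² + μ)
and a modest true effect, n = 200:

```r
library(robustpois)
d <- sim_dataset(n = 200, beta0 = 2, beta1 = 0.4, family = "negbin", seed = 7)
summary(robpois(y ~ x, data = d, se.method = "poisson_naive"))
#>             Estimate Std. Error z value  Pr(>|z|)
#> (Intercept) 2.256541   0.032359  69.734 < 2.2e-16 ***
#> x           0.490730   0.041087  11.944 < 2.2e-16 ***

summary(robpois(y ~ x, data = d, se.method = "sandwich_hc3"))
#>             Estimate Std. Error z value Pr(>|z|)
#> (Intercept)  2.25654    0.25695   8.782   <2e-16 ***
#> x            0.49073    0.37718   1.301   0.1932
```

The two fits share the same coefficients (the quasi-MLE), but the naive
Poisson standard error for the slope (0.041) is an order of magnitude too
small for data this overdispersed — it would declare overwhelming
significance for any slope of this size. The HC3 sandwich standard error
(0.377) reflects the actual sampling variability: a single n = 200 dataset
from this generator carries little information about a log-fold change of
0.4, and the honest p-value is 0.19. In the simulation study this difference
is exactly what turns an 83% type I error (naive) into 5.6% (sandwich) under
the same generator with a null slope.

The per-taxon pipeline on a counts + metadata pair (synthetic example data
ship with the package):

```r
study <- read_abundance(system.file("extdata", "synthetic_counts.tsv", package = "robustpois"),
                        system.file("extdata", "synthetic_metadata.tsv", package = "robustpois"))
res <- fit_all_taxa(study, exposure = "x", method = "sandwich_hc3", prevalence = 0.05)
head(res[order(res$p_bh), c("taxon", "estimate", "se", "p", "p_bh")])
```

Command-line wrappers for the pipeline and the simulation benchmark live in
`inst/cli/` (`dafit.R`, `benchmark.R`).

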