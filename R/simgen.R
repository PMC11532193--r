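#' Balanced binary covariate for the single-taxon simulations
#'
#' Fixed design with exactly `n/2` zeros followed by `n/2` ones. A fixed
#' balanced design (rather than Bernoulli draws) guarantees the stated exact
#' 50/50 split in every replicate and rules out degenerate replicates in
#' which one group is empty.
#'
#' @param n even sample size.
#' @return integer vector of `n/2` zeros then `n/2` ones.
#' @examples
#' sim_covariate(4)  # 0 0 1 1
#' @export
sim_covariate <- function(n) {
  n <- as.integer(n)
  if (n < 2L || n %% 2L != 0L) stop("n must be an even integer >= 2")
  rep(0:1, each = n %/% 2L)
}

#' Families available to the response generator
#' @return character vector of family names.
#' @export
sim_families <- function() {
  c("gamma_misspec", "poisson", "pareto", "od_poisson", "negbin")
}

#' Draw responses under one of five mean-variance laws
#'
#' All five generators share the log-linear mean
#' \eqn{\mu_i = \exp(\beta_0 + \beta_1 x_i)} but differ in their variance:
#'
#' * `gamma_misspec`: Gamma with shape \eqn{k = \mu^{1.5}}, scale
#'   \eqn{\theta = \mu^{-0.5}}, so \eqn{Var = \mu^{0.5}} (under-dispersed for
#'   \eqn{\mu > 1}); continuous.
#' * `poisson`: Poisson(\eqn{\mu}), \eqn{Var = \mu} (the correctly specified
#'   case).
#' * `pareto`: Pareto Type I with shape \eqn{\gamma = 5} and scale
#'   \eqn{x_m = 0.8\mu}, drawn by inverse CDF \eqn{x_m U^{-1/\gamma}}; mean
#'   \eqn{\mu}, \eqn{Var = \mu^2/15}; continuous, heavy-tailed, support
#'   \eqn{[x_m, \infty)}.
#' * `od_poisson`: negative binomial with per-observation size \eqn{r_i =
#'   \mu_i}, so \eqn{Var = \mu + \mu^2/\mu = 2\mu} (mildly over-dispersed).
#' * `negbin`: negative binomial with size \eqn{r = 0.1}, so
#'   \eqn{Var = 10\mu^2 + \mu} (heavy quadratic over-dispersion, mimicking
#'   highly variable taxa).
#'
#' Gamma and Pareto draws are kept continuous — rounding would break the
#' stated variance laws — and the Poisson quasi-score fitter accepts them.
#'
#' @param x covariate vector (typically from [sim_covariate()]).
#' @param beta0,beta1 intercept and slope of the log-linear mean.
#' @param family one of [sim_families()].
#' @return numeric response vector of `length(x)`.
#' @export
sim_response <- function(x, beta0, beta1,
                         family = c("gamma_misspec", "poisson", "pareto",
                                    "od_poisson", "negbin")) {
  family <- match.arg(family)
  mu <- exp(beta0 + beta1 * x)
  n <- length(x)
  switch(family,
    gamma_misspec = stats::rgamma(n, shape = mu^1.5, scale = mu^-0.5),
    poisson = stats::rpois(n, lambda = mu),
    pareto = (0.8 * mu) * stats::runif(n)^(-1 / 5),
    od_poisson = stats::rnbinom(n, size = mu, mu = mu),
    negbin = stats::rnbinom(n, size = 0.1, mu = mu)
  )
}

#' One single-taxon simulation dataset
#'
#' Convenience wrapper binding [sim_covariate()] and [sim_response()] into a
#' data frame, optionally written as TSV.
#'
#' @inheritParams sim_response
#' @param n even sample size (the study design uses 200).
#' @param seed optional integer seed.
#' @param file optional path; when given, the data frame is written as
#'   tab-separated `y`, `x` columns.
#' @return data frame with columns `y` and `x`.
#' @export
sim_dataset <- function(n = 200L, beta0 = 2, beta1 = 0,
                        family = "gamma_misspec", seed = NULL, file = NULL) {
  if (!is.null(seed)) set.seed(seed)
  x <- sim_covariate(n)
  y <- sim_response(x, beta0, beta1, family)
  d <- data.frame(y = y, x = x)
  if (!is.null(file))
    utils::write.table(d, file, sep = "\t", quote = FALSE, row.names = FALSE)
  d
}

#' Parametric multi-taxon count generator for pipeline testing
#'
#' Generates a taxa-by-samples integer count matrix in which a chosen
#' fraction of taxa are truly associated with a uniform(0, 1) covariate and
#' the rest are null, with known truth labels for FDR/TPR scoring. Per taxon
#' `t` and sample `s`, counts are negative binomial with mean
#' \deqn{\mu_{ts} = d_s \, c_t \, \exp(b_t x_s),}
#' where baseline abundances \eqn{c_t} are log-normal across taxa, sample
#' depth factors \eqn{d_s} are log-normal across samples, and the log-mean
#' slope \eqn{b_t} equals `effect` for signal taxa and 0 otherwise. This is a
#' fully parametric stand-in for template-resampling simulators that require
#' a real reference dataset; it reproduces the design's structure (signal
#' fraction, uniform covariate, sparsity and over-dispersion) but not the
#' taxon-specific abundance profile of any particular study.
#'
#' @param n_samples,n_taxa dimensions of the count matrix (defaults 400 and
#'   100, the multi-taxon study design).
#' @param signal_fraction fraction of taxa associated with the covariate
#'   (0.1 and 0.3 are the low/high signal-density designs).
#' @param effect log-mean slope of signal taxa on the uniform covariate.
#' @param dispersion negative binomial size parameter shared by all taxa;
#'   smaller is more over-dispersed.
#' @param baseline_meanlog,baseline_sdlog log-normal parameters of the
#'   across-taxa baseline abundances.
#' @param depth_sdlog log-normal spread of per-sample depth factors.
#' @param seed optional integer seed.
#' @return list with `counts` (n_taxa x n_samples integer matrix with taxon
#'   and sample names), `metadata` (data frame with `sample` and covariate
#'   `x`), and `truth` (logical length-`n_taxa`; `TRUE` for signal taxa — the
#'   first `round(signal_fraction * n_taxa)` taxa).
#' @export
sim_multitaxon <- function(n_samples = 400L, n_taxa = 100L,
                           signal_fraction = 0.1, effect = 1,
                           dispersion = 0.5,
                           baseline_meanlog = 3, baseline_sdlog = 1.5,
                           depth_sdlog = 0.3, seed = NULL) {
  if (signal_fraction < 0 || signal_fraction > 1)
    stop("signal_fraction must lie in [0, 1]")
  if (!is.null(seed)) set.seed(seed)
  n_sig <- round(signal_fraction * n_taxa)
  truth <- c(rep(TRUE, n_sig), rep(FALSE, n_taxa - n_sig))
  x <- stats::runif(n_samples)
  depth <- exp(stats::rnorm(n_samples, 0, depth_sdlog))
  baseline <- exp(stats::rnorm(n_taxa, baseline_meanlog, baseline_sdlog))
  slope <- ifelse(truth, effect, 0)
  mu <- outer(baseline, depth) * exp(outer(slope, x))
  counts <- matrix(
    stats::rnbinom(n_taxa * n_samples, size = dispersion, mu = mu),
    nrow = n_taxa
  )
  rownames(counts) <- sprintf("taxon_%03d", seq_len(n_taxa))
  colnames(counts) <- sprintf("sample_%03d", seq_len(n_samples))
  list(
    counts = counts,
    metadata = data.frame(sample = colnames(counts), x = x),
    truth = truth
  )
}
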