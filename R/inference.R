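#' Two-sided Wald test and confidence interval
#'
#' Forms the statistic `estimate / se`, a two-sided p-value and the symmetric
#' `level` confidence interval `estimate +/- q * se`, where `q` is the
#' `1 - (1 - level)/2` quantile of the reference distribution. The standard
#' normal reference is used for the model-based Poisson, sandwich, bootstrap
#' and negative binomial estimators; quasi-Poisson inference conventionally
#' uses a t reference with `n - p` degrees of freedom (`df` finite).
#'
#' @param estimate coefficient estimate.
#' @param se its standard error; must be positive.
#' @param level confidence level in (0, 1), default 0.95.
#' @param df degrees of freedom of the t reference; `Inf` (default) selects
#'   the standard normal.
#' @return a list of class `"wald_test"` with `estimate`, `se`, `statistic`,
#'   `p_value`, `ci_lower`, `ci_upper`, `level`, `df`.
#' @examples
#' wald_test(0.1, 0.0303)
#' @export
wald_test <- function(estimate, se, level = 0.95, df = Inf) {
  if (any(se <= 0)) stop("se must be positive")
  if (level <= 0 || level >= 1) stop("level must be in (0, 1)")
  z <- estimate / se
  p <- if (is.finite(df)) 2 * stats::pt(-abs(z), df = df) else 2 * stats::pnorm(-abs(z))
  q <- if (is.finite(df)) stats::qt(1 - (1 - level) / 2, df = df) else stats::qnorm(1 - (1 - level) / 2)
  structure(
    list(estimate = estimate, se = se, statistic = z, p_value = p,
         ci_lower = estimate - q * se, ci_upper = estimate + q * se,
         level = level, df = df),
    class = "wald_test"
  )
}

#' @export
print.wald_test <- function(x, ...) {
  cat(sprintf("Wald test: estimate %.4g (SE %.4g), z = %.3f, p = %.3g\n",
              x$estimate, x$se, x$statistic, x$p_value))
  cat(sprintf("%d%% CI: [%.4g, %.4g]\n", round(100 * x$level),
              x$ci_lower, x$ci_upper))
  invisible(x)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment across a family of tests, as
#' applied across taxa in the differential-abundance pipeline. Thin wrapper
#' around [stats::p.adjust()] with input validation; `NA` entries are
#' preserved and excluded from the family size.
#'
#' @param p numeric vector of raw p-values in \[0, 1\] (`NA` allowed).
#' @return adjusted p-values, same length and order as `p`.
#' @export
bh_adjust <- function(p) {
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}
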