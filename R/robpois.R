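#' Poisson regression with robust variance estimation
#'
#' The main fitting function. Estimates a Poisson log-linear model of a
#' count (or non-negative) response on covariates by IRLS — the point
#' estimates are consistent whenever the log-linear mean is correct, even if
#' the variance law is not Poisson — and pairs them with a covariance
#' estimator chosen for robustness to that misspecification:
#'
#' * `"sandwich_hc3"` (default): heteroscedasticity-consistent HC3 sandwich,
#'   see [vcov_hc3()];
#' * `"bootstrap"`: case-resampling bootstrap, see [vcov_bootstrap()];
#' * `"poisson_naive"`: the model-based inverse information (correct only
#'   under equidispersion);
#' * `"quasipoisson"`: Pearson-dispersion-scaled model covariance, with
#'   t(n-p) reference for inference;
#' * `"negbin"`: the negative binomial NB2 maximum-likelihood baseline (its
#'   own fit, see [negbin_fit()]).
#'
#' @param formula model formula for the response and covariates.
#' @param data data frame in which to evaluate `formula`.
#' @param offset optional log-scale offset vector (e.g. `log(library_size)`
#'   for total-sum scaling); may also be given via `offset()` in the formula.
#' @param se.method covariance estimator, one of [benchmark_methods()].
#' @param B bootstrap resamples when `se.method = "bootstrap"`.
#' @param seed optional seed for the bootstrap resampling.
#' @param level confidence level used by [summary.robpois()] and
#'   [confint.robpois()].
#' @param tol,max_iter IRLS control, see [irls_fit()].
#' @return an object of class `"robpois"`: the `"pois_irls"` fit augmented
#'   with `vcov_result`, `se.method`, `df` (inference reference degrees of
#'   freedom), `level`, `call`, `terms` and, for the negative binomial
#'   method, the size estimate `nb_size`.
#' @examples
#' d <- sim_dataset(100, beta0 = 2, beta1 = 0.5, family = "od_poisson", seed = 1)
#' m <- robpois(y ~ x, data = d)
#' summary(m)
#' @export
robpois <- function(formula, data, offset = NULL,
                    se.method = c("sandwich_hc3", "bootstrap",
                                  "poisson_naive", "quasipoisson", "negbin"),
                    B = 1000L, seed = NULL, level = 0.95,
                    tol = 1e-8, max_iter = 50L) {
  se.method <- match.arg(se.method)
  mf <- stats::model.frame(formula, data = data)
  y <- stats::model.response(mf)
  X <- stats::model.matrix(attr(mf, "terms"), mf)
  n <- nrow(X)
  moff <- stats::model.offset(mf)
  if (is.null(offset)) offset <- moff
  if (is.null(offset)) offset <- numeric(n)

  if (se.method == "negbin") {
    nb <- negbin_fit(y, X, offset = offset, tol = tol)
    fit <- nb$fit
    vc <- nb$vcov
    r <- nb$r
  } else {
    fit <- irls_fit(y, X, offset = offset, tol = tol, max_iter = max_iter)
    vc <- switch(se.method,
      sandwich_hc3 = vcov_hc3(fit),
      poisson_naive = vcov_naive(fit),
      quasipoisson = vcov_quasipoisson(fit),
      bootstrap = vcov_bootstrap(y, X, offset = offset, B = B, seed = seed,
                                 tol = tol, max_iter = max_iter)
    )
    r <- NULL
  }
  fit$vcov_result <- vc
  fit$se.method <- se.method
  fit$df <- if (se.method == "quasipoisson") n - ncol(X) else Inf
  fit$level <- level
  fit$call <- match.call()
  fit$terms <- attr(mf, "terms")
  fit$nb_size <- r
  class(fit) <- c("robpois", "pois_irls")
  fit
}

#' @export
vcov.robpois <- function(object, ...) object$vcov_result$cov

#' @export
print.robpois <- function(x, ...) {
  cat("Robust Poisson log-linear model (", x$se.method, " covariance)\n",
      sep = "")
  cat("Call: ", deparse(x$call), "\n")
  cat("Coefficients:\n")
  print(x$coefficients)
  if (!x$converged) cat("Warning: IRLS did not converge\n")
  invisible(x)
}

#' @export
summary.robpois <- function(object, level = object$level, ...) {
  se <- object$vcov_result$se
  w <- wald_test(object$coefficients, se, level = level, df = object$df)
  tab <- cbind(
    Estimate = object$coefficients,
    `Std. Error` = se,
    `z value` = w$statistic,
    `Pr(>|z|)` = w$p_value,
    Lower = w$ci_lower,
    Upper = w$ci_upper
  )
  out <- list(call = object$call, coefficients = tab,
              se.method = object$se.method, level = level,
              df = object$df, converged = object$converged,
              n_iter = object$n_iter, nb_size = object[["nb_size"]],
              meta = object$vcov_result$meta)
  class(out) <- "summary.robpois"
  out
}

#' @export
print.summary.robpois <- function(x, ...) {
  cat("Robust Poisson log-linear model\n")
  cat("Call: ", deparse(x$call), "\n")
  cat("Covariance method:", x$se.method)
  if (is.finite(x$df)) cat("  (t reference, df =", x$df, ")")
  cat("\n\n")
  stats::printCoefmat(x$coefficients[, 1:4, drop = FALSE],
                      P.values = TRUE, has.Pvalue = TRUE)
  cat(sprintf("\n%d%% confidence intervals:\n", round(100 * x$level)))
  print(x$coefficients[, 5:6, drop = FALSE])
  if (!is.null(x$nb_size)) cat("\nNB size estimate:", format(x$nb_size), "\n")
  if (!is.null(x$meta$phi)) cat("\nDispersion estimate:", format(x$meta$phi), "\n")
  if (!x$converged) cat("\nWarning: fit did not converge\n")
  invisible(x)
}

#' @export
confint.robpois <- function(object, parm, level = 0.95, ...) {
  se <- object$vcov_result$se
  w <- wald_test(object$coefficients, se, level = level, df = object$df)
  ci <- cbind(w$ci_lower, w$ci_upper)
  rownames(ci) <- names(object$coefficients)
  colnames(ci) <- sprintf("%.1f %%", 100 * c((1 - level) / 2, 1 - (1 - level) / 2))
  if (!missing(parm)) ci <- ci[parm, , drop = FALSE]
  ci
}

#' Predict from a robust Poisson fit
#'
#' @param object a `"robpois"` fit.
#' @param newdata optional data frame of covariates; the fitting data's
#'   design is reused when omitted.
#' @param type `"response"` for fitted means, `"link"` for the linear
#'   predictor.
#' @param offset optional log-scale offset for `newdata` (defaults to zero;
#'   the original offsets are used when `newdata` is omitted).
#' @param ... unused.
#' @return numeric vector of predictions.
#' @export
predict.robpois <- function(object, newdata = NULL,
                            type = c("response", "link"), offset = NULL, ...) {
  type <- match.arg(type)
  if (is.null(newdata)) {
    eta <- object$offset + drop(object$X %*% object$coefficients)
  } else {
    X <- stats::model.matrix(stats::delete.response(object$terms), newdata)
    if (is.null(offset)) offset <- numeric(nrow(X))
    eta <- offset + drop(X %*% object$coefficients)
  }
  if (type == "link") eta else exp(eta)
}

#' Simulate responses from a fitted robust Poisson model
#'
#' Draws Poisson responses at the fitted means. Note this uses the working
#' Poisson law; when the data are over-dispersed the simulated counts will
#' be less variable than the originals.
#'
#' @param object a `"robpois"` fit.
#' @param nsim number of simulated response vectors.
#' @param seed optional seed.
#' @param ... unused.
#' @return data frame with `nsim` columns, as [stats::simulate()].
#' @export
simulate.robpois <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  n <- length(object$mu)
  out <- as.data.frame(
    matrix(stats::rpois(n * nsim, rep(object$mu, nsim)), n, nsim)
  )
  names(out) <- paste0("sim_", seq_len(nsim))
  out
}

#' Residual diagnostics plot
#'
#' Pearson residuals against fitted means on a log mean axis; a horizontal
#' spread widening with the mean indicates variance growing faster than the
#' Poisson law, the regime the robust covariance estimators address.
#'
#' @param x a `"robpois"` fit.
#' @param ... further arguments passed to [plot()].
#' @return `x`, invisibly.
#' @export
plot.robpois <- function(x, ...) {
  r <- x$residuals / sqrt(x$mu)
  graphics::plot(x$mu, r, log = "x", xlab = "fitted mean (log scale)",
                 ylab = "Pearson residual", ...)
  graphics::abline(h = 0, lty = 2)
  invisible(x)
}
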