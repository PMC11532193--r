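#' @title Covariance estimators for Poisson IRLS coefficients
#' @description Internal constructor for covariance results shared by all
#'   estimators. Each estimator returns a `"robpois_vcov"` object carrying the
#'   method label, the p x p covariance matrix, the per-coefficient standard
#'   errors and a method-specific `meta` record.
#' @keywords internal
#' @noRd
new_vcov <- function(method, cov, meta = list()) {
  cov <- (cov + t(cov)) / 2
  se <- sqrt(pmax(diag(cov), 0))
  names(se) <- colnames(cov)
  structure(
    list(method = method, cov = cov, se = se, meta = meta),
    class = "robpois_vcov"
  )
}

#' @export
print.robpois_vcov <- function(x, ...) {
  cat("Coefficient covariance (method: ", x$method, ")\n", sep = "")
  cat("Standard errors:\n")
  print(x$se)
  invisible(x)
}

xtwx_inverse <- function(fit, X) {
  xtwx <- crossprod(X, X * fit$weights)
  tryCatch(
    solve(xtwx),
    error = function(e) stop("information matrix X'WX is singular", call. = FALSE)
  )
}

#' Model-based (naive) Poisson covariance
#'
#' The inverse Fisher information \eqn{(X^T W X)^{-1}} at the converged
#' weights. Correct only when the response variance actually equals the mean;
#' under- or over-states the true sampling variability otherwise.
#'
#' @param fit a converged `"pois_irls"` fit.
#' @param X the design matrix used in the fit (defaults to `fit$X`).
#' @return a `"robpois_vcov"` object with `method = "poisson_naive"`.
#' @export
vcov_naive <- function(fit, X = fit$X) {
  stopifnot(inherits(fit, "pois_irls"))
  X <- as.matrix(X)
  cov <- xtwx_inverse(fit, X)
  dimnames(cov) <- list(colnames(X), colnames(X))
  new_vcov("poisson_naive", cov)
}

#' HC3 sandwich covariance for a Poisson fit
#'
#' Heteroscedasticity-consistent covariance with the small-sample HC3 leverage
#' correction:
#' \deqn{\widehat{Cov}(\hat\beta) = (X^T W X)^{-1} \, X^T
#'   \mathrm{diag}\{(e_i / (1 - h_{ii}))^2\} X \, (X^T W X)^{-1},}
#' where \eqn{e_i = y_i - \mu_i} are response residuals and \eqn{h_{ii}} the
#' hat-matrix leverages. Consistent for the true covariance of the Poisson
#' quasi-MLE whenever the log-linear mean is correct, regardless of the
#' variance law; the \eqn{(1-h_{ii})^{-2}} scaling counteracts the downward
#' bias of squared residuals at high-leverage points in small samples.
#'
#' @inheritParams vcov_naive
#' @param hc0 logical; if `TRUE` omit the leverage correction (plain HC0
#'   sandwich). Mainly for internal consistency checks.
#' @return a `"robpois_vcov"` object with `method = "sandwich_hc3"` (or
#'   `"sandwich_hc0"`).
#' @export
vcov_hc3 <- function(fit, X = fit$X, hc0 = FALSE) {
  stopifnot(inherits(fit, "pois_irls"))
  X <- as.matrix(X)
  h <- fit$leverages
  if (!hc0 && any(h >= 1 - 1e-12)) {
    stop("leverage h_ii = 1 at observation(s) ",
         paste(which(h >= 1 - 1e-12), collapse = ", "),
         ": HC3 correction divides by zero")
  }
  e <- fit$residuals
  scaled <- if (hc0) e else e / (1 - h)
  bread <- xtwx_inverse(fit, X)
  meat <- crossprod(X * scaled)
  cov <- bread %*% meat %*% bread
  dimnames(cov) <- list(colnames(X), colnames(X))
  new_vcov(if (hc0) "sandwich_hc0" else "sandwich_hc3", cov)
}

#' Nonparametric bootstrap covariance for Poisson coefficients
#'
#' Case-resampling bootstrap: whole rows of `(y, X, offset)` are resampled
#' jointly with replacement, the Poisson IRLS fit is repeated on each
#' resample, and the empirical covariance (denominator `B - 1`) of the `B`
#' coefficient vectors is returned. Resamples on which the fit is degenerate
#' (rank-deficient design, e.g. a binary covariate collapsing to one level,
#' or an all-zero response) are discarded and redrawn; if more than 10% of
#' draws are degenerate the estimator aborts.
#'
#' @param y,X,offset the data, as for [irls_fit()].
#' @param B number of bootstrap resamples (default 1000).
#' @param seed optional integer seed making the resampling reproducible.
#' @param tol,max_iter IRLS settings for the per-resample fits.
#' @return a `"robpois_vcov"` object with `method = "bootstrap"`; `meta`
#'   records `B`, `seed` and `n_discarded`.
#' @export
vcov_bootstrap <- function(y, X, offset = NULL, B = 1000L, seed = NULL,
                           tol = 1e-8, max_iter = 50L) {
  X <- as.matrix(X)
  n <- nrow(X)
  p <- ncol(X)
  B <- as.integer(B)
  if (B < 2L) stop("B must be >= 2")
  if (is.null(offset)) offset <- numeric(n)
  if (!is.null(seed)) set.seed(seed)

  betas <- matrix(NA_real_, B, p)
  discarded <- 0L
  max_discard <- ceiling(0.1 * B)
  for (b in seq_len(B)) {
    repeat {
      idx <- sample.int(n, n, replace = TRUE)
      cf <- tryCatch(
        suppressWarnings(
          irls_core(y[idx], X[idx, , drop = FALSE], offset[idx], tol, max_iter)
        ),
        error = function(e) NULL
      )
      if (!is.null(cf)) break
      discarded <- discarded + 1L
      if (discarded > max_discard)
        stop("more than 10% of bootstrap resamples were degenerate; ",
             "the design is too fragile for case resampling")
    }
    betas[b, ] <- cf
  }
  cov <- stats::cov(betas)
  dimnames(cov) <- list(colnames(X), colnames(X))
  new_vcov("bootstrap", cov,
           meta = list(B = B, seed = seed, n_discarded = discarded))
}

# Lean IRLS returning only coefficients; errors on degeneracy. This is the
# inner loop of the bootstrap (B * n_reps fits in the simulation study), so it
# skips the bookkeeping of irls_fit.
irls_core <- function(y, X, offset, tol = 1e-8, max_iter = 50L) {
  if (all(y == 0)) stop("all-zero response")
  p <- ncol(X)
  beta <- numeric(p)
  beta[1L] <- log(mean(y)) - mean(offset)
  eta <- offset + drop(X %*% beta)
  mu <- exp(eta)
  for (iter in seq_len(max_iter)) {
    delta <- solve(crossprod(X, X * mu), crossprod(X, y - mu))
    beta <- beta + drop(delta)
    mu <- exp(offset + drop(X %*% beta))
    if (!all(is.finite(mu))) stop("divergent means")
    if (sqrt(sum(delta^2)) < tol) return(beta)
  }
  stop("no convergence")
}

#' Quasi-Poisson covariance
#'
#' Scales the model-based covariance by the Pearson dispersion estimate
#' \eqn{\hat\phi = \sum_i e_i^2/\mu_i / (n - p)}, the moment estimator under
#' the working variance law \eqn{V(Y) = \phi\mu}. Inference for this method
#' conventionally uses a t reference with `n - p` degrees of freedom.
#'
#' @inheritParams vcov_naive
#' @return a `"robpois_vcov"` object with `method = "quasipoisson"`; `meta`
#'   carries the dispersion estimate `phi`.
#' @export
vcov_quasipoisson <- function(fit, X = fit$X) {
  stopifnot(inherits(fit, "pois_irls"))
  X <- as.matrix(X)
  n <- nrow(X)
  p <- ncol(X)
  if (n <= p) stop("dispersion undefined: need n > p")
  phi <- sum(fit$residuals^2 / fit$mu) / (n - p)
  cov <- phi * xtwx_inverse(fit, X)
  dimnames(cov) <- list(colnames(X), colnames(X))
  new_vcov("quasipoisson", cov, meta = list(phi = phi, df = n - p))
}

#' Negative binomial (NB2) maximum-likelihood fit and covariance
#'
#' Baseline comparator: fits mean \eqn{\mu = \exp(o + X\beta)} with NB2
#' variance \eqn{\mu + \mu^2/r} by alternating Fisher scoring for \eqn{\beta}
#' (working weights \eqn{\mu/(1 + \mu/r)}) with one-dimensional maximisation
#' of the profile log-likelihood in \eqn{\log r}. The coefficient covariance
#' is the inverse expected information \eqn{(X^T \mathrm{diag}\{\mu/(1 +
#' \mu/r)\} X)^{-1}} at the converged \eqn{(\hat\beta, \hat r)} (\eqn{\beta}
#' and \eqn{r} are information-orthogonal in NB2).
#'
#' Non-integer responses are accepted with a warning: the gamma-function form
#' of the NB log-likelihood is evaluated at real \eqn{y}, acting as a
#' quasi-likelihood. If the profile likelihood pushes \eqn{r} to the
#' equidispersion boundary (`r > 1e8`) the fit falls back to the Poisson
#' model-based covariance with a warning.
#'
#' @inheritParams vcov_bootstrap
#' @param tol convergence tolerance on the coefficient update norm.
#' @param max_iter maximum outer alternation cycles.
#' @return a list with components `fit` (a `"pois_irls"`-like object whose
#'   `weights` are the NB working weights), `vcov` (a `"robpois_vcov"` with
#'   `method = "negbin"`, `meta` holding the size estimate `r`), `r`,
#'   `converged` and `logLik`.
#' @export
negbin_fit <- function(y, X, offset = NULL, tol = 1e-8, max_iter = 100L) {
  X <- as.matrix(X)
  n <- nrow(X)
  p <- ncol(X)
  y <- as.numeric(y)
  if (any(y < 0)) stop("y must be non-negative")
  if (any(y != floor(y)))
    warning("non-integer responses: NB log-likelihood evaluated at real y (quasi-likelihood)")
  if (is.null(offset)) offset <- numeric(n)
  if (all(y == 0)) stop("all responses are zero")

  nb_loglik <- function(log_r, mu) {
    r <- exp(log_r)
    sum(lgamma(y + r) - lgamma(r) - lgamma(y + 1) +
          r * (log_r - log(r + mu)) + y * (log(mu) - log(r + mu)))
  }

  # start from the Poisson quasi-fit and a moment estimate of r
  beta <- irls_core(y, X, offset, tol = 1e-6, max_iter = 50L)
  mu <- exp(offset + drop(X %*% beta))
  excess <- sum((y - mu)^2 - mu) / sum(mu^2)
  log_r <- if (is.finite(excess) && excess > 1e-8) -log(excess) else log(1e4)
  log_r <- min(max(log_r, -12), 20)

  converged <- FALSE
  for (cycle in seq_len(max_iter)) {
    opt <- stats::optimize(nb_loglik, interval = c(-12, 20), mu = mu,
                           maximum = TRUE, tol = 1e-10)
    log_r <- opt$maximum
    r <- exp(log_r)
    # one or more scoring steps for beta at fixed r
    delta_norm <- Inf
    for (k in 1:25) {
      w <- mu / (1 + mu / r)
      delta <- tryCatch(
        drop(solve(crossprod(X, X * w), crossprod(X, (y - mu) / (1 + mu / r)))),
        error = function(e) stop("NB information matrix singular", call. = FALSE)
      )
      beta <- beta + delta
      mu <- exp(offset + drop(X %*% beta))
      if (!all(is.finite(mu))) stop("NB fit diverged")
      delta_norm <- sqrt(sum(delta^2))
      if (delta_norm < tol) break
    }
    if (delta_norm < tol &&
        abs(log_r - opt$maximum) < 1e-8) {
      # r re-optimised at the new beta must agree too
      opt2 <- stats::optimize(nb_loglik, interval = c(-12, 20), mu = mu,
                              maximum = TRUE, tol = 1e-10)
      if (abs(opt2$maximum - log_r) < 1e-6) {
        log_r <- opt2$maximum
        r <- exp(log_r)
        converged <- TRUE
        break
      }
      log_r <- opt2$maximum
      r <- exp(log_r)
    }
  }
  if (!converged) warning("negative binomial fit did not converge")

  boundary <- log_r > log(1e8)
  if (boundary) {
    warning("NB size estimate at the equidispersion boundary; ",
            "using the Poisson model-based covariance")
    w <- mu
  } else {
    w <- mu / (1 + mu / r)
  }
  cov <- solve(crossprod(X, X * w))
  dimnames(cov) <- list(colnames(X), colnames(X))
  names(beta) <- colnames(X)

  fit <- structure(
    list(coefficients = beta, mu = mu, weights = w, residuals = y - mu,
         converged = converged, n_iter = cycle, tol_used = tol,
         y = y, X = X, offset = offset),
    class = "pois_irls"
  )
  fit$leverages <- hat_diagonals(fit, X)
  list(
    fit = fit,
    vcov = new_vcov("negbin", cov,
                    meta = list(r = r, boundary = boundary)),
    r = r,
    converged = converged,
    logLik = nb_loglik(log_r, mu)
  )
}
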