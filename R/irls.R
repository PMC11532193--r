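#' Fit a Poisson log-linear model by iteratively reweighted least squares
#'
#' Maximises the Poisson log-likelihood with a log link,
#' \eqn{\log \mu_i = o_i + X_i^T \beta}, by Fisher scoring. At each iteration
#' the coefficient vector is updated by
#' \eqn{\beta_{k+1} = \beta_k + (X^T W_k X)^{-1} X^T (y - \mu_k)} with working
#' weights \eqn{W_k = \mathrm{diag}(\mu_k)}, and iteration stops when the
#' Euclidean norm of the update falls below `tol`. The intercept is
#' initialised at the log of the (offset-centred) mean response and all other
#' coefficients at zero.
#'
#' Non-negative real-valued responses are accepted: the Poisson score
#' equations \eqn{X^T(y - \mu) = 0} define a valid quasi-likelihood estimator
#' for any \eqn{y \ge 0}, which is what allows the same fitter to be used on
#' continuous heavy-tailed simulation draws.
#'
#' @param y numeric response vector, all entries `>= 0`.
#' @param X numeric design matrix with `n` rows and `p` columns (include an
#'   intercept column of ones if one is wanted; `n >= p >= 1` and `X` must
#'   have full column rank).
#' @param offset optional numeric vector of log-scale offsets (e.g. log
#'   library sizes); defaults to zero.
#' @param tol convergence tolerance on the Euclidean norm of the coefficient
#'   update.
#' @param max_iter maximum number of Fisher-scoring iterations; if reached
#'   without convergence the fit is returned with `converged = FALSE` and a
#'   warning.
#'
#' @return An object of class `"pois_irls"`: a list with components
#'   `coefficients` (length-`p`, log scale), `mu` (fitted means),
#'   `weights` (working weights, equal to `mu`), `leverages` (diagonal of the
#'   hat matrix), `residuals` (response residuals `y - mu`), `converged`,
#'   `n_iter`, `tol_used`, and the inputs `y`, `X`, `offset`.
#'
#' @examples
#' x <- rep(0:1, each = 10)
#' y <- rpois(20, exp(1 + 0.5 * x))
#' fit <- irls_fit(y, cbind(1, x))
#' coef(fit)
#' @seealso [vcov_hc3()], [vcov_bootstrap()], [robpois()] for the formula
#'   interface.
#' @export
irls_fit <- function(y, X, offset = NULL, tol = 1e-8, max_iter = 50L) {
  X <- as.matrix(X)
  n <- nrow(X)
  p <- ncol(X)
  y <- as.numeric(y)
  if (length(y) != n) stop("length(y) must equal nrow(X)")
  if (n < p || p < 1L) stop("need n >= p >= 1")
  if (any(!is.finite(y)) || any(y < 0)) stop("y must be finite and non-negative")
  if (is.null(offset)) offset <- numeric(n)
  offset <- as.numeric(offset)
  if (length(offset) != n || any(!is.finite(offset)))
    stop("offset must be a finite vector of length n")
  if (tol <= 0) stop("tol must be positive")
  max_iter <- as.integer(max_iter)
  if (max_iter < 1L) stop("max_iter must be >= 1")
  if (all(y == 0))
    stop("all responses are zero: the intercept initialisation log(mean(y)) is undefined; filter such taxa upstream")

  beta <- numeric(p)
  intercept_col <- which(apply(X, 2L, function(cl) all(cl == 1)))
  if (length(intercept_col))
    beta[intercept_col[1L]] <- log(mean(y)) - mean(offset)

  eta <- offset + drop(X %*% beta)
  mu <- exp(eta)
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    xtwx <- crossprod(X, X * mu)
    score <- crossprod(X, y - mu)
    delta <- tryCatch(
      drop(solve(xtwx, score)),
      error = function(e) stop("weighted cross-product matrix is singular (rank-deficient design)", call. = FALSE)
    )
    # step-halving guard against overshoot into non-finite means
    step <- 1
    repeat {
      beta_new <- beta + step * delta
      mu_new <- exp(offset + drop(X %*% beta_new))
      if (all(is.finite(mu_new)) && all(mu_new > 0)) break
      step <- step / 2
      if (step < 1e-10) stop("IRLS step collapsed: fitted means diverged")
    }
    beta <- beta_new
    mu <- mu_new
    if (sqrt(sum((step * delta)^2)) < tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged)
    warning("IRLS did not converge in ", max_iter, " iterations")

  names(beta) <- colnames(X)
  fit <- list(
    coefficients = beta,
    mu = mu,
    weights = mu,
    residuals = y - mu,
    converged = converged,
    n_iter = iter,
    tol_used = tol,
    y = y,
    X = X,
    offset = offset
  )
  fit$leverages <- hat_diagonals(fit, X)
  class(fit) <- "pois_irls"
  fit
}

#' Leverage values of a weighted GLM fit
#'
#' Diagonal of the hat matrix \eqn{H = X (X^T W X)^{-1} X^T W} at the working
#' weights of a converged fit. For a GLM this non-symmetric form has the same
#' diagonal as the symmetric \eqn{W^{1/2} X (X^T W X)^{-1} X^T W^{1/2}} form.
#' The diagonal entries lie in \eqn{(0, 1)} and sum to \eqn{p}.
#'
#' @param fit a `"pois_irls"` fit (or any list with a `weights` component).
#' @param X the design matrix the fit used.
#' @return numeric vector of length `n` of leverages \eqn{h_{ii}}.
#' @export
hat_diagonals <- function(fit, X) {
  X <- as.matrix(X)
  w <- fit$weights
  xtwx <- crossprod(X, X * w)
  xtwx_inv <- tryCatch(
    solve(xtwx),
    error = function(e) stop("X'WX is singular; leverages undefined", call. = FALSE)
  )
  rowSums((X %*% xtwx_inv) * (X * w))
}

#' @export
coef.pois_irls <- function(object, ...) object$coefficients

#' @export
fitted.pois_irls <- function(object, ...) object$mu

#' @export
residuals.pois_irls <- function(object,
                                type = c("response", "pearson"), ...) {
  type <- match.arg(type)
  switch(type,
    response = object$residuals,
    pearson = object$residuals / sqrt(object$mu)
  )
}

#' @export
print.pois_irls <- function(x, ...) {
  cat("Poisson log-linear fit (IRLS)\n")
  cat("Coefficients:\n")
  print(x$coefficients)
  cat("Converged:", x$converged, "in", x$n_iter, "iterations\n")
  invisible(x)
}
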