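# Robust fitting back end. Every model fit in the package is either linear in
# its parameters or linearized by Gauss-Newton, so a single weighted
# least-squares core with Huber reweighting serves them all.

# Weighted least-squares solve with a ridge fallback when the normal
# equations are (near-)singular.
wls_solve <- function(X, y, w = NULL, ridge = 0) {
  if (is.null(w)) w <- rep(1, length(y))
  Xw <- X * w
  XtX <- crossprod(Xw, X)
  Xty <- crossprod(Xw, y)
  if (ridge > 0) XtX <- XtX + diag(ridge, ncol(X))
  beta <- tryCatch(solve(XtX, Xty), error = function(e) NULL)
  if (is.null(beta)) {
    scale <- mean(diag(XtX))
    if (!is.finite(scale) || scale <= 0) scale <- 1
    warning("singular normal equations; falling back to ridge-regularized solve.")
    beta <- solve(XtX + diag(1e-8 * scale, ncol(X)), Xty)
  }
  drop(beta)
}

#' Huber weights for a residual vector
#'
#' `min(1, c / |r / sigma|)`, with `sigma` the 1.4826-scaled median absolute
#' deviation of the residuals unless supplied. A zero scale (all residuals
#' equal) yields unit weights.
#'
#' @param r Residual vector.
#' @param c Huber tuning constant (1.345 gives 95 percent efficiency under
#'   Gaussian errors).
#' @param sigma Optional fixed scale.
#' @return Weights in `[0, 1]`, same shape as `r`.
#' @export
huber_weights <- function(r, c = 1.345, sigma = NULL) {
  if (is.null(sigma)) sigma <- stats::mad(r, center = 0)
  if (!is.finite(sigma) || sigma <= 0) {
    w <- rep(1, length(r))
  } else {
    w <- pmin(1, c * sigma / abs(r))
    w[!is.finite(w)] <- 1  # zero residuals
  }
  if (!is.null(dim(r))) dim(w) <- dim(r)
  w
}

# Huber rho evaluated at fixed scale; used for monotone line searches.
huber_loss <- function(r, c = 1.345, sigma = 1) {
  a <- abs(r / sigma)
  sum(ifelse(a <= c, 0.5 * a^2, c * a - 0.5 * c^2))
}

#' Huber M-estimation by iteratively reweighted least squares
#'
#' Fits `y ~ X beta` under the Huber loss: repeated weighted least-squares
#' solves with weights `min(1, c / |r / sigma|)`, `sigma` re-estimated each
#' iteration as 1.4826 times the median absolute residual. Optional fixed
#' base weights multiply the robust weights (used e.g. for the asymmetric
#' background penalty). On outlier-free linear data the estimate coincides
#' with ordinary least squares, because all residuals stay inside the
#' quadratic region.
#'
#' @param X Design matrix (n x p).
#' @param y Response vector.
#' @param init Optional starting coefficients; when the residuals at `init`
#'   are all zero it is returned unchanged with unit weights.
#' @param base_weights Optional fixed non-negative per-point weights.
#' @param c Huber tuning constant.
#' @param max_iter,tol IRLS iteration cap and relative-change tolerance.
#' @return A list with `coefficients`, `weights` (final robust weights in
#'   `[0,1]`, excluding `base_weights`), `fitted`, `residuals`, `sigma`,
#'   `iterations` and `converged`.
#' @export
huber_irls <- function(X, y, init = NULL, base_weights = NULL, c = 1.345,
                       max_iter = 50L, tol = 1e-6) {
  X <- as.matrix(X)
  n <- length(y)
  stopifnot(nrow(X) == n)
  if (is.null(base_weights)) base_weights <- rep(1, n)

  if (!is.null(init)) {
    r0 <- y - drop(X %*% init)
    if (all(abs(r0) < 1e-300)) {
      return(list(coefficients = init, weights = rep(1, n), fitted = y,
                  residuals = r0, sigma = 0, iterations = 0L, converged = TRUE))
    }
    beta <- init
  } else {
    beta <- wls_solve(X, y, base_weights)
  }

  converged <- FALSE
  w <- rep(1, n)
  sigma <- NA_real_
  for (it in seq_len(max_iter)) {
    r <- y - drop(X %*% beta)
    sigma <- stats::mad(r, center = 0)
    w <- huber_weights(r, c = c, sigma = sigma)
    beta_new <- wls_solve(X, y, base_weights * w)
    delta <- max(abs(beta_new - beta)) / (1 + max(abs(beta)))
    beta <- beta_new
    if (delta < tol) { converged <- TRUE; break }
  }
  r <- y - drop(X %*% beta)
  list(coefficients = beta, weights = huber_weights(r, c = c, sigma = sigma),
       fitted = drop(X %*% beta), residuals = r, sigma = sigma,
       iterations = it, converged = converged)
}
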