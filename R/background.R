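# Reference pseudo-array construction and its decomposition into optical
# background (scalar o), non-specific-binding background (per-probe b) and
# true signal (per-probe x), with s = o + b + x enforced exactly where the
# reference exceeds the optical floor.

#' Median reference pseudo-array
#'
#' Element-wise median intensity across arrays, linear scale. All arrays are
#' subsequently compared against this pseudo-array, avoiding the quadratic
#' number of pairwise comparisons.
#'
#' @param arrays An [rdn_arrayset()] with at least two arrays.
#' @return Numeric vector of per-probe reference intensities.
#' @export
build_reference <- function(arrays) {
  stopifnot(inherits(arrays, "rdn_arrayset"))
  if (ncol(arrays$signals) < 2) {
    stop("at least two arrays are required; reference-free mode is unsupported.")
  }
  apply(arrays$signals, 1L, stats::median)
}

#' Fit the reference background model
#'
#' Estimates a scalar optical background `o` and sequence-dependent
#' non-specific-binding background `2^tau(phi)` by robustly fitting
#' `log2(o + 2^(tau_j)) ~ log2 min_i(s_ij)`. The per-array minimum is used as
#' the fit target because it is the closest available estimate of an
#' only-background signal (the median reference is available as a fallback).
#' The fit is a damped Gauss-Newton iteration with Huber reweighting; an
#' asymmetric weight multiplies the loss by `eta` wherever the model
#' overshoots the target, so that with `eta > 1` the fitted background
#' deliberately underestimates rather than eats into true signal.
#'
#' @param arrays An [rdn_arrayset()].
#' @param eta Asymmetry factor (>= 1); 10 by default, 1 gives a symmetric
#'   ("accuracy") fit.
#' @param target `"min"` (default) or `"median"` fit target.
#' @param n_knots,degree Hybridization-model spline controls.
#' @param huber_c Huber tuning constant.
#' @param max_iter,tol Gauss-Newton iteration cap and relative-change
#'   tolerance.
#' @param design Optional precomputed [hyb_design()] matrix for the probes.
#' @return An object of class `rdn_background`: list with `o_ref` (scalar
#'   optical background), `params` (`rdn_hyb_params`), `bg_hat` (per-probe
#'   linear background `2^tau`), `target` (log2 target used), `loss`,
#'   `iterations`, `converged`.
#' @export
fit_background <- function(arrays, eta = 10, target = c("min", "median"),
                           n_knots = 5L, degree = 3L, huber_c = 1.345,
                           max_iter = 50L, tol = 1e-6, design = NULL) {
  stopifnot(inherits(arrays, "rdn_arrayset"))
  if (eta < 1) stop("`eta` must be >= 1.")
  target <- match.arg(target)
  tvec <- if (target == "min") {
    apply(arrays$signals, 1L, min)
  } else {
    build_reference(arrays)
  }
  y <- log2(tvec)
  if (is.null(design)) {
    design <- hyb_design(arrays$annotation$sequence, n_knots = n_knots,
                         degree = degree)
  }
  fit <- fit_optical_plus_tau(y, design, eta = eta, huber_c = huber_c,
                              max_iter = max_iter, tol = tol)
  structure(
    list(o_ref = fit$o, params = hyb_params_from_vector(fit$phi, n_knots),
         bg_hat = 2^drop(design %*% fit$phi), target = y, loss = fit$loss,
         iterations = fit$iterations, converged = fit$converged,
         eta = eta, n_knots = as.integer(n_knots)),
    class = "rdn_background"
  )
}

# Gauss-Newton for y ~ log2(o + 2^(D phi)) with Huber + asymmetric weights.
# Parametrized with log2(o) to keep the optical floor positive.
fit_optical_plus_tau <- function(y, design, eta, huber_c, max_iter, tol) {
  n <- length(y)
  o_floor <- 1e-6
  o <- max(0.5 * stats::quantile(2^y, 0.05), o_floor)
  # the partition-of-unity design has exact collinear directions, so every
  # solve carries a small ridge
  z0 <- log2(pmax(2^y - o, o_floor))
  phi <- wls_solve(design, z0, ridge = 1e-6 * nrow(design))
  obj <- function(o, phi) {
    f <- log2(o + 2^drop(design %*% phi))
    r <- y - f
    wa <- ifelse(r < 0, eta, 1)  # model above target = overestimation
    sum(wa * ifelse(abs(r) <= huber_c, 0.5 * r^2,
                    huber_c * abs(r) - 0.5 * huber_c^2))
  }
  loss <- obj(o, phi)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    m <- 2^drop(design %*% phi)
    shat <- o + m
    r <- y - log2(shat)
    wa <- ifelse(r < 0, eta, 1)
    w <- wa * huber_weights(r, c = huber_c)
    # Jacobian of log2(o + m) wrt (log2 o, phi)
    J <- cbind(o / shat, (m / shat) * design)
    ridge <- 1e-8 * mean(colSums((J * w) * J))
    delta <- wls_solve(J, r, w, ridge = ridge)
    step <- 1
    improved <- FALSE
    for (h in 1:20) {
      o_new <- 2^(log2(o) + step * delta[1])
      phi_new <- phi + step * delta[-1]
      if (o_new < o_floor) o_new <- o_floor
      loss_new <- obj(o_new, phi_new)
      if (is.finite(loss_new) && loss_new <= loss + 1e-12) { improved <- TRUE; break }
      step <- step / 2
    }
    if (!improved) break
    change <- max(abs(c(o_new - o, phi_new - phi))) /
      (1 + max(abs(c(o, phi))))
    o <- o_new; phi <- phi_new; loss <- loss_new
    if (change < tol) { converged <- TRUE; break }
  }
  if (!converged && max_iter > 0) {
    warning("background fit did not converge in ", max_iter,
            " iterations; returning best iterate.")
  }
  list(o = o, phi = phi, loss = loss, iterations = it, converged = converged)
}

#' Decompose the reference into signal components
#'
#' Splits the reference pseudo-array into optical background, non-specific
#' binding and true signal under the constraint `s >= b + o`: the fitted
#' background is clipped so it never exceeds the optically-corrected
#' reference, and the remainder is the true signal. Probes at or below the
#' optical floor carry no background or true signal and are flagged
#' background-only.
#'
#' @param s_ref Per-probe reference intensities ([build_reference()]).
#' @param o_ref Scalar optical background (> 0).
#' @param bg_hat Per-probe fitted linear background (`2^tau`, >= 0).
#' @return An object of class `rdn_reference`: list with scalar `o` and
#'   aligned vectors `s`, `b`, `x`, logical `background_only`.
#' @export
decompose_reference <- function(s_ref, o_ref, bg_hat) {
  stopifnot(length(bg_hat) == length(s_ref), o_ref > 0, all(bg_hat >= 0))
  headroom <- pmax(s_ref - o_ref, 0)
  b <- pmin(bg_hat, headroom)
  x <- ifelse(s_ref > o_ref, s_ref - o_ref - b, 0)
  structure(
    list(o = o_ref, s = s_ref, b = b, x = x,
         background_only = s_ref <= o_ref | x == 0),
    class = "rdn_reference"
  )
}

#' @export
print.rdn_reference <- function(x, ...) {
  cat(sprintf(
    "<rdn_reference> %d probes, optical background %.3f, %d background-only probes\n",
    length(x$s), x$o, sum(x$background_only)))
  invisible(x)
}

#' @rdname decompose_reference
#' @param arrays An [rdn_arrayset()].
#' @param ... Passed to [fit_background()].
#' @export
estimate_reference <- function(arrays, ...) {
  s_ref <- build_reference(arrays)
  bg <- fit_background(arrays, ...)
  ref <- decompose_reference(s_ref, bg$o_ref, bg$bg_hat)
  ref$background_fit <- bg
  ref
}
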