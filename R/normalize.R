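# Per-array technical-difference estimation against the reference
# decomposition, and quantile normalization to the reference distribution.
#
# The component model for array i is
#   s_hat_ij = (o + d_i) + b_j * 2^tau(phi_b_i) + x_j * 2^(tau(phi_f_i) + kappa(a_i))
# i.e. an additive optical difference, separate multiplicative hybridization
# differences for the background and foreground components, and a
# multiplicative amplification difference acting on the true signal only.
# Parameters are fitted per array by minimizing the Huber loss of
# log2 s_ij - log2 s_hat_ij, alternating damped Gauss-Newton steps over the
# parameter blocks (d -> phi_b -> phi_f -> a).

#' Precompute model design matrices for a probe annotation
#'
#' @param annotation An `rdn_annotation` (or `rdn_arrayset`).
#' @param n_knots,degree Hybridization spline controls.
#' @return List with `hyb` (probes x 230 hybridization design) and `amp`
#'   (probes x 16 dinucleotide-count matrix).
#' @export
rdn_designs <- function(annotation, n_knots = 5L, degree = 3L) {
  if (inherits(annotation, "rdn_arrayset")) annotation <- annotation$annotation
  list(hyb = hyb_design(annotation$sequence, n_knots = n_knots, degree = degree),
       amp = as.matrix(annotation$dinuc), n_knots = as.integer(n_knots))
}

predict_array_difference <- function(o, d, b, x, tau_b, tau_f, kap) {
  (o + d) + b * 2^tau_b + x * 2^(tau_f + kap)
}

#' Fit per-array technical differences to the reference
#'
#' Estimates, for one array, the optical difference `d`, background and
#' foreground hybridization difference parameters and the amplification
#' coefficient vector `a`, by robust minimization of the log2 difference
#' between the measured signal and the technically-distorted reference.
#' Effects can be switched off individually (their parameters stay 0), which
#' is how the ablated pipeline variants are produced.
#'
#' @param s Per-probe linear intensities of the array.
#' @param ref An `rdn_reference` ([decompose_reference()]).
#' @param designs Design matrices from [rdn_designs()].
#' @param steps Named logical vector enabling `optical`, `hyb`, `amp`.
#' @param huber_c Huber tuning constant.
#' @param sweeps Outer block-coordinate sweeps.
#' @param inner Gauss-Newton steps per block per sweep.
#' @param tol Relative loss-change tolerance for early stopping.
#' @return An object of class `rdn_arrayfit`: list with scalar `d`,
#'   parameter vectors `phi_b`, `phi_f` (hybridization, design order), `a`
#'   (length 16), per-probe effects `tau_b`, `tau_f`, `kappa`, the final
#'   `loss`, `iterations` and the fitted `s_hat`.
#' @export
fit_array_difference <- function(s, ref, designs,
                                 steps = c(optical = TRUE, hyb = TRUE, amp = TRUE),
                                 huber_c = 1.345, sweeps = 3L, inner = 2L,
                                 tol = 1e-5) {
  stopifnot(inherits(ref, "rdn_reference"), length(s) == length(ref$s))
  y <- log2(s)
  o <- ref$o; b <- ref$b; x <- ref$x
  D <- designs$hyb; P <- designs$amp
  p_hyb <- ncol(D)

  d <- 0
  phi_b <- numeric(p_hyb)
  phi_f <- numeric(p_hyb)
  a <- numeric(16L)
  tau_b <- numeric(length(s)); tau_f <- tau_b; kap <- tau_b

  loss_fun <- function(d, tau_b, tau_f, kap) {
    r <- y - log2(predict_array_difference(o, d, b, x, tau_b, tau_f, kap))
    huber_loss(r, c = huber_c)
  }
  loss <- loss_fun(d, tau_b, tau_f, kap)
  d_floor <- -0.95 * o  # keep the optical level positive

  gn_step <- function(J, r, w) {
    ridge <- 1e-8 * mean(colSums((J * w) * J)) + 1e-12
    wls_solve(J, r, w, ridge = ridge)
  }

  n_iter <- 0L
  for (sweep in seq_len(sweeps)) {
    loss_at_sweep_start <- loss
    for (block in c("optical", "hyb_b", "hyb_f", "amp")) {
      enabled <- switch(block,
                        optical = isTRUE(steps[["optical"]]),
                        hyb_b = isTRUE(steps[["hyb"]]),
                        hyb_f = isTRUE(steps[["hyb"]]),
                        amp = isTRUE(steps[["amp"]]))
      if (!enabled) next
      for (k in seq_len(inner)) {
        n_iter <- n_iter + 1L
        shat <- predict_array_difference(o, d, b, x, tau_b, tau_f, kap)
        r <- y - log2(shat)
        w <- huber_weights(r, c = huber_c)
        fg <- x * 2^(tau_f + kap)
        if (block == "optical") {
          J <- matrix(1 / (shat * log(2)), ncol = 1)
        } else if (block == "hyb_b") {
          J <- ((b * 2^tau_b) / shat) * D
        } else if (block == "hyb_f") {
          J <- (fg / shat) * D
        } else {
          J <- (fg / shat) * P
        }
        delta <- gn_step(J, r, w)
        step <- 1
        repeat {
          if (block == "optical") {
            d_new <- max(d + step * delta, d_floor)
            cand <- loss_fun(d_new, tau_b, tau_f, kap)
          } else if (block == "hyb_b") {
            tb_new <- tau_b + step * drop(D %*% delta)
            cand <- loss_fun(d, tb_new, tau_f, kap)
          } else if (block == "hyb_f") {
            tf_new <- tau_f + step * drop(D %*% delta)
            cand <- loss_fun(d, tau_b, tf_new, kap)
          } else {
            k_new <- kap + step * drop(P %*% delta)
            cand <- loss_fun(d, tau_b, tau_f, k_new)
          }
          if (is.finite(cand) && cand <= loss + 1e-12) break
          step <- step / 2
          if (step < 1e-6) break
        }
        if (step < 1e-6) break  # no improvement in this block
        if (block == "optical") {
          d <- max(d + step * delta, d_floor)
        } else if (block == "hyb_b") {
          phi_b <- phi_b + step * delta; tau_b <- drop(D %*% phi_b)
        } else if (block == "hyb_f") {
          phi_f <- phi_f + step * delta; tau_f <- drop(D %*% phi_f)
        } else {
          a <- a + step * delta; kap <- drop(P %*% a)
        }
        loss <- cand
      }
    }
    if (abs(loss_at_sweep_start - loss) < tol * (1 + abs(loss))) break
  }

  shat <- predict_array_difference(o, d, b, x, tau_b, tau_f, kap)
  structure(
    list(d = d, phi_b = phi_b, phi_f = phi_f, a = a,
         tau_b = tau_b, tau_f = tau_f, kappa = kap,
         s_hat = shat, loss = loss, iterations = n_iter,
         n_knots = designs$n_knots),
    class = "rdn_arrayfit"
  )
}

#' @export
print.rdn_arrayfit <- function(x, ...) {
  cat(sprintf(
    "<rdn_arrayfit> d = %.3f, |tau_b| med %.3f, |tau_f| med %.3f, |kappa| med %.3f, loss %.2f\n",
    x$d, stats::median(abs(x$tau_b)), stats::median(abs(x$tau_f)),
    stats::median(abs(x$kappa)), x$loss))
  invisible(x)
}

#' Remove fitted technical differences from an array
#'
#' Subtracts the fitted technical-effect difference `t_ij = log2 s_hat_ij -
#' log2 s_ref_j` from the measured log2 signal, returning the corrected
#' signal on linear scale (strictly positive by construction).
#'
#' @param s Per-probe linear intensities.
#' @param fit An `rdn_arrayfit`.
#' @param ref The `rdn_reference` used for the fit.
#' @return Corrected linear intensities.
#' @export
apply_difference_correction <- function(s, fit, ref) {
  stopifnot(inherits(fit, "rdn_arrayfit"), inherits(ref, "rdn_reference"))
  t_ij <- log2(fit$s_hat) - log2(ref$s)
  2^(log2(s) - t_ij)
}

#' Quantile normalization to the reference distribution
#'
#' Maps every array's signal distribution onto the distribution of the
#' median array: each column's sorted values are replaced, rank for rank, by
#' the per-rank median of the column-sorted values. Rank order within each
#' column is preserved; ties are assigned stably in input order. The
#' operation is idempotent, because after one pass every column already has
#' exactly the reference distribution.
#'
#' @param arrays An [rdn_arrayset()] or a plain probes x arrays matrix.
#' @return Same type as the input, normalized.
#' @export
quantile_to_reference <- function(arrays) {
  m <- if (inherits(arrays, "rdn_arrayset")) arrays$signals else as.matrix(arrays)
  if (ncol(m) < 2) stop("at least two arrays are required.")
  sorted <- apply(m, 2L, sort, method = "quick")
  ref_dist <- apply(sorted, 1L, stats::median)
  has_ties <- any(apply(m, 2L, anyDuplicated) > 0)
  if (has_ties) {
    message("ties present; assigning tied ranks stably in input order.")
  }
  out <- m
  for (i in seq_len(ncol(m))) {
    out[, i] <- ref_dist[rank(m[, i], ties.method = "first")]
  }
  if (inherits(arrays, "rdn_arrayset")) {
    arrays$signals <- out
    arrays
  } else {
    out
  }
}
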