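# Probe-set summarization: a background-aware robust fit of
#   log2 y_ij ~ log2( o + b_j + 2^(omega + alpha_i + rho_j) )
# per probe set, with identifiability constraints sum_i alpha_i = 0 and
# sum_j rho_j = 0 (rho per probe set). Probes whose true-signal term is small
# relative to o + b_j barely move the residual when alpha changes, so
# background-dominated probes automatically lose influence on the summarized
# fold changes. Outlier probes (low Huber weight on many arrays) are removed,
# and fold changes can be backscaled so that background-dominated probe sets
# do not report inflated fold changes.

#' Fit the summarization model for one probe set
#'
#' Alternates damped Gauss-Newton/IRLS steps over the mean level `omega`,
#' the per-array effects `alpha` and the per-probe affinities `rho`, with
#' Huber reweighting of the log2 residuals; the zero-sum constraints are
#' re-absorbed into `omega` after every sweep. With `include_optical =
#' FALSE` the optical term is dropped from inside the log.
#'
#' @param y Probes x arrays matrix of linear, normalized intensities.
#' @param b Per-probe linear background levels (`b_j`), length `nrow(y)`.
#' @param o Scalar optical background.
#' @param huber_c Huber tuning constant.
#' @param include_optical Include `o` inside the model (default TRUE).
#' @param max_sweeps,tol Iteration cap and max-parameter-change tolerance.
#' @return List with `omega` (scalar), `alpha` (length `ncol(y)`, sums to
#'   0), `rho` (length `nrow(y)`, sums to 0), `weights` (probes x arrays
#'   Huber weights in `[0,1]`), `fitted`, `iterations`, `converged`.
#' @export
clamp <- function(v, lo, hi) pmin(pmax(v, lo), hi)

fit_probeset <- function(y, b, o, huber_c = 1.345, include_optical = TRUE,
                         max_sweeps = 100L, tol = 1e-6) {
  y <- as.matrix(y)
  np <- nrow(y); K <- ncol(y)
  stopifnot(length(b) == np, all(y > 0), all(b >= 0), o >= 0)
  base <- if (include_optical) o + b else b
  ly <- log2(y)

  # moment-style init on the background-subtracted log signal
  z <- log2(pmax(y - base, 2^-10))
  omega <- stats::median(z)
  alpha <- apply(z, 2L, stats::median) - omega
  alpha <- alpha - mean(alpha)
  rho <- if (np > 1) {
    r0 <- apply(z, 1L, stats::median) - omega
    r0 - mean(r0)
  } else 0
  omega <- stats::median(z - outer(rho, alpha, `+`))

  eval_model <- function(omega, alpha, rho) {
    g <- 2^(omega + outer(rho, alpha, `+`))
    shat <- base + g
    list(g = g, shat = shat, r = ly - log2(shat))
  }
  loss_fun <- function(omega, alpha, rho) {
    huber_loss(eval_model(omega, alpha, rho)$r, c = huber_c)
  }

  converged <- FALSE
  for (sweep in seq_len(max_sweeps)) {
    om0 <- omega; al0 <- alpha; rh0 <- rho
    for (block in c("omega", "alpha", "rho")) {
      if (block == "rho" && np == 1L) next
      st <- eval_model(omega, alpha, rho)
      w <- huber_weights(st$r, c = huber_c)
      G <- st$g / st$shat  # d log2(shat) / d theta, shared by all blocks
      den_floor <- 1e-12
      if (block == "omega") {
        delta <- sum(w * G * st$r) / max(sum(w * G * G), den_floor)
      } else if (block == "alpha") {
        delta <- colSums(w * G * st$r) / pmax(colSums(w * G * G), den_floor)
      } else {
        delta <- rowSums(w * G * st$r) / pmax(rowSums(w * G * G), den_floor)
      }
      delta <- clamp(delta, -4, 4)  # trust region for near-flat directions
      loss <- huber_loss(st$r, c = huber_c)
      step <- 1
      repeat {
        om_n <- omega; al_n <- alpha; rh_n <- rho
        # generous box bounds: a column whose signal sits below the
        # background level has an unidentifiable foreground, and its fold
        # change would otherwise drift to -Inf
        if (block == "omega") om_n <- clamp(omega + step * delta, -20, 40)
        if (block == "alpha") al_n <- clamp(alpha + step * delta, -25, 25)
        if (block == "rho") rh_n <- clamp(rho + step * delta, -15, 15)
        cand <- loss_fun(om_n, al_n, rh_n)
        if (is.finite(cand) && cand <= loss + 1e-12) break
        step <- step / 2
        if (step < 1e-8) { om_n <- omega; al_n <- alpha; rh_n <- rho; break }
      }
      omega <- om_n; alpha <- al_n; rho <- rh_n
    }
    # re-impose identifiability, absorbing the means into omega
    omega <- omega + mean(alpha) + if (np > 1) mean(rho) else 0
    alpha <- alpha - mean(alpha)
    if (np > 1) rho <- rho - mean(rho)
    change <- max(abs(c(omega - om0, alpha - al0, rho - rh0)))
    if (change < tol) { converged <- TRUE; break }
  }
  st <- eval_model(omega, alpha, rho)
  list(omega = omega, alpha = alpha, rho = rho,
       weights = huber_weights(st$r, c = huber_c),
       fitted = st$shat, iterations = sweep, converged = converged)
}

#' Outlier-probe removal rule
#'
#' A probe is flagged when its Huber weight falls below `weight_cutoff` on
#' more than `fraction` of the arrays (its quality on the remaining arrays
#' is then also questionable). Flagged probes are removed worst first
#' (largest low-weight fraction), but at least `floor` probes are always
#' retained (all probes, if the set started with `floor` or fewer).
#'
#' @param weights Probes x arrays matrix of Huber weights in `[0,1]`.
#' @param floor Minimum number of probes to retain (default 5).
#' @param weight_cutoff Low-weight threshold (default 0.9).
#' @param fraction Array fraction above which a probe is flagged (default 1/3).
#' @return List with logical `retained`, and a tibble `removed`
#'   (`probe`, `low_weight_fraction`).
#' @export
remove_outlier_probes <- function(weights, floor = 5L, weight_cutoff = 0.9,
                                  fraction = 1 / 3) {
  weights <- as.matrix(weights)
  stopifnot(all(weights >= 0 & weights <= 1))
  np <- nrow(weights)
  low_frac <- rowMeans(weights < weight_cutoff)
  flagged <- which(low_frac > fraction)
  retained <- rep(TRUE, np)
  if (length(flagged) > 0 && np > floor) {
    n_removable <- np - min(floor, np)
    drop_order <- flagged[order(low_frac[flagged], decreasing = TRUE)]
    drop <- drop_order[seq_len(min(length(drop_order), n_removable))]
    retained[drop] <- FALSE
  }
  list(retained = retained,
       removed = tibble::tibble(probe = which(!retained),
                                low_weight_fraction = low_frac[!retained]))
}

#' Backscale fold changes for background level
#'
#' Background removal inflates fold changes of background-dominated probe
#' sets; backscaling re-adds a probe-set-level background `F_k` (optical
#' floor plus the median retained-probe background) so the reported fold
#' change is the one an observer of the full signal would see:
#' `alpha_tilde = log2((F + 2^(omega + alpha)) / (F + 2^omega))`. Shrinks
#' every fold change toward 0, monotonically in `F`; `F = 0` leaves `alpha`
#' untouched.
#'
#' @param omega Scalar probe-set mean level (log2).
#' @param alpha Vector/matrix of log2 fold changes.
#' @param f Probe-set background level `F_k >= 0` (linear scale).
#' @return Backscaled fold changes, same shape as `alpha`.
#' @export
backscale_alpha <- function(omega, alpha, f) {
  stopifnot(f >= 0)
  log2((f + 2^(omega + alpha)) / (f + 2^omega))
}

#' Summarize all probe sets of a normalized array set
#'
#' Runs [fit_probeset()] per probe set, applies the outlier-probe rule with
#' one refit, and assembles expression values. The default output is the
#' backscaled `omega + alpha_tilde`; `output = "raw"` skips backscaling.
#'
#' @param arrays Normalized [rdn_arrayset()].
#' @param ref `rdn_reference` with the background decomposition.
#' @param output `"backscaled"` or `"raw"`.
#' @param backscale_aggregate `"median"` (default) or `"mean"` aggregation of
#'   probe backgrounds into `F_k`.
#' @param huber_c,include_optical,probe_floor,weight_cutoff,outlier_fraction
#'   Tuning controls (see [fit_probeset()] and [remove_outlier_probes()]).
#' @return An object of class `rdn_expression`: list with `expression`
#'   (probe sets x arrays log2 matrix), `omega`, `alpha`,
#'   `alpha_backscaled`, `rho` (list per probe set), `probe_weights` (list),
#'   `removed_probes` (tibble), `removed_probesets` (tibble), `f` (per-set
#'   background level) and `array_ids`.
#' @export
summarize_probesets <- function(arrays, ref, output = c("backscaled", "raw"),
                                backscale_aggregate = c("median", "mean"),
                                huber_c = 1.345, include_optical = TRUE,
                                probe_floor = 5L, weight_cutoff = 0.9,
                                outlier_fraction = 1 / 3) {
  stopifnot(inherits(arrays, "rdn_arrayset"), inherits(ref, "rdn_reference"))
  output <- match.arg(output)
  backscale_aggregate <- match.arg(backscale_aggregate)
  ann <- arrays$annotation
  sets <- split(seq_len(nrow(ann)), ann$probeset_id)
  K <- ncol(arrays$signals)
  ids <- names(sets)
  omega <- stats::setNames(rep(NA_real_, length(sets)), ids)
  alpha <- matrix(NA_real_, length(sets), K,
                  dimnames = list(ids, colnames(arrays$signals)))
  alpha_bs <- alpha
  f_k <- omega
  rho <- vector("list", length(sets)); names(rho) <- ids
  wts <- vector("list", length(sets)); names(wts) <- ids
  removed <- list()

  agg <- if (backscale_aggregate == "median") stats::median else mean
  for (k in seq_along(sets)) {
    idx <- sets[[k]]
    y <- arrays$signals[idx, , drop = FALSE]
    b <- ref$b[idx]
    fit <- fit_probeset(y, b, ref$o, huber_c = huber_c,
                        include_optical = include_optical)
    keep <- remove_outlier_probes(fit$weights, floor = probe_floor,
                                  weight_cutoff = weight_cutoff,
                                  fraction = outlier_fraction)
    if (any(!keep$retained)) {
      removed[[ids[k]]] <- dplyr::mutate(
        keep$removed, probeset_id = ids[k],
        probe_id = ann$probe_id[idx][keep$removed$probe], .before = 1)
      idx <- idx[keep$retained]
      y <- arrays$signals[idx, , drop = FALSE]
      b <- ref$b[idx]
      fit <- fit_probeset(y, b, ref$o, huber_c = huber_c,
                          include_optical = include_optical)
    }
    omega[k] <- fit$omega
    alpha[k, ] <- fit$alpha
    rho[[k]] <- stats::setNames(fit$rho, ann$probe_id[idx])
    w <- fit$weights
    dimnames(w) <- list(ann$probe_id[idx], colnames(arrays$signals))
    wts[[k]] <- w
    f_k[k] <- ref$o + agg(b)
    alpha_bs[k, ] <- backscale_alpha(fit$omega, fit$alpha, f_k[k])
  }
  expr <- if (output == "backscaled") omega + alpha_bs else omega + alpha
  removed_tbl <- if (length(removed) > 0) {
    dplyr::bind_rows(removed)
  } else {
    tibble::tibble(probeset_id = character(), probe_id = character(),
                   probe = integer(), low_weight_fraction = double())
  }
  structure(
    list(expression = expr, omega = omega, alpha = alpha,
         alpha_backscaled = alpha_bs, rho = rho, probe_weights = wts,
         removed_probes = removed_tbl,
         removed_probesets = tibble::tibble(probeset_id = character(),
                                            reason = character()),
         f = f_k, output = output, array_ids = colnames(arrays$signals)),
    class = "rdn_expression"
  )
}

#' @export
print.rdn_expression <- function(x, ...) {
  cat(sprintf("<rdn_expression> %d probe sets x %d arrays (%s output), %d probes removed\n",
              nrow(x$expression), ncol(x$expression), x$output,
              nrow(x$removed_probes)))
  invisible(x)
}
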