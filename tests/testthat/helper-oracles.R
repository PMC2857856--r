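# Independent oracles and small fixture builders shared across tests.

# Naive de Boor / Cox recursion for B-spline basis functions, independent of
# splines::splineDesign.
deboor_basis <- function(knots, degree, x, i) {
  if (degree == 0) {
    # half-open intervals, closed at the right end of the last span
    last <- max(which(knots < max(knots)))
    if (knots[i] <= x && x < knots[i + 1]) return(1)
    if (x == max(knots) && knots[i] < knots[i + 1] && i == last) return(1)
    return(0)
  }
  d1 <- knots[i + degree] - knots[i]
  d2 <- knots[i + degree + 1] - knots[i + 1]
  t1 <- if (d1 > 0) (x - knots[i]) / d1 * deboor_basis(knots, degree - 1, x, i) else 0
  t2 <- if (d2 > 0) {
    (knots[i + degree + 1] - x) / d2 * deboor_basis(knots, degree - 1, x, i + 1)
  } else 0
  t1 + t2
}

deboor_row <- function(knots, degree, x) {
  nb <- length(knots) - degree - 1
  vapply(seq_len(nb), function(i) deboor_basis(knots, degree, x, i), numeric(1))
}

# Brute-force windowed median with invalid (NA) cells.
brute_box_median <- function(grid, size) {
  h <- (size - 1) %/% 2
  out <- matrix(NA_real_, nrow(grid), ncol(grid))
  for (r in seq_len(nrow(grid))) {
    for (cc in seq_len(ncol(grid))) {
      if (is.na(grid[r, cc])) next
      rs <- max(1, r - h):min(nrow(grid), r + h)
      cs <- max(1, cc - h):min(ncol(grid), cc + h)
      vals <- grid[rs, cs]
      vals <- vals[!is.na(vals)]
      out[r, cc] <- if (length(vals) == 0) 0 else median(vals)
    }
  }
  out
}

# Exhaustive truncated ROC: walk the ranked step curve.
step_curve_roc <- function(scores, labels, max_fp) {
  ord <- order(scores, decreasing = TRUE)
  lab <- labels[ord]
  cutoff <- min(max_fp, sum(!labels))
  if (cutoff == 0) return(1)
  area <- 0; fp <- 0
  for (l in lab) {
    if (l) {
      area <- area + max(cutoff - fp, 0)
    } else {
      fp <- fp + 1
      if (fp >= cutoff) break
    }
  }
  area / (cutoff * sum(labels))
}

# Brute-force dinucleotide count of a coded transcript window [from, to_end-1]
brute_window_counts <- function(codes, from, to_end) {
  out <- integer(16)
  if (to_end - 1 >= from) {
    for (t in from:(to_end - 1)) {
      p <- codes[t] + 4L * (codes[t + 1L] - 1L)
      out[p] <- out[p] + 1L
    }
  }
  out
}

# Random 25-mers
random_probe_seqs <- function(n) {
  vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "T"), 25, replace = TRUE), collapse = "")
  }, character(1))
}

# Minimal arrayset: n_sets probe sets of npp probes on a compact grid.
tiny_arrayset <- function(n_sets = 2, npp = 3, K = 3, seed = 42,
                          signal_fun = NULL) {
  withr::with_seed(seed, {
    n <- n_sets * npp
    nc <- ceiling(sqrt(n))
    ann <- tibble::tibble(
      probe_id = sprintf("p%03d", seq_len(n)),
      probeset_id = rep(sprintf("s%02d", seq_len(n_sets)), each = npp),
      sequence = random_probe_seqs(n),
      x = (seq_len(n) - 1L) %% nc,
      y = (seq_len(n) - 1L) %/% nc,
      dist3 = rep(seq(0, by = 30, length.out = npp), times = n_sets))
    sig <- if (is.null(signal_fun)) {
      matrix(2^runif(n * K, 5, 12), n, K)
    } else {
      signal_fun(n, K)
    }
    colnames(sig) <- sprintf("a%d", seq_len(K))
    rdn_arrayset(ann, sig)
  })
}

# Reference object with known components built directly (no fitting).
known_reference <- function(sim) {
  tr <- sim$truth
  ann <- sim$arrays$annotation
  X <- 2^(sweep(tr$expression[ann$probeset_id, 1, drop = FALSE], 1,
                tr$rho, `+`))[, 1]
  decompose_reference(tr$optical + tr$background + X, tr$optical,
                      tr$background)
}
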