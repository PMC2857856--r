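# Array-location (spatial) effect estimation and correction. Location
# effects act multiplicatively on the hybridization signal (background +
# foreground) but not on the optical floor, so residuals are computed in
# log2 scale after optical subtraction, smoothed with a fixed-size median
# box filter over the physical probe grid (invalid cells - empty grid
# positions, mismatch rows, masked probes - are simply skipped), and the
# smoothed field is divided out.

#' Per-probe spatial residuals
#'
#' `eps_ij = log2(s_ij - o) - log2(median_i(s_ij) - o)`, the log2 difference
#' of the optically-corrected signal to the optically-corrected per-probe
#' median across arrays. Entries where either term is non-positive are
#' masked (`NA`) and excluded from field estimation.
#'
#' @param signals Probes x arrays matrix of linear intensities (already
#'   normalized for optical/hybridization/amplification differences).
#' @param o_ref Scalar optical background.
#' @return Probes x arrays matrix of residuals with `NA` for masked entries.
#' @export
location_residuals <- function(signals, o_ref) {
  m <- if (inherits(signals, "rdn_arrayset")) signals$signals else as.matrix(signals)
  med <- apply(m, 1L, stats::median)
  num <- m - o_ref
  den <- matrix(med - o_ref, nrow(m), ncol(m))
  valid <- num > 0 & den > 0
  eps <- matrix(NA_real_, nrow(m), ncol(m), dimnames = dimnames(m))
  eps[valid] <- log2(num[valid]) - log2(den[valid])
  eps
}

#' Median box filter over a probe grid
#'
#' For every valid cell of a 2-D grid, the median of the valid cells inside
#' a `size` x `size` window centred on it (clipped at the grid borders).
#' Cells whose window contains no valid values get 0.
#'
#' @param grid Numeric matrix (rows = y, cols = x) with `NA` marking invalid
#'   cells.
#' @param size Odd window side length (default 9).
#' @return Matrix of the same shape; invalid input cells are `NA` on output,
#'   but their values still contribute nothing (they were `NA`).
#' @export
median_box_filter <- function(grid, size = 9L) {
  stopifnot(is.matrix(grid), size %% 2L == 1L, size >= 1L)
  h <- (size - 1L) %/% 2L
  nr <- nrow(grid); nc <- ncol(grid)
  n_win <- size * size
  stack <- matrix(NA_real_, nr * nc, n_win)
  k <- 0L
  for (dx in -h:h) {
    cs <- seq_len(nc) + dx
    cok <- cs >= 1L & cs <= nc
    for (dy in -h:h) {
      k <- k + 1L
      rs <- seq_len(nr) + dy
      rok <- rs >= 1L & rs <= nr
      sub <- matrix(NA_real_, nr, nc)
      sub[rok, cok] <- grid[rs[rok], cs[cok]]
      stack[, k] <- sub
    }
  }
  med <- apply(stack, 1L, stats::median, na.rm = TRUE)
  med[is.na(med)] <- 0  # window held no valid probe
  out <- matrix(med, nr, nc)
  out[is.na(grid)] <- NA_real_
  out
}

# Scatter per-probe values onto the (y, x) grid; 0-based coordinates.
probe_grid <- function(values, x, y, dims = NULL) {
  if (is.null(dims)) dims <- c(max(y) + 1L, max(x) + 1L)
  g <- matrix(NA_real_, dims[1], dims[2])
  g[cbind(y + 1L, x + 1L)] <- values
  g
}

#' Estimate the per-probe location-effect field
#'
#' Computes spatial residuals ([location_residuals()]), scatters each
#' array's residuals onto the physical probe grid and smooths them with the
#' median box filter. Probes masked in the residuals receive a location
#' effect of 0 (they pass through the correction unchanged).
#'
#' @param arrays An [rdn_arrayset()].
#' @param o_ref Scalar optical background.
#' @param size Filter window side (default 9).
#' @return An object of class `rdn_location_field`: list with `lambda`
#'   (probes x arrays matrix of log2 effects), `mask` (logical matrix of
#'   masked residual entries) and `size`.
#' @export
estimate_location_field <- function(arrays, o_ref, size = 9L) {
  stopifnot(inherits(arrays, "rdn_arrayset"))
  eps <- location_residuals(arrays$signals, o_ref)
  ann <- arrays$annotation
  dims <- c(max(ann$y) + 1L, max(ann$x) + 1L)
  lambda <- matrix(0, nrow(eps), ncol(eps), dimnames = dimnames(arrays$signals))
  for (i in seq_len(ncol(eps))) {
    g <- probe_grid(eps[, i], ann$x, ann$y, dims)
    f <- median_box_filter(g, size = size)
    v <- f[cbind(ann$y + 1L, ann$x + 1L)]
    v[is.na(v)] <- 0
    lambda[, i] <- v
  }
  structure(list(lambda = lambda, mask = is.na(eps), size = as.integer(size)),
            class = "rdn_location_field")
}

#' Apply a location-effect correction
#'
#' `corrected = (s - o) * 2^(-lambda) + o`; entries masked during residual
#' estimation pass through unchanged, and positivity is preserved.
#'
#' @param arrays An [rdn_arrayset()] (or matrix).
#' @param field An `rdn_location_field` from [estimate_location_field()].
#' @param o_ref Scalar optical background.
#' @return Same type as the input, corrected.
#' @export
apply_location_correction <- function(arrays, field, o_ref) {
  m <- if (inherits(arrays, "rdn_arrayset")) arrays$signals else as.matrix(arrays)
  stopifnot(inherits(field, "rdn_location_field"),
            all(dim(field$lambda) == dim(m)))
  lam <- field$lambda
  lam[field$mask] <- 0
  out <- (m - o_ref) * 2^(-lam) + o_ref
  if (inherits(arrays, "rdn_arrayset")) {
    arrays$signals <- out
    arrays
  } else {
    out
  }
}
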