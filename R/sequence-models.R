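# Sequence-driven effect models: the hybridization model tau (smoothed
# dinucleotide-position weights plus nucleotide-count terms) and the
# amplification model kappa (dinucleotide content between probe centre and
# probe-set 3' end). Both are linear in their parameters, so each reduces to
# a design matrix times a weight vector; the design matrices are what the
# robust fits in the rest of the package operate on.

NUCLEOTIDES <- c("A", "C", "G", "T")

#' @rdname hyb_design
#' @format NULL
#' @export
DINUCLEOTIDES <- as.vector(outer(NUCLEOTIDES, NUCLEOTIDES,
                                 function(a, b) paste0(a, b)))

# The ten nucleotide sets counted by the second model part: the four single
# nucleotides plus the six unordered pairs (e.g. "CG" counts C's and G's, i.e.
# GC content).
NUCLEOTIDE_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  AC = c("A", "C"), AG = c("A", "G"), AT = c("A", "T"),
  CG = c("C", "G"), CT = c("C", "T"), GT = c("G", "T")
)

# Sequence ranges (1-based, inclusive) over which nucleotide sets are counted:
# whole probe, 5' half (through the centre base) and 3' half.
COUNT_RANGES <- list(r1_25 = c(1L, 25L), r1_13 = c(1L, 13L), r14_25 = c(14L, 25L))

PROBE_LENGTH <- 25L

#' Number of free hybridization-model parameters
#'
#' `16 * n_knots` dinucleotide-position weights plus
#' `10 * 3 * n_knots` nucleotide-count weights; 230 with the default five
#' knots.
#'
#' @param n_knots Number of B-spline knot weights per smooth.
#' @return Integer parameter count.
#' @export
n_hyb_params <- function(n_knots = 5L) {
  as.integer(length(DINUCLEOTIDES) * n_knots +
               length(NUCLEOTIDE_SETS) * length(COUNT_RANGES) * n_knots)
}

check_sequences <- function(sequences) {
  if (!is.character(sequences)) stop("`sequences` must be a character vector.")
  if (any(nchar(sequences) != PROBE_LENGTH)) {
    bad <- which(nchar(sequences) != PROBE_LENGTH)[1]
    stop("probe sequence ", bad, " is not ", PROBE_LENGTH, " nt long.")
  }
  if (any(grepl("[^ACGT]", sequences))) {
    bad <- which(grepl("[^ACGT]", sequences))[1]
    stop("probe sequence ", bad, " contains characters outside {A,C,G,T}.")
  }
  invisible(sequences)
}

# n x 25 integer matrix of nucleotide codes 1..4
sequence_code_matrix <- function(sequences) {
  check_sequences(sequences)
  m <- matrix(match(unlist(strsplit(sequences, "", fixed = TRUE), use.names = FALSE),
                    NUCLEOTIDES),
              nrow = length(sequences), ncol = PROBE_LENGTH, byrow = TRUE)
  m
}

#' Hybridization-model design matrix
#'
#' The hybridization effect of a 25-nt probe is modelled in log2 scale as the
#' sum of two parts: (1) a weight for the dinucleotide at each of the 24
#' positions, smoothed over position by a B-spline with `n_knots` knot weights
#' per dinucleotide; (2) a smooth function of the number of nucleotides from
#' each of ten nucleotide sets within each of three sequence ranges (whole
#' probe, 5' half, 3' half), capturing non-linear composition effects such as
#' runs of C/G. Both parts are linear in their knot weights, so the model for
#' a set of probes is `design %*% phi`. With the defaults (five knots, cubic
#' splines) `phi` has 230 entries.
#'
#' Column order: for each dinucleotide (AA, CA, GA, TA, AC, ...) the
#' `n_knots` position-spline weights, then for each (nucleotide set, range)
#' combination the `n_knots` count-spline weights.
#'
#' @param sequences Character vector of 25-nt probe sequences over
#'   \{A,C,G,T\}.
#' @param n_knots Knot weights per smooth (default 5).
#' @param degree Spline degree (default 3, cubic).
#' @return A numeric matrix with `length(sequences)` rows and
#'   [n_hyb_params()] columns, with a `"bases"` attribute holding the spline
#'   bases used.
#' @export
hyb_design <- function(sequences, n_knots = 5L, degree = 3L) {
  codes <- sequence_code_matrix(sequences)
  n <- nrow(codes)
  Q <- as.integer(n_knots)

  pos_basis <- spline_basis(Q, degree, c(1, PROBE_LENGTH - 1L))
  Bpos <- spline_basis_matrix(pos_basis, seq_len(PROBE_LENGTH - 1L))  # 24 x Q

  n_pair_cols <- length(DINUCLEOTIDES) * Q
  D <- matrix(0, n, n_hyb_params(Q))

  # part 1: accumulate the position-spline factors into the column of the
  # dinucleotide observed at each position
  for (m in seq_len(PROBE_LENGTH - 1L)) {
    pair <- codes[, m] + 4L * (codes[, m + 1L] - 1L)  # 1..16, first-base fast
    for (q in seq_len(Q)) {
      col <- (pair - 1L) * Q + q
      idx <- cbind(seq_len(n), col)
      D[idx] <- D[idx] + Bpos[m, q]
    }
  }

  # part 2: counts of nucleotide sets within ranges, through count splines
  count_bases <- list()
  off <- n_pair_cols
  for (ri in seq_along(COUNT_RANGES)) {
    r <- COUNT_RANGES[[ri]]
    len <- r[2] - r[1] + 1L
    count_bases[[ri]] <- spline_basis(Q, degree, c(0, len))
  }
  for (vi in seq_along(NUCLEOTIDE_SETS)) {
    set_codes <- match(NUCLEOTIDE_SETS[[vi]], NUCLEOTIDES)
    in_set <- matrix(codes %in% set_codes, nrow = n)
    for (ri in seq_along(COUNT_RANGES)) {
      r <- COUNT_RANGES[[ri]]
      cnt <- rowSums(in_set[, r[1]:r[2], drop = FALSE])
      Bc <- spline_basis_matrix(count_bases[[ri]], cnt)
      D[, off + seq_len(Q)] <- Bc
      off <- off + Q
    }
  }
  attr(D, "bases") <- list(position = pos_basis, counts = count_bases)
  D
}

#' Hybridization-model parameter container
#'
#' Bundles the two parameter blocks of the hybridization model, in the column
#' order of [hyb_design()].
#'
#' @param pair_weights 16 x `n_knots` matrix of dinucleotide position-spline
#'   weights (rows ordered as `DINUCLEOTIDES`).
#' @param count_weights 10 x 3 x `n_knots` array of nucleotide-count spline
#'   weights (sets x ranges x knots).
#' @return An object of class `rdn_hyb_params`.
#' @export
hyb_params <- function(pair_weights, count_weights) {
  stopifnot(is.matrix(pair_weights), dim(pair_weights)[1] == 16L,
            length(dim(count_weights)) == 3L,
            dim(count_weights)[1] == length(NUCLEOTIDE_SETS),
            dim(count_weights)[2] == length(COUNT_RANGES),
            dim(count_weights)[3] == ncol(pair_weights))
  if (!all(is.finite(pair_weights)) || !all(is.finite(count_weights))) {
    stop("hybridization parameters must be finite.")
  }
  structure(list(pair_weights = pair_weights, count_weights = count_weights,
                 n_knots = ncol(pair_weights)),
            class = "rdn_hyb_params")
}

#' @rdname hyb_params
#' @param n_knots Knot weights per smooth.
#' @export
hyb_params_zero <- function(n_knots = 5L) {
  hyb_params(matrix(0, 16L, n_knots),
             array(0, c(length(NUCLEOTIDE_SETS), length(COUNT_RANGES), n_knots)))
}

#' @rdname hyb_params
#' @param x For `hyb_params_vector()`, an `rdn_hyb_params` object; for
#'   `hyb_params_from_vector()`, a numeric vector of length [n_hyb_params()].
#' @export
hyb_params_vector <- function(x) {
  stopifnot(inherits(x, "rdn_hyb_params"))
  Q <- x$n_knots
  pair <- as.vector(t(x$pair_weights))                       # p-major, q fast
  cw <- x$count_weights
  cnt <- as.vector(aperm(cw, c(3L, 2L, 1L)))                 # v-major, r, q fast
  c(pair, cnt)
}

#' @rdname hyb_params
#' @export
hyb_params_from_vector <- function(x, n_knots = 5L) {
  Q <- as.integer(n_knots)
  stopifnot(length(x) == n_hyb_params(Q))
  pair <- matrix(x[seq_len(16L * Q)], nrow = 16L, byrow = TRUE)
  rest <- x[-seq_len(16L * Q)]
  cnt <- aperm(array(rest, c(Q, length(COUNT_RANGES), length(NUCLEOTIDE_SETS))),
               c(3L, 2L, 1L))
  hyb_params(pair, cnt)
}

#' Evaluate the hybridization model
#'
#' Returns the per-probe hybridization effect in log2 scale. `tau()` accepts
#' either an `rdn_hyb_params` object or a bare parameter vector in
#' [hyb_design()] column order; precomputed designs avoid re-deriving the
#' basis when called repeatedly.
#'
#' @param params `rdn_hyb_params` or numeric vector.
#' @param sequences 25-nt probe sequences (ignored when `design` is given).
#' @param design Optional precomputed [hyb_design()] matrix.
#' @return Numeric vector of log2 effects, one per probe.
#' @export
tau <- function(params, sequences = NULL, design = NULL) {
  v <- if (inherits(params, "rdn_hyb_params")) hyb_params_vector(params) else params
  if (is.null(design)) {
    Q <- if (inherits(params, "rdn_hyb_params")) params$n_knots else {
      Qs <- length(v) / (16L + length(NUCLEOTIDE_SETS) * length(COUNT_RANGES))
      if (Qs != round(Qs)) stop("parameter vector length does not match any knot count.")
      as.integer(Qs)
    }
    design <- hyb_design(sequences, n_knots = Q)
  }
  drop(design %*% v)
}

#' Evaluate the amplification model
#'
#' The amplification difference of a probe is the inner product of its
#' dinucleotide-count vector (occurrences of each dinucleotide between the
#' probe centre and the probe-set 3' end) with a length-16 coefficient
#' vector, in log2 scale. A probe sitting at the 3' end of its probe set
#' (distance 0) has an empty count window and effect 0 for any coefficients.
#'
#' @param a Length-16 numeric vector of per-dinucleotide coefficients,
#'   ordered as `DINUCLEOTIDES`.
#' @param dinuc_counts A probes x 16 matrix of dinucleotide counts (e.g. the
#'   `dinuc` column of an annotation built by [read_probe_table()]).
#' @return Numeric vector of log2 amplification effects.
#' @export
kappa <- function(a, dinuc_counts) {
  if (length(a) != 16L || !all(is.finite(a))) {
    stop("`a` must be a finite length-16 vector.")
  }
  dinuc_counts <- as.matrix(dinuc_counts)
  stopifnot(ncol(dinuc_counts) == 16L)
  drop(dinuc_counts %*% a)
}
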