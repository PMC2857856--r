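# Probe-level data containers and the tabular interchange format.
#
# Mismatch probes are outside the data model: every row is a perfect-match
# probe. The interchange format is TSV with a fixed header:
#   probe_id  probeset_id  sequence  x  y  dist3  <one column per array>
# `dist3` (nucleotides between the probe centre, base 13 of 25, and the
# probe-set 3' end) may be replaced by `probe_pos` + `probeset_3prime_pos`
# transcript coordinates. Sixteen optional `cnt_AA` ... `cnt_TT` columns carry
# the per-dinucleotide counts of the centre-to-3'-end window; when absent they
# are reconstructed from the probes' own sequences (see
# `dinuc_counts_from_layout`).

ANNOT_COLS <- c("probe_id", "probeset_id", "sequence", "x", "y", "dist3")

#' Probe annotation table
#'
#' Validates a per-probe annotation data frame and attaches the
#' dinucleotide-count matrix used by the amplification model.
#'
#' @param df Data frame with columns `probe_id`, `probeset_id`, `sequence`
#'   (25-nt over A/C/G/T), `x`, `y` (0-based grid column/row), `dist3`
#'   (non-negative integer), and optionally a 16-column numeric matrix column
#'   `dinuc` (or 16 columns `cnt_AA` ... `cnt_TT`).
#' @return A tibble of class `rdn_annotation` with a `dinuc` matrix column.
#' @export
probe_annotation <- function(df) {
  df <- tibble::as_tibble(df)
  missing_cols <- setdiff(ANNOT_COLS, names(df))
  if (length(missing_cols) > 0) {
    stop("annotation is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  check_sequences(df$sequence)
  if (anyDuplicated(df$probe_id)) stop("duplicate probe_id values.")
  if (anyDuplicated(paste(df$x, df$y))) {
    stop("grid coordinates (x, y) must be unique per probe.")
  }
  if (any(df$dist3 < 0) || any(df$dist3 != round(df$dist3))) {
    stop("`dist3` must be non-negative integers.")
  }
  cnt_cols <- paste0("cnt_", DINUCLEOTIDES)
  if (!("dinuc" %in% names(df)) && all(cnt_cols %in% names(df))) {
    dn <- as.matrix(df[cnt_cols])
    colnames(dn) <- DINUCLEOTIDES
    df <- df[setdiff(names(df), cnt_cols)]
    df$dinuc <- dn
  }
  if (!("dinuc" %in% names(df))) {
    df$dinuc <- dinuc_counts_from_layout(df)
  }
  dn <- df$dinuc
  if (!is.matrix(dn) || ncol(dn) != 16L) stop("`dinuc` must be a 16-column matrix.")
  if (any(dn < 0)) stop("dinucleotide counts must be non-negative.")
  if (any(rowSums(dn) > df$dist3)) {
    stop("sum of dinucleotide counts exceeds `dist3` for some probe.")
  }
  df <- df[c(ANNOT_COLS, setdiff(names(df), c(ANNOT_COLS, "dinuc")), "dinuc")]
  class(df) <- c("rdn_annotation", class(df))
  df
}

#' Reconstruct dinucleotide counts from probe layout
#'
#' Counts, for each probe, the dinucleotides between the probe centre and the
#' probe-set 3' end, using only sequence observable from the set's own
#' probes: each probe of the set is placed on a common transcript coordinate
#' system (centre at `3'end - dist3`), known bases are filled in (3'-most
#' probes take precedence where probes overlap), and a dinucleotide at
#' positions `(t, t+1)` is counted only when both bases are known.
#' Unobserved gaps between probes are left uncounted, so the row sums are at
#' most `dist3`. A probe with `dist3 = 0` has an empty window and all-zero
#' counts.
#'
#' @param df Annotation data frame (`probeset_id`, `sequence`, `dist3`).
#' @return Integer matrix, rows matching `df`, 16 columns named by
#'   dinucleotide.
#' @export
dinuc_counts_from_layout <- function(df) {
  n <- nrow(df)
  out <- matrix(0L, n, 16L, dimnames = list(NULL, DINUCLEOTIDES))
  half <- (PROBE_LENGTH - 1L) %/% 2L  # 12 bases either side of the centre
  for (idx in split(seq_len(n), df$probeset_id)) {
    E <- max(df$dist3[idx])
    centres <- E - df$dist3[idx]
    lo <- -half  # most 5' base coordinate possible (centre coordinate 0)
    tr <- rep(NA_integer_, E + half - lo + 1L)
    pos0 <- 1L - lo  # index offset: coordinate t lives at tr[t + pos0]
    ord <- idx[order(df$dist3[idx], decreasing = TRUE)]  # 3'-most fill last
    for (j in ord) {
      cj <- E - df$dist3[j]
      tr[(cj - half + pos0):(cj + half + pos0)] <-
        match(strsplit(df$sequence[j], "", fixed = TRUE)[[1]], NUCLEOTIDES)
    }
    for (k in seq_along(idx)) {
      j <- idx[k]
      if (df$dist3[j] == 0L) next
      ts <- centres[k]:(E - 1L)
      b1 <- tr[ts + pos0]
      b2 <- tr[ts + 1L + pos0]
      ok <- !is.na(b1) & !is.na(b2)
      if (!any(ok)) next
      pair <- b1[ok] + 4L * (b2[ok] - 1L)
      tab <- tabulate(pair, nbins = 16L)
      out[j, ] <- tab
    }
  }
  out
}

#' Probe-level array set
#'
#' The central container: a validated probe annotation plus a probes x
#' arrays matrix of strictly positive linear-scale intensities.
#'
#' @param annotation An annotation data frame (passed through
#'   [probe_annotation()] unless already validated).
#' @param signals Numeric matrix, rows aligned with `annotation`, one column
#'   per array; strictly positive and finite.
#' @param array_ids Optional array labels (default: signal column names).
#' @param batch Optional per-array batch labels.
#' @return An object of class `rdn_arrayset` with fields `annotation`,
#'   `signals` and `batch`.
#' @export
rdn_arrayset <- function(annotation, signals, array_ids = NULL, batch = NULL) {
  if (!inherits(annotation, "rdn_annotation")) {
    annotation <- probe_annotation(annotation)
  }
  signals <- as.matrix(signals)
  storage.mode(signals) <- "double"
  if (nrow(signals) != nrow(annotation)) {
    stop("`signals` rows must match annotation rows.")
  }
  bad <- which(!is.finite(signals) | signals <= 0)
  if (length(bad) > 0) {
    rc <- arrayInd(bad[1], dim(signals))
    stop(sprintf("non-positive or non-finite intensity at probe row %d, array column %d.",
                 rc[1], rc[2]), call. = FALSE)
  }
  if (is.null(array_ids)) {
    array_ids <- colnames(signals)
    if (is.null(array_ids)) array_ids <- paste0("array_", seq_len(ncol(signals)))
  }
  stopifnot(length(array_ids) == ncol(signals))
  colnames(signals) <- array_ids
  if (!is.null(batch)) stopifnot(length(batch) == ncol(signals))
  structure(list(annotation = annotation, signals = signals, batch = batch),
            class = "rdn_arrayset")
}

#' @export
print.rdn_arrayset <- function(x, ...) {
  cat(sprintf("<rdn_arrayset> %d probes, %d probe sets, %d arrays\n",
              nrow(x$signals), length(unique(x$annotation$probeset_id)),
              ncol(x$signals)))
  if (!is.null(x$batch)) {
    cat("  batches:", paste(unique(x$batch), collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
dim.rdn_arrayset <- function(x) dim(x$signals)

#' Read / write the probe-level interchange table
#'
#' `read_probe_table()` reads a TSV with the fixed annotation header and one
#' intensity column per array into an [rdn_arrayset()];
#' `write_probe_table()` writes one back (always including the explicit
#' `cnt_*` dinucleotide columns, so a round trip is exact). When `dist3` is
#' absent, it is derived as `probeset_3prime_pos - probe_pos` from transcript
#' coordinates.
#'
#' @param path File path.
#' @param batch Optional per-array batch labels attached after reading.
#' @return An `rdn_arrayset` (reading); the input, invisibly (writing).
#' @export
read_probe_table <- function(path, batch = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (!("dist3" %in% names(df))) {
    if (all(c("probe_pos", "probeset_3prime_pos") %in% names(df))) {
      df$dist3 <- df$probeset_3prime_pos - df$probe_pos
      if (any(df$dist3 < 0)) stop("probe_pos lies 3' of probeset_3prime_pos.")
      df$probe_pos <- NULL
      df$probeset_3prime_pos <- NULL
    } else {
      stop("missing required column: dist3 (or probe_pos + probeset_3prime_pos).",
           call. = FALSE)
    }
  }
  missing_cols <- setdiff(setdiff(ANNOT_COLS, "dist3"), names(df))
  if (length(missing_cols) > 0) {
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  cnt_cols <- intersect(paste0("cnt_", DINUCLEOTIDES), names(df))
  sig_cols <- setdiff(names(df), c(ANNOT_COLS, cnt_cols))
  sig_cols <- sig_cols[vapply(df[sig_cols], is.numeric, logical(1))]
  if (length(sig_cols) < 1) stop("no intensity columns found.", call. = FALSE)
  ann <- probe_annotation(df[c(ANNOT_COLS, cnt_cols)])
  rdn_arrayset(ann, as.matrix(df[sig_cols]), array_ids = sig_cols, batch = batch)
}

#' @rdname read_probe_table
#' @param arrays An `rdn_arrayset`.
#' @export
write_probe_table <- function(arrays, path) {
  stopifnot(inherits(arrays, "rdn_arrayset"))
  ann <- arrays$annotation
  out <- tibble::as_tibble(ann[ANNOT_COLS])
  dn <- ann$dinuc
  colnames(dn) <- paste0("cnt_", DINUCLEOTIDES)
  out <- dplyr::bind_cols(out, tibble::as_tibble(dn),
                          tibble::as_tibble(arrays$signals))
  readr::write_tsv(out, path, progress = FALSE)
  invisible(arrays)
}

#' Read / write an expression matrix table
#'
#' Tab-separated, one row per probe set, one column per array, log2 scale.
#' `write_expression_table()` accepts either the result object of
#' [run_rdn()] / [summarize_probesets()] or a bare matrix with probe-set row
#' names. Probe sets dropped during QC are simply absent from the table; the
#' writer reports how many were dropped relative to the fit's input.
#'
#' @param expr An `rdn_expression` object or a numeric matrix with row names.
#' @param path File path.
#' @return The expression matrix (reading: matrix with probe-set row names).
#' @export
write_expression_table <- function(expr, path) {
  m <- if (inherits(expr, "rdn_expression")) expr$expression else as.matrix(expr)
  if (is.null(rownames(m))) stop("expression matrix must have probe-set row names.")
  if (inherits(expr, "rdn_expression") && nrow(expr$removed_probesets) > 0) {
    message(nrow(expr$removed_probesets),
            " probe set(s) removed by QC are absent from the output table.")
  }
  out <- dplyr::bind_cols(tibble::tibble(probeset_id = rownames(m)),
                          tibble::as_tibble(m))
  readr::write_tsv(out, path, progress = FALSE)
  invisible(expr)
}

#' @rdname write_expression_table
#' @export
read_expression_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (names(df)[1] != "probeset_id") stop("expected first column `probeset_id`.")
  m <- as.matrix(df[-1])
  rownames(m) <- df$probeset_id
  m
}
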