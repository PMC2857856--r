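# Evaluation protocols: truncated ROC on spike-in concentration pairs, a
# SAM-type regularized t statistic, and the batch top-gene overlap score.
# These score ANY probe-set expression matrix, so externally produced
# matrices can be compared on the same footing.

#' Truncated ROC score (ROC50)
#'
#' Ranks items by decreasing score and computes the area under the ROC curve
#' truncated at `max_fp` false positives, normalized to `[0, 1]`. When there
#' are fewer than `max_fp` negatives the truncation point is the number of
#' negatives, so the score then equals the full AUC. Ties are broken stably
#' in input order.
#'
#' @param scores Numeric vector of ranking scores (higher = more confident).
#' @param positives Logical vector (same length) or vector of positive
#'   indices/names into `scores`.
#' @param max_fp False-positive truncation point (default 50).
#' @return Scalar in `[0, 1]`.
#' @export
roc50 <- function(scores, positives, max_fp = 50L) {
  if (!all(is.finite(scores))) stop("`scores` must be finite.")
  n <- length(scores)
  lab <- if (is.logical(positives)) {
    stopifnot(length(positives) == n)
    positives
  } else if (is.character(positives)) {
    stopifnot(!is.null(names(scores)))
    names(scores) %in% positives
  } else {
    seq_len(n) %in% positives
  }
  p <- sum(lab)
  if (p == 0) stop("no positive examples; the score is undefined.")
  ord <- order(scores, decreasing = TRUE)  # stable for ties
  lab <- lab[ord]
  cutoff <- min(max_fp, n - p)
  if (cutoff == 0) return(1)  # no negatives at all
  fp_before <- cumsum(!lab)[which(lab)]  # negatives ranked above each positive
  sum(pmax(cutoff - fp_before, 0)) / (cutoff * p)
}

#' SAM-type test statistic
#'
#' Per-gene moderated mean-difference statistic
#' `d_g = (mean_a - mean_b) / (s_g + s0)`, with `s_g` the pooled standard
#' error and `s0` a fudge constant stabilizing low-variance genes
#' (`"auto"` = median of `s_g`). Single-array groups have no within-group
#' variance; the statistic then degrades to a fold change over `s0` (with a
#' warning), and `s0` must be positive.
#'
#' @param group_a,group_b Genes x arrays matrices (log2 expression) for the
#'   two groups; vectors are treated as single-array groups.
#' @param s0 Positive fudge constant, or `"auto"`.
#' @return Named list with `statistic` (per gene), `s` (pooled SE) and `s0`.
#' @export
sam_statistic <- function(group_a, group_b, s0 = "auto") {
  a <- as.matrix(group_a); b <- as.matrix(group_b)
  stopifnot(nrow(a) == nrow(b))
  na <- ncol(a); nb <- ncol(b)
  if (na < 1 || nb < 1) stop("each group needs at least one array.")
  diff <- rowMeans(a) - rowMeans(b)
  if (na + nb > 2) {
    ss <- (rowSums((a - rowMeans(a))^2) + rowSums((b - rowMeans(b))^2)) /
      (na + nb - 2)
    s <- sqrt((1 / na + 1 / nb) * ss)
  } else {
    warning("single-array groups: no pooled variance, statistic is fold change / s0.")
    s <- rep(0, nrow(a))
  }
  if (identical(s0, "auto")) {
    s0 <- stats::median(s)
    if (s0 == 0) s0 <- 1e-8
  }
  if (s0 <= 0 && any(s == 0)) {
    stop("zero-variance genes with s0 = 0 give infinite statistics; use s0 > 0.")
  }
  list(statistic = diff / (s + s0), s = s, s0 = s0)
}

#' Batch top-gene overlap score
#'
#' Measures agreement of ranked gene lists from different batches. For depth
#' `m`, each gene scores `max(0, (c_g(m) - 1) / (|B| - 1))` where `c_g(m)`
#' counts the batches whose top-`m` list contains the gene; `o(m)` sums the
#' gene scores, and the final score is the area under `o(m)` for `1 <= m <=
#' M` normalized by `sum(1..M)`. Identical lists score 1, pairwise-disjoint
#' lists 0; the score is invariant to gene relabelling and non-decreasing in
#' list agreement.
#'
#' @param toplists List (length >= 2) of ranked gene identifier vectors,
#'   most significant first; each of length >= `M`.
#' @param M Maximum list depth.
#' @return Scalar in `[0, 1]`.
#' @export
overlap_score <- function(toplists, M) {
  if (length(toplists) < 2) stop("need at least two batch lists.")
  if (any(vapply(toplists, length, integer(1)) < M)) {
    stop("`M` exceeds the length of the shortest list.")
  }
  nb <- length(toplists)
  genes <- unique(unlist(lapply(toplists, utils::head, M)))
  # rank of each gene in each batch (Inf when outside the top M)
  pos <- vapply(toplists, function(tl) {
    p <- match(genes, tl[seq_len(M)])
    ifelse(is.na(p), Inf, p)
  }, numeric(length(genes)))
  pos <- matrix(pos, nrow = length(genes))
  # gene g enters o(m) with weight 1/(nb-1) for every batch beyond its first
  # occurrence, from depth p_(t) onward
  total <- 0
  for (g in seq_along(genes)) {
    ps <- sort(pos[g, ])
    extra <- ps[-1]
    extra <- extra[is.finite(extra)]
    total <- total + sum(M - extra + 1)
  }
  total / ((nb - 1) * sum(seq_len(M)))
}

#' Cyclic spike-in concentration design
#'
#' Builds a Latin-square-style spike-in design: `n_groups` concentration
#' groups in 2-fold steps, each spike set entering the series at a rotated
#' offset, `replicates` arrays per group.
#'
#' @param spike_ids Probe-set ids of the spiked transcripts.
#' @param n_groups Number of concentration groups.
#' @param base_conc Lowest concentration (pmol); 0 is allowed for the first
#'   step of the series when `include_zero = TRUE`.
#' @param replicates Arrays per concentration group.
#' @param include_zero Replace the lowest concentration by 0.
#' @return An object of class `rdn_spike_design`: list with `concentration`
#'   (spike sets x arrays matrix), `groups` (array group index) and
#'   `spike_ids`.
#' @export
spike_design <- function(spike_ids, n_groups, base_conc = 0.25,
                         replicates = 1L, include_zero = FALSE) {
  ns <- length(spike_ids)
  series <- base_conc * 2^(seq_len(n_groups) - 1)
  if (include_zero) series[1] <- 0
  conc_group <- matrix(NA_real_, ns, n_groups,
                       dimnames = list(spike_ids, NULL))
  for (s in seq_len(ns)) {
    conc_group[s, ] <- series[((seq_len(n_groups) - 1 + (s - 1)) %% n_groups) + 1]
  }
  groups <- rep(seq_len(n_groups), each = replicates)
  conc <- conc_group[, groups, drop = FALSE]
  structure(list(concentration = conc, conc_group = conc_group,
                 groups = groups, spike_ids = spike_ids,
                 n_groups = n_groups, replicates = replicates),
            class = "rdn_spike_design")
}

#' Spike-in differential-expression benchmark
#'
#' For every pair of subsequent concentration groups, scores all probe sets
#' by absolute log2 fold change (or SAM statistic) between the two groups'
#' arrays, takes as positives the spike sets whose concentration steps
#' exactly 2-fold across the pair (including a step from 0 to the lowest
#' concentration), excludes spike sets with any other concentration change
#' from the ranking, and computes the truncated ROC. Pair scores are
#' averaged.
#'
#' @param expr Probe sets x arrays log2 expression matrix (row names =
#'   probe-set ids, columns aligned with the design's arrays).
#' @param design An [spike_design()].
#' @param stat `"fold"` (absolute mean log2 difference) or `"sam"`.
#' @param max_fp ROC truncation (default 50).
#' @return List with `score` (mean over pairs) and `per_pair` tibble.
#' @export
spikein_roc50 <- function(expr, design, stat = c("fold", "sam"), max_fp = 50L) {
  stopifnot(inherits(design, "rdn_spike_design"))
  stat <- match.arg(stat)
  expr <- as.matrix(expr)
  if (is.null(rownames(expr))) stop("`expr` needs probe-set row names.")
  stopifnot(ncol(expr) == length(design$groups))
  spike_rows <- match(design$spike_ids, rownames(expr))
  if (anyNA(spike_rows)) stop("spike ids missing from `expr` rows.")
  scores_pairs <- numeric(0)
  pair_tbl <- list()
  for (g in seq_len(design$n_groups - 1L)) {
    ia <- which(design$groups == g + 1L)
    ib <- which(design$groups == g)
    cg <- design$conc_group[, g]
    cg1 <- design$conc_group[, g + 1L]
    ratio2 <- (cg > 0 & cg1 == 2 * cg) | (cg == 0 & cg1 > 0)
    # spike sets with a non-2-fold change (Latin-square wrap) leave the ranking
    other_change <- !ratio2 & cg1 != cg
    keep <- rep(TRUE, nrow(expr))
    keep[spike_rows[other_change]] <- FALSE
    pos <- rep(FALSE, nrow(expr))
    pos[spike_rows[ratio2]] <- TRUE
    sc <- if (stat == "fold") {
      abs(rowMeans(expr[, ia, drop = FALSE]) - rowMeans(expr[, ib, drop = FALSE]))
    } else {
      abs(sam_statistic(expr[, ia, drop = FALSE],
                        expr[, ib, drop = FALSE])$statistic)
    }
    if (!any(pos[keep])) next
    r <- roc50(sc[keep], pos[keep], max_fp = max_fp)
    scores_pairs <- c(scores_pairs, r)
    pair_tbl[[length(pair_tbl) + 1L]] <-
      tibble::tibble(pair = g, roc50 = r, n_positive = sum(pos[keep]))
  }
  list(score = mean(scores_pairs), per_pair = dplyr::bind_rows(pair_tbl))
}
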