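test_that("truncated ROC handles the extreme rankings", {
  scores <- c(rep(10, 5), rep(1, 60))
  pos <- seq_len(5)
  expect_equal(roc50(scores, pos), 1)
  # all positives ranked after more than 50 negatives score zero
  scores2 <- c(rep(1, 5), rep(10, 60))
  expect_equal(roc50(scores2, pos), 0)
})

test_that("truncated ROC matches the exhaustive step-curve oracle", {
  withr::with_seed(71, {
    for (i in 1:20) {
      n <- 510
      scores <- rnorm(n)
      lab <- rep(FALSE, n)
      lab[sample(n, 10)] <- TRUE
      expect_equal(roc50(scores, lab), step_curve_roc(scores, lab, 50),
                   tolerance = 1e-12)
    }
  })
})

test_that("truncated ROC equals the full AUC when negatives are scarce", {
  withr::with_seed(72, {
    scores <- rnorm(60)
    lab <- rep(c(TRUE, FALSE), c(20, 40))
    full_auc <- {
      r <- rank(scores)
      (sum(r[lab]) - 20 * 21 / 2) / (20 * 40)
    }
    expect_equal(roc50(scores, lab, max_fp = 50), full_auc, tolerance = 1e-12)
  })
})

test_that("ROC without positives is undefined", {
  expect_error(roc50(rnorm(10), rep(FALSE, 10)), "positive")
})

test_that("SAM statistic has its closed forms and symmetries", {
  withr::with_seed(73, {
    a <- matrix(rnorm(50 * 3), 50)
    expect_equal(sam_statistic(a, a)$statistic, rep(0, 50))

    b <- a + 2  # constant shift
    s <- sam_statistic(b, a, s0 = 0)
    pooled <- sam_statistic(b, a)$s
    expect_equal(s$statistic, 2 / pooled)

    # antisymmetry under group swap
    g2 <- matrix(rnorm(50 * 3), 50)
    expect_equal(sam_statistic(a, g2, s0 = 0.1)$statistic,
                 -sam_statistic(g2, a, s0 = 0.1)$statistic)
  })
})

test_that("SAM null distribution calibrates against a permutation oracle", {
  withr::with_seed(74, {
    n_genes <- 2000
    x <- matrix(rnorm(n_genes * 6), n_genes)
    d_obs <- sam_statistic(x[, 1:3], x[, 4:6])$statistic
    perms <- utils::combn(6, 3)
    d_null <- unlist(lapply(seq_len(ncol(perms)), function(k) {
      g <- perms[, k]
      sam_statistic(x[, g], x[, -g])$statistic
    }))
    thr <- stats::quantile(abs(d_null), 0.95)
    hit_rate <- mean(abs(d_obs) > thr)
    expect_gt(hit_rate, 0.03)
    expect_lt(hit_rate, 0.07)
  })
})

test_that("single-array groups degrade to fold change with a warning", {
  x <- matrix(rnorm(20), 10)
  expect_warning(s <- sam_statistic(x[, 1, drop = FALSE],
                                    x[, 2, drop = FALSE], s0 = 1),
                 "single-array")
  expect_equal(s$statistic, x[, 1] - x[, 2])
})

test_that("overlap score spans its extremes and the worked example", {
  ids <- sprintf("g%02d", 1:20)
  expect_equal(overlap_score(list(ids, ids, ids), M = 10), 1)
  expect_equal(overlap_score(list(ids[1:8], ids[9:16]), M = 8), 0)
  expect_equal(overlap_score(list(c("g1", "g2"), c("g2", "g3")), M = 2), 1 / 3)
  expect_error(overlap_score(list(ids[1:3], ids[1:3]), M = 5), "shortest")
})

test_that("overlap score is relabelling-invariant and monotone in agreement", {
  withr::with_seed(75, {
    l1 <- sample(sprintf("g%03d", 1:100))
    l2 <- sample(sprintf("g%03d", 1:100))
    s0 <- overlap_score(list(l1, l2), M = 30)
    relabel <- setNames(sprintf("h%03d", 1:100), sprintf("g%03d", 1:100))
    expect_equal(overlap_score(list(unname(relabel[l1]), unname(relabel[l2])),
                               M = 30), s0)
    # making the second list agree more cannot lower the score
    l2_better <- c(l1[1:10], setdiff(l2, l1[1:10]))
    expect_gte(overlap_score(list(l1, l2_better), M = 30), s0)
  })
})

test_that("spike-in protocol scores a perfect expression matrix at 1", {
  withr::with_seed(76, {
    spikes <- sprintf("spk%02d", 1:5)
    des <- spike_design(spikes, n_groups = 8)
    others <- sprintf("bg%03d", 1:100)
    expr <- rbind(log2(des$concentration),
                  matrix(rnorm(100 * 8, 0, 1e-3), 100,
                         dimnames = list(others, NULL)))
    out <- spikein_roc50(expr, des)
    expect_equal(out$score, 1)
    expect_equal(nrow(out$per_pair), 7)
  })
})
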