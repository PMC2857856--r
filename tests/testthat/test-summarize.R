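test_that("noise-free generative data is recovered exactly", {
  withr::with_seed(61, {
    np <- 11; K <- 6
    omega <- 6.5
    alpha <- rnorm(K); alpha <- alpha - mean(alpha)
    rho <- rnorm(np, 0, 0.5); rho <- rho - mean(rho)
    o <- 40
    y <- o + 2^(omega + outer(rho, alpha, `+`))
    fit <- fit_probeset(y, b = rep(0, np), o = o)
    expect_equal(fit$omega, omega, tolerance = 1e-6)
    expect_equal(fit$alpha, alpha, tolerance = 1e-6)
    expect_equal(fit$rho, rho, tolerance = 1e-6)
    expect_true(all(fit$weights == 1))
  })
})

test_that("identifiability constraints hold to machine precision", {
  withr::with_seed(62, {
    y <- (50 + 2^(7 + outer(rnorm(8, 0, 0.4), rnorm(5), `+`))) *
      2^matrix(rnorm(40, 0, 0.2), 8)
    fit <- fit_probeset(y, b = runif(8, 0, 60), o = 50)
    expect_lt(abs(sum(fit$alpha)), 1e-10)
    expect_lt(abs(sum(fit$rho)), 1e-10)
  })
})

test_that("constant arrays give exactly zero fold changes", {
  withr::with_seed(63, {
    v <- 60 + 2^rnorm(7, 8, 0.5)
    y <- matrix(v, 7, 4)
    fit <- fit_probeset(y, b = rep(10, 7), o = 50)
    expect_equal(fit$alpha, rep(0, 4), tolerance = 1e-8)
  })
})

test_that("background-dominated probes lose leverage on fold changes", {
  np <- 8; K <- 6
  alpha <- c(1, -1, 0.5, -0.5, 0.4, -0.4)
  rho <- rep(0, np)
  o <- 30
  b <- rep(0, np)
  b[1] <- 6000  # one probe is swamped by non-specific binding
  y <- o + rep(b, K) + 2^(6 + outer(rho, alpha, `+`))
  dim(y) <- c(np, K)
  # probes 1 and 2 carry the same deliberate discrepancy (+0.4 log2 of
  # foreground on half the arrays); the background-dominated probe 1 must
  # pull the fold changes far less than its clean twin
  discord <- 2^c(0.4, 0.4, 0.4, 0, 0, 0)
  y[1, ] <- o + b[1] + (y[1, ] - o - b[1]) * discord
  y[2, ] <- o + (y[2, ] - o) * discord

  f_base <- fit_probeset(y[-c(1, 2), ], b[-c(1, 2)], o)
  leverage <- function(keep_probe) {
    f <- fit_probeset(y[-setdiff(1:2, keep_probe), ],
                      b[-setdiff(1:2, keep_probe)], o)
    max(abs(f$alpha - f_base$alpha))
  }
  infl_bg <- leverage(1)   # adding the background-dominated discordant probe
  infl_fg <- leverage(2)   # adding the equal-foreground discordant probe
  expect_lt(infl_bg, 0.2 * infl_fg)
})

test_that("outlier-probe rule flags, orders and respects the floor", {
  w_ok <- matrix(1, 11, 6)
  expect_true(all(remove_outlier_probes(w_ok)$retained))

  # weight 0.2 on half of the arrays -> more than one-third -> removed
  w <- matrix(1, 11, 6)
  w[4, 1:3] <- 0.2
  out <- remove_outlier_probes(w)
  expect_equal(which(!out$retained), 4L)

  # low weight on exactly one-third of the arrays is not enough
  w2 <- matrix(1, 11, 6)
  w2[4, 1:2] <- 0.2
  expect_true(all(remove_outlier_probes(w2)$retained))

  # 6-probe set with 3 bad probes: only the worst one goes (floor of 5)
  w3 <- matrix(1, 6, 6)
  w3[1, 1:3] <- 0.5
  w3[2, 1:4] <- 0.5
  w3[3, 1:5] <- 0.5
  out3 <- remove_outlier_probes(w3, floor = 5)
  expect_equal(which(!out3$retained), 3L)  # worst first
  expect_equal(sum(out3$retained), 5L)

  # sets at or below the floor are never reduced
  w4 <- matrix(0.1, 4, 6)
  expect_true(all(remove_outlier_probes(w4, floor = 5)$retained))
})

test_that("backscaling shrinks fold changes monotonically in background", {
  expect_equal(backscale_alpha(4, 1, 0), 1)
  expect_equal(backscale_alpha(4, 1, 2^4), log2(48 / 32))
  expect_lt(backscale_alpha(4, 1, 1e12), 1e-6)
  withr::with_seed(65, {
    omega <- runif(50, 2, 10)
    alpha <- rnorm(50, 0, 2)
    f <- runif(50, 0, 500)
    bs <- backscale_alpha(omega, alpha, f)
    expect_true(all(abs(bs) <= abs(alpha) + 1e-12))
    expect_true(all(sign(bs) == sign(alpha) | bs == 0))
    # monotone in f
    bs2 <- backscale_alpha(omega, alpha, f * 2)
    expect_true(all(abs(bs2) <= abs(bs) + 1e-12))
  })
})

test_that("probe-set summarization enforces constraints and records removals", {
  cfg <- synth_config(n_probesets = 25, n_arrays = 5, seed = 66, n_spike = 3,
                      optical_shift = 0, hyb_bg_sd = 0, hyb_fg_sd = 0,
                      amp_sd = 0, blemish = list())
  sim <- synth_generate(cfg)
  ref <- known_reference(sim)
  res <- summarize_probesets(sim$arrays, ref)
  expect_lt(max(abs(rowSums(res$alpha))), 1e-8)
  for (r in res$rho) expect_lt(abs(sum(r)), 1e-8)
  expect_true(all(abs(res$alpha_backscaled) <= abs(res$alpha) + 1e-12))
  # every probe set keeps at least 5 probes (or all it started with)
  for (id in names(res$rho)) expect_gte(length(res$rho[[id]]), 5L)
})
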