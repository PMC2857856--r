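test_that("reference is the element-wise median across arrays", {
  arrays <- tiny_arrayset(n_sets = 1, npp = 1, K = 3,
                          signal_fun = function(n, K) matrix(c(1, 2, 9), 1))
  expect_equal(build_reference(arrays), 2)

  arrays2 <- tiny_arrayset(n_sets = 20, npp = 5, K = 5, seed = 31)
  ref <- build_reference(arrays2)
  oracle <- apply(arrays2$signals, 1, function(v) {
    sv <- sort(v); (sv[3])  # odd count: middle order statistic
  })
  expect_equal(ref, oracle)

  same <- arrays2
  same$signals <- matrix(arrays2$signals[, 1], nrow(arrays2$signals), 5)
  expect_equal(build_reference(same), arrays2$signals[, 1])
})

test_that("a single array cannot define a reference", {
  arrays <- tiny_arrayset(K = 3)
  arrays$signals <- arrays$signals[, 1, drop = FALSE]
  expect_error(build_reference(arrays), "reference-free")
})

test_that("decomposition obeys s = o + b + x with clamping at the headroom", {
  d1 <- decompose_reference(100, 10, 30)
  expect_equal(d1$b, 30); expect_equal(d1$x, 60)
  d2 <- decompose_reference(100, 10, 300)
  expect_equal(d2$b, 90); expect_equal(d2$x, 0)
  withr::with_seed(32, {
    s <- runif(500, 1, 1000)
    bg <- runif(500, 0, 800)
    o <- 25
    d <- decompose_reference(s, o, bg)
    expect_true(all(d$x >= 0))
    expect_true(all(d$b >= 0))
    above <- s >= o
    expect_lt(max(abs((d$o + d$b + d$x - s)[above])), 1e-9)
  })
})

test_that("background fit recovers optical floor and probe backgrounds", {
  # pure background data: negligible true signal, no per-array effects
  cfg <- synth_config(n_probesets = 150, n_arrays = 4, seed = 33, n_spike = 0,
                      expr_range = c(-12, -10), noise_sd = 0,
                      optical_shift = 0, hyb_bg_sd = 0, hyb_fg_sd = 0,
                      amp_sd = 0, blemish = list(), optical = 50)
  sim <- synth_generate(cfg)
  bg <- suppressWarnings(fit_background(sim$arrays, eta = 10))
  expect_lt(abs(bg$o_ref - 50) / 50, 0.05)
  rel_err <- abs(bg$bg_hat - sim$truth$background) / sim$truth$background
  expect_lt(median(rel_err), 0.10)
  expect_gt(cor(bg$bg_hat, sim$truth$background, method = "spearman"), 0.95)
})

test_that("eta controls the asymmetry of the background fit", {
  cfg <- synth_config(n_probesets = 120, n_arrays = 4, seed = 34, n_spike = 0,
                      expr_range = c(-12, -10), noise_sd = 0.2,
                      optical_shift = 0, hyb_bg_sd = 0, hyb_fg_sd = 0,
                      amp_sd = 0, blemish = list())
  sim <- synth_generate(cfg)
  bg1 <- suppressWarnings(fit_background(sim$arrays, eta = 1))
  bg10 <- suppressWarnings(fit_background(sim$arrays, eta = 10))
  r1 <- bg1$target - log2(bg1$o_ref + bg1$bg_hat)
  r10 <- bg10$target - log2(bg10$o_ref + bg10$bg_hat)
  # symmetric loss balances the residual signs
  expect_lt(abs(mean(sign(r1))), 0.1)
  # strong overestimation penalty makes the model under-predict most probes
  expect_gt(mean(r10 > 0), 0.5)
})

test_that("raising eta never increases the fitted background level", {
  for (seed in 35:37) {
    cfg <- synth_config(n_probesets = 80, n_arrays = 3, seed = seed,
                        n_spike = 0, expr_range = c(-12, -10), noise_sd = 0.25,
                        optical_shift = 0, hyb_bg_sd = 0, hyb_fg_sd = 0,
                        amp_sd = 0, blemish = list())
    sim <- synth_generate(cfg)
    levels <- vapply(c(1, 3, 10), function(eta) {
      bg <- suppressWarnings(fit_background(sim$arrays, eta = eta))
      mean(log2(bg$o_ref + bg$bg_hat))
    }, numeric(1))
    expect_true(all(diff(levels) <= 1e-6))
  }
})

test_that("eta below one is rejected", {
  arrays <- tiny_arrayset()
  expect_error(fit_background(arrays, eta = 0.5), "eta")
})
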