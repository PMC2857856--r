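# Per-array difference fits are checked by parameter recovery on data built
# from a known reference with a single injected effect.

make_clean_sim <- function(seed = 41, n_probesets = 150) {
  cfg <- synth_config(n_probesets = n_probesets, n_arrays = 4, seed = seed,
                      n_spike = 0, noise_sd = 0, optical_shift = 0,
                      hyb_bg_sd = 0, hyb_fg_sd = 0, amp_sd = 0,
                      blemish = list())
  synth_generate(cfg)
}

test_that("an array identical to the reference fits to zero effects", {
  sim <- make_clean_sim()
  ref <- known_reference(sim)
  designs <- rdn_designs(sim$arrays$annotation)
  fit <- fit_array_difference(ref$s, ref, designs)
  expect_lt(abs(fit$d), 0.01 * ref$o)
  expect_lt(max(abs(fit$tau_f)), 0.02)
  expect_lt(max(abs(fit$tau_b)), 0.05)
  expect_lt(max(abs(fit$a)), 1e-3)
  t_ij <- log2(fit$s_hat) - log2(ref$s)
  expect_lt(median(abs(t_ij)), 0.05)
})

test_that("an injected GC-dependent foreground gain is recovered", {
  sim <- make_clean_sim(42)
  ref <- known_reference(sim)
  ann <- sim$arrays$annotation
  designs <- rdn_designs(ann)
  gc <- vapply(strsplit(ann$sequence, ""), function(s) sum(s %in% c("C", "G")),
               numeric(1))
  gain <- 0.5 * (gc - mean(gc)) / max(abs(gc - mean(gc)))
  s <- ref$o + ref$b + ref$x * 2^gain
  fit <- fit_array_difference(s, ref, designs,
                              steps = c(optical = FALSE, hyb = TRUE, amp = FALSE))
  expressed <- ref$x > 1
  expect_gt(cor(fit$tau_f[expressed], gain[expressed]), 0.95)
})

test_that("an injected amplification gradient is recovered elementwise", {
  sim <- make_clean_sim(43)
  ref <- known_reference(sim)
  designs <- rdn_designs(sim$arrays$annotation)
  a_true <- withr::with_seed(44, rnorm(16, 0, 0.003))
  s <- ref$o + ref$b + ref$x * 2^drop(designs$amp %*% a_true)
  fit <- fit_array_difference(s, ref, designs,
                              steps = c(optical = FALSE, hyb = FALSE, amp = TRUE))
  populated <- colSums(designs$amp) > stats::quantile(colSums(designs$amp), 0.25)
  expect_lt(max(abs((fit$a - a_true) / a_true)[populated]), 0.10)
})

test_that("an injected optical shift is recovered", {
  sim <- make_clean_sim(45)
  ref <- known_reference(sim)
  designs <- rdn_designs(sim$arrays$annotation)
  fit <- fit_array_difference(ref$s + 18, ref, designs,
                              steps = c(optical = TRUE, hyb = FALSE, amp = FALSE))
  expect_lt(abs(fit$d - 18) / 18, 0.10)
})

test_that("difference correction inverts the fitted model", {
  sim <- make_clean_sim(46, n_probesets = 60)
  ref <- known_reference(sim)
  designs <- rdn_designs(sim$arrays$annotation)

  # zero-effect fit: identity
  fit0 <- fit_array_difference(ref$s, ref, designs,
                               steps = c(optical = FALSE, hyb = FALSE, amp = FALSE))
  expect_equal(apply_difference_correction(ref$s, fit0, ref), ref$s)

  # an array that is exactly the fitted model maps back onto the reference
  withr::with_seed(47, {
    gain <- drop(designs$hyb %*% rnorm(230, 0, 0.02))
  })
  s <- (ref$o + 12) + ref$b + ref$x * 2^gain
  fit <- fit_array_difference(s, ref, designs)
  expect_equal(apply_difference_correction(fit$s_hat, fit, ref), ref$s,
               tolerance = 1e-9)
  # and the corrected observed array is close to the reference
  corr <- apply_difference_correction(s, fit, ref)
  expect_lt(median(abs(log2(corr) - log2(ref$s))), 0.05)
})

test_that("quantile normalization equalizes distributions and is idempotent", {
  withr::with_seed(48, {
    m <- matrix(2^runif(4000, 4, 12), 1000, 4)
    q1 <- quantile_to_reference(m)
    sorted <- apply(q1, 2, sort)
    expect_equal(sorted[, 1], sorted[, 2])
    expect_equal(sorted[, 1], sorted[, 3])
    expect_equal(sorted[, 1], sorted[, 4])
    # rank order preserved within each column
    for (i in 1:4) expect_equal(order(q1[, i]), order(m[, i]))
    # idempotence
    expect_lt(max(abs(quantile_to_reference(q1) - q1)), 1e-9)
  })
})

test_that("a shuffled copy of the reference maps back onto it", {
  withr::with_seed(49, {
    v <- sort(2^runif(200, 3, 10))
    m <- cbind(v, sample(v), sample(v))
    q <- quantile_to_reference(m)
    expect_equal(unname(q), unname(m))
  })
})
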