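# Delta-lambda, switch counting, x_bar, bootstrap, eta

test_that("delta_lambda implements both conventions including the 0/360 boundary", {
  expect_equal(delta_lambda(c(10, 40, 45, 70)), c(30, 5, 25))
  expect_equal(delta_lambda(rep(123.4, 5)), rep(0, 4))
  # the boundary case that separates the conventions, hand-checked:
  # wrapped values 355 -> 5 differ by 350 literally, 10 along the circle
  expect_equal(delta_lambda(c(355, 5), "literal"), 350)
  expect_equal(delta_lambda(c(355, 5), "circular"), 10)
  expect_error(delta_lambda(42), "insufficient")
})

test_that("switch counting is inclusive at the threshold", {
  expect_equal(count_switches(c(30, 5, 25)), 2)
  expect_equal(count_switches(19.999), 0)
  expect_equal(count_switches(20.0), 1)
})

test_that("x_bar is the population mean of per-molecule counts and respects bounds", {
  expect_equal(mean_switches(list(c(10, 40, 45, 70), c(0, 30, 60, 90)))$x_bar,
               mean(c(2, 3)))
  s25 <- mean_switches(replicate(25, c(0, 25, 50, 75), simplify = FALSE))
  expect_equal(s25$x_bar, 3)  # degenerate mean: every molecule identical
  sw <- mean_switches(list(c(0, 30, 35, 90), c(0, 5, 10, 15)))
  expect_gte(sw$x_bar, min(sw$per_molecule_switches))
  expect_lte(sw$x_bar, max(sw$per_molecule_switches))
  expect_error(mean_switches(list()), "insufficient")
})

test_that("circular switch counts are invariant to a constant lambda offset", {
  set.seed(21)
  for (i in 1:20) {
    lam <- cumsum(c(runif(1, 0, 360), runif(99, -40, 40)))
    off <- runif(1, 0, 360)
    c0 <- count_switches(delta_lambda(wrap_360(lam), "circular"))
    c1 <- count_switches(delta_lambda(wrap_360(lam + off), "circular"))
    expect_equal(c1, c0)
  }
})

test_that("bootstrap of x_bar matches the exhaustively enumerated resample space", {
  # two molecules with counts {0, 2}: the 4 equally likely resamples give
  # means {0, 1, 1, 2}, so E = 1 and sd = sqrt(1/2)
  b <- bootstrap_x_bar(c(0, 2), n_resamples = 1000, seed = 99)
  expect_length(b$resampled_x_bars, 1000)
  expect_true(all(b$resampled_x_bars %in% c(0, 1, 2)))
  expect_lt(abs(b$mean - 1), 3 * sqrt(0.5) / sqrt(1000))

  # degenerate distribution
  expect_equal(bootstrap_x_bar(rep(4, 10), seed = 1)$sd, 0)
  # seed reproducibility, and the seed is recorded
  b2 <- bootstrap_x_bar(c(0, 2), n_resamples = 1000, seed = 99)
  expect_identical(b$resampled_x_bars, b2$resampled_x_bars)
  expect_identical(b$seed, 99)
  expect_error(bootstrap_x_bar(3), "insufficient")
})

test_that("bootstrap mean converges to the sample mean (both resampling units)", {
  set.seed(31)
  counts <- rpois(25, 50)
  b <- bootstrap_x_bar(counts, n_resamples = 1000, seed = 7)
  # the mean of 1000 resampled means has standard error ~ sd(counts)/sqrt(25)/sqrt(1000)
  se_boot <- sd(counts) / sqrt(25) / sqrt(1000)
  expect_lt(abs(b$mean - mean(counts)), 3 * se_boot)

  # frame-level delta-lambda resampling is also reproducible given a seed
  dl <- replicate(5, runif(50, 0, 60), simplify = FALSE)
  f1 <- bootstrap_x_bar(dl, n_resamples = 200, seed = 3, unit = "steps")
  f2 <- bootstrap_x_bar(dl, n_resamples = 200, seed = 3, unit = "steps")
  expect_identical(f1$resampled_x_bars, f2$resampled_x_bars)
})

test_that("eta is the max/min ratio with the documented limits and invariances", {
  expect_equal(compute_eta(list(cc = 4, ct = 4, tc = 4, tt = 4))$eta, 1)
  r <- compute_eta(list(cc = 2, ct = 1, tc = 2, tt = 2))
  expect_equal(r$eta, 2)
  expect_equal(r$state_min, "ct")
  expect_gte(compute_eta(list(a = runif(1, 1, 9), b = runif(1, 1, 9)))$eta, 1)
  # scale invariance
  x <- c(cc = 3.2, ct = 1.6, tc = 2.4, tt = 1.9)
  expect_equal(compute_eta(x * 17)$eta, compute_eta(x)$eta)
  # degenerate minimum is representable, not fatal
  expect_warning(z <- compute_eta(list(cc = 0, ct = 2)), "infinite")
  expect_identical(z$eta, Inf)
  expect_error(compute_eta(list(cc = 1)), "insufficient")
})

test_that("switch-rate recovery: x_bar matches the binomial expectation across seeds", {
  n_frames <- 800; n_mol <- 25; N <- n_frames - 1
  for (p in c(0.005, 0.02, 0.1)) {
    hits <- 0L
    for (seed in 1:10) {
      g <- generate_ensemble(synthetic_spec(
        n_molecules = n_mol, n_frames = n_frames,
        switch_probability = p, seed = seed))
      lm <- g$truth$lambda
      xb <- mean_switches(lm, convention = "circular")$x_bar
      se <- sqrt(N * p * (1 - p) / n_mol)
      if (abs(xb - N * p) <= 3 * se) hits <- hits + 1L
    }
    expect_gte(hits, 9L)
  }
})
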