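test_that("computePeth averages trials elementwise", {
  expect_equal(computePeth(rbind(c(0, 1), c(2, 3))), c(1, 2))
  one <- matrix(c(1, 0, 2, 5), 1)
  expect_equal(computePeth(rbind(one, one, one)[, , drop = FALSE]),
               drop(one))
  ## duplicating the trial set leaves the PETH unchanged
  set.seed(1)
  tc <- matrix(rpois(60, 2), 6, 10)
  expect_equal(computePeth(rbind(tc, tc)), computePeth(tc))
})

test_that("PETH of a modulated synthetic unit peaks at the planted latent time", {
  sim <- quickSession(nUnits = c(10, 10), nTrials = 60, seed = 31)
  al <- alignTrials(sim$session, "reach_start", c(-1, 1), 100)
  ## unit whose local loading dominates its shared loading
  u <- which.max(sim$truth$wLocal$M2 - 2 * abs(sim$truth$wShared$M2[, 1]))
  tc <- t(vapply(al$M2, function(b) counts(b)[, u], numeric(20)))
  peth <- computePeth(tc)
  pk <- binTimes(al$M2[[1]])[which.max(peth)]
  ## local bump center: reach - lag/2 + per-unit offset (jitter averages out)
  expect_lt(abs(pk - (-0.05 + sim$truth$localOffset$M2[u])), 0.15)
})

test_that("circular shuffle test flags locked modulation and not noise", {
  set.seed(5)
  tc <- matrix(rpois(50 * 20, 1), 50, 20)
  tc[, 10] <- tc[, 10] + rpois(50, 8)
  res <- circularShuffleTest(tc, nShuffles = 10000, seed = 2)
  expect_equal(res$p, 1 / 10001)            # +1-corrected floor
  expect_lt(res$p, 0.000125)                # significant at the printed alpha
  expect_true(res$significant)
  expect_equal(res$peakBin, 10L)

  expect_error(circularShuffleTest(matrix(1, 5, 1)), "2 bins")
  z <- circularShuffleTest(matrix(0, 5, 8), nShuffles = 10)
  expect_equal(z$p, 1)
})

test_that("circular shuffle p-values are calibrated for stationary units", {
  set.seed(6)
  ps <- replicate(150, {
    circularShuffleTest(matrix(rpois(30 * 15, 2), 30, 15),
                        nShuffles = 200, seed = sample.int(1e6, 1))$p
  })
  ## super-uniform: rejection rate at 0.05 within binomial bounds
  expect_lt(mean(ps < 0.05), 0.05 + 2.58 * sqrt(0.05 * 0.95 / 150))
  expect_lt(mean(ps < 0.01), 0.01 + 2.58 * sqrt(0.01 * 0.99 / 150))
})

test_that("normalized cross-correlation finds peak lag and value", {
  set.seed(7)
  a <- rnorm(400)
  self <- normalizedXcorr(a, a, 100, 200)
  expect_equal(self$peakLagMs, 0)
  expect_gt(self$value, 0)

  b <- c(rep(0, 1), a[1:399])   # B trails A by one bin (+100 ms)
  expect_equal(normalizedXcorr(a, b, 100, 200)$peakLagMs, 100)

  ## swap symmetry: r_AB(lag) = r_BA(-lag)
  x <- normalizedXcorr(a, b, 100, 200)
  y <- normalizedXcorr(b, a, 100, 200)
  expect_equal(x$r, rev(y$r))
  expect_equal(x$value, y$value)
  expect_equal(x$peakLagMs, -y$peakLagMs)

  expect_equal(normalizedXcorr(rep(1, 50), rnorm(50), 100, 200)$value, 0)
  expect_error(normalizedXcorr(a, a, 150, 200), "divide")

  ## independent white noise: mean value matches the expected maximum of
  ## five near-independent null correlations, E[max] ~ 1.163 / sqrt(n)
  vals <- replicate(300, normalizedXcorr(rnorm(200), rnorm(200), 100, 200)$value)
  expect_lt(abs(mean(vals) - 1.163 / sqrt(198)), 0.02)
})

test_that("cross-correlation vs CCA-weight regression behaves", {
  x <- seq(0.1, 1, length.out = 10)
  fit <- xcorrWeightRegression(2 * x, x)
  expect_equal(fit$slope, 2, tolerance = 1e-12)
  expect_equal(fit$r.squared, 1, tolerance = 1e-12)
  expect_error(xcorrWeightRegression(1:2, 1:2), "3 pairs")

  ## null calibration
  set.seed(8)
  ps <- replicate(200, xcorrWeightRegression(rnorm(50), rnorm(50))$p)
  expect_lt(abs(mean(ps < 0.05) - 0.05), 0.05)

  ## weak planted relation at the scale reported for real pairs
  set.seed(9)
  w <- rnorm(5000)
  y <- sqrt(0.08) * w + sqrt(0.92) * rnorm(5000)
  expect_lt(abs(xcorrWeightRegression(y, w)$r.squared - 0.08), 0.02)
})
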