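test_that("local projection decomposes population vectors exactly", {
  set.seed(1)
  W <- matrix(rnorm(10 * 2), 10, 2)
  Q <- qr.Q(qr(W))
  ## vector inside the shared span: no local component
  x <- t(Q %*% c(2, -1))
  d <- localProjection(x, W)
  expect_equal(d$localMag, 0, tolerance = 1e-8)
  expect_equal(d$sharedMag, sqrt(5), tolerance = 1e-8)
  ## vector orthogonal to the span: all local
  v <- rnorm(10); v <- v - Q %*% crossprod(Q, v)
  d <- localProjection(t(v), W)
  expect_equal(d$sharedMag, 0, tolerance = 1e-8)
  expect_equal(d$localMag, sqrt(sum(v^2)), tolerance = 1e-8)
  ## Pythagorean identity on random data
  X <- matrix(rnorm(500), 50, 10)
  d <- localProjection(X, W)
  expect_lt(max(abs(d$sharedMag^2 + d$localMag^2 - d$totalMag^2)), 1e-8)
  ## local magnitude invariant to adding any in-span vector
  d2 <- localProjection(X + matrix(Q %*% c(3, 3), 50, 10, byrow = TRUE), W)
  expect_equal(d2$localMag, d$localMag, tolerance = 1e-8)
  expect_error(localProjection(X, diag(10)), "complement")
})

test_that("trialMedianTiming implements the cumulative-half rule", {
  tm <- seq(-0.95, 0.95, by = 0.1)
  bump <- exp(-(tm - 0.25)^2 / 0.02)
  expect_lt(abs(trialMedianTiming(bump, tm) - 0.25), 0.05 + 1e-9)
  onebin <- rep(0, 20); onebin[4] <- 5
  expect_equal(trialMedianTiming(onebin, tm), tm[4])
  expect_true(is.na(trialMedianTiming(rep(0, 20), tm)))
  expect_error(trialMedianTiming(c(-1, 1), c(0, 1)), "nonnegative")
})

test_that("timing permutation test: antisymmetry, power, calibration", {
  set.seed(2)
  d <- rnorm(100, -0.1, 0.25)
  res <- timingPermutationTest(d, nPerm = 2000, seed = 3)
  expect_lt(res$p, 0.01)
  expect_equal(res$statistic, mean(d))
  ## full label swap negates the statistic exactly
  resSwap <- timingPermutationTest(-d, nPerm = 2000, seed = 3,
                                   alternative = "greater")
  expect_equal(resSwap$statistic, -res$statistic)
  expect_equal(resSwap$p, res$p)
  ## calibration under an exchangeable null
  ps <- replicate(120, timingPermutationTest(rnorm(40, 0, 0.2), nPerm = 200,
                                             seed = sample.int(1e6, 1))$p)
  expect_lt(mean(ps < 0.05), 0.05 + 2.58 * sqrt(0.05 * 0.95 / 120))
  ## NA pairs excluded and counted
  res2 <- timingPermutationTest(c(d, NA, NA), nPerm = 100, seed = 1)
  expect_equal(res2$nExcluded, 2L)
  expect_error(timingPermutationTest(c(0.1, NA), nPerm = 10), "2 complete")
})

test_that("coupling-change test detects tightening and is label-symmetric", {
  set.seed(4)
  early <- rnorm(150, -0.12, 0.15)
  late <- rnorm(150, -0.02, 0.15)
  res <- couplingChangeTest(early, late, nPerm = 2000, seed = 5)
  expect_lt(res$p, 0.01)
  expect_equal(res$statistic, mean(late) - mean(early))
  ## the two one-sided tails are complementary up to the +1 correction
  resL <- couplingChangeTest(early, late, nPerm = 2000, seed = 5,
                             alternative = "less")
  expect_lt(abs(res$p + resL$p - (2 + 2000) / (1 + 2000)), 2 / 2001)
  ## swapping groups negates the statistic
  res2 <- couplingChangeTest(late, early, nPerm = 500, seed = 5)
  expect_equal(res$statistic, -res2$statistic)
  expect_error(couplingChangeTest(numeric(0), late), "nonempty")
  ## identical groups: p well away from significance
  same <- rnorm(100)
  expect_gt(couplingChangeTest(same, same, nPerm = 500, seed = 6)$p, 0.2)
})

test_that("the local-timing pipeline recovers a planted M2 lead", {
  sim <- quickSession(nUnits = c(20, 20), nTrials = 150, seed = 61)
  fit <- sessionCCA(sim$session)
  tt <- localTimingTable(fit, nCV = 1)
  expect_true(all(abs(tt$tA) <= 1) && all(abs(tt$tB) <= 1))
  expect_lt(mean(tt$diff), 0)                       # M2 leads on average
  res <- timingPermutationTest(tt$diff, nPerm = 1000, seed = 7)
  expect_lt(res$p, 0.05)
})
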