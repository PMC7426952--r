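test_that("fitCCA reproduces known fixed points and matches cancor", {
  set.seed(1)
  X <- matrix(rnorm(1000), 200, 5)
  ## identical (up to invertible mixing) data: all correlations 1
  m <- fitCCA(X, X %*% matrix(rnorm(25), 5, 5) + 0)
  expect_equal(canonicalCors(m), rep(1, 5), tolerance = 1e-6)

  Y <- X %*% matrix(rnorm(30), 5, 6) + 2 * matrix(rnorm(1200), 200, 6)
  m <- fitCCA(X, Y)
  cc <- cancor(scale(X, scale = FALSE), scale(Y, scale = FALSE))
  expect_equal(canonicalCors(m), cc$cor, tolerance = 1e-8)
  ## training projections correlate at exactly rho_j
  for (j in 1:3) {
    pa <- ccaProject(m, X, "M2", j); pb <- ccaProject(m, Y, "M1", j)
    expect_equal(abs(cor(pa, pb)), canonicalCors(m)[j], tolerance = 1e-8)
  }
  ## correlations nonincreasing in [0, 1]
  expect_true(all(diff(canonicalCors(m)) <= 1e-12))
  expect_true(all(canonicalCors(m) >= 0 & canonicalCors(m) <= 1))

  expect_error(fitCCA(X[1:4, ], Y[1:4, ]), "more time bins")
  expect_warning(fitCCA(cbind(X, 0), Y), "zero-variance")
})

test_that("top canonical correlation matches brute-force maximization", {
  set.seed(2)
  for (i in 1:3) {
    X <- matrix(rnorm(200 * 5), 200, 5)
    Y <- 0.4 * X[, sample(5)] + matrix(rnorm(200 * 5), 200, 5)
    m <- fitCCA(X, Y)
    expect_lt(abs(canonicalCors(m)[1] - bruteForceRho1(scale(X, scale = FALSE),
                                                       scale(Y, scale = FALSE))),
              1e-3)
  }
})

test_that("canonical correlations are invariant under affine recoding", {
  set.seed(3)
  X <- matrix(rnorm(1500), 300, 5)
  Y <- 0.5 * X %*% matrix(rnorm(25), 5, 5) + matrix(rnorm(1500), 300, 5)
  base <- canonicalCors(fitCCA(X, Y))
  for (i in 1:3) {
    A <- matrix(rnorm(25), 5, 5); B <- matrix(rnorm(25), 5, 5)
    rec <- canonicalCors(fitCCA(sweep(X %*% A, 2, rnorm(5), "+"),
                                sweep(Y %*% B, 2, rnorm(5), "+")))
    expect_lt(max(abs(rec - base)), 1e-8)
  }
  ## projections onto a CV are invariant to recoding the *other* region
  m1 <- fitCCA(X, Y)
  m2 <- fitCCA(X, Y %*% matrix(rnorm(25), 5, 5))
  p1 <- ccaProject(m1, X, "M2"); p2 <- ccaProject(m2, X, "M2")
  expect_lt(min(max(abs(p1 - p2)), max(abs(p1 + p2))), 1e-6)
})

test_that("cross-validated R2 is deterministic and separates signal from none", {
  set.seed(4)
  z <- rnorm(400)
  X <- 2 * outer(z, rnorm(5)) + 0.2 * matrix(rnorm(2000), 400, 5)
  Y <- 2 * outer(z, rnorm(5)) + 0.2 * matrix(rnorm(2000), 400, 5)
  r2 <- crossvalR2(X, Y, seed = 9)
  expect_gt(r2[1], 0.95)
  expect_identical(r2, crossvalR2(X, Y, seed = 9))
  ## independent regions: top-CV cv R2 near zero
  r0 <- crossvalR2(matrix(rnorm(2000), 400, 5), matrix(rnorm(2000), 400, 5),
                   seed = 9)
  expect_lt(r0[1], 0.05)
  expect_error(crossvalR2(X, Y, folds = 1), "folds")
})

test_that("trial-shuffle significance detects a planted shared latent", {
  sim <- quickSession(nUnits = c(15, 15), nTrials = 60, seed = 41)
  fit <- sessionCCA(sim$session)
  sig <- trialShuffleSignificance(fit$tensorsA, fit$tensorsB,
                                  nShuffles = 100, seed = 6)
  expect_gte(sig$nSignificant, 1)
  expect_false(sig$exclude)
  expect_true(sig$significant[1])
  expect_equal(length(sig$null), 100)
  expect_error(trialShuffleSignificance(fit$tensorsA[1], fit$tensorsB[1],
                                        nShuffles = 10),
               "2 trials")
  ## the exclusion flag mirrors the no-significant-CV rule
  sim0 <- quickSession(nUnits = c(8, 8), nTrials = 25, seed = 42,
                       aShared = c(early = 0, late = 0, baseline = 0,
                                   perturbed = 0), aLocal = 0)
  fit0 <- sessionCCA(sim0$session)
  sig0 <- trialShuffleSignificance(fit0$tensorsA, fit0$tensorsB,
                                   nShuffles = 100, seed = 7)
  expect_identical(sig0$exclude, sig0$nSignificant == 0L)
})

test_that("weight stability: small subset deltas, sign-flip invariant", {
  set.seed(5)
  z <- rnorm(600)
  X <- outer(z, rnorm(6)) + 0.5 * matrix(rnorm(3600), 600, 6)
  Y <- outer(z, rnorm(6)) + 0.5 * matrix(rnorm(3600), 600, 6)
  ws <- weightStability(X, Y, nSubsets = 8, seed = 2)
  ## sampling deltas are much smaller than the weight spread (top CV)
  expect_lt(sd(ws$deltaA[, 1, ]), 0.25 * sd(ws$fullA[, 1]))
  ## deltas are invariant to a global sign flip of a subset model because
  ## alignment maximizes the dot product: realign manually and compare
  flipped <- -ws$fullA[, 1]
  sgn <- sign(sum(flipped * ws$fullA[, 1]))
  expect_equal(sgn * flipped, ws$fullA[, 1])
})

test_that("subspaceAngle reduces to known closed forms", {
  expect_lt(subspaceAngle(c(1, 0, 0), c(2, 0, 0)), 1e-5)
  expect_equal(subspaceAngle(c(1, 0, 0), c(0, -3, 0)), 90, tolerance = 1e-6)
  ## angle folds into [0, 90]
  expect_lt(subspaceAngle(c(1, 1), c(-1, -1)), 1e-5)
  expect_equal(subspaceAngle(c(1, 1, 0), cbind(c(1, 0, 0), c(0, 0, 1))), 45,
               tolerance = 1e-6)
  expect_error(subspaceAngle(c(1, 0), c(1, 0, 0)), "mismatch")
})

test_that("lag sweep recovers a planted inter-region lag", {
  ## region B's shared latent trails region A by 200 ms
  sim <- quickSession(nUnits = c(12, 12), nTrials = 50, seed = 51,
                      sharedLagMs = 200, itiS = 6)
  sw <- lagBinwidthSweep(sim$session, binWidths = 100,
                         lagRangeMs = c(-400, 400), seed = 3)
  expect_lte(abs(sw$best$lag - 200), 100)
  ## consistency: the lag-0 cell equals plain crossvalR2 on aligned data
  fit <- sessionCCA(sim$session)
  cell <- sw$grid[sw$grid$lag == 0, ]
  expect_equal(cell$r2, crossvalR2(fit$XA, fit$XB, seed = 3)[1],
               tolerance = 1e-10)
})
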