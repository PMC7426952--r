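test_that("reach and baseline windows follow the stated rules", {
  w <- reachWindows(10.0, 10.2)
  expect_equal(w$reach, c(9.9, 10.3))
  expect_equal(w$baseline, c(8.5, 8.9))
  ## degenerate grasp-at-reach trial: 0.2 s windows
  w <- reachWindows(5, 5)
  expect_equal(w$reach, c(4.9, 5.1))
  expect_equal(w$baseline, c(3.7, 3.9))
  expect_equal(diff(w$reach), diff(w$baseline))
  expect_error(reachWindows(5, 4), "grasp before")
})

test_that("CA-modulation implements the printed d-prime form", {
  ## baseline (-2, 0, 2): median 0, sd 2; reach (0, 2, 4): mean 2, sd 2
  tms <- c(0.5, 1.5, 2.5, 10, 11, 12)
  sig <- c(-2, 0, 2, 0, 2, 4)
  m <- caModulation(sig, tms, c(9.5, 12.5), c(0, 3))
  expect_equal(m$dprime, 2)
  ## identical segments: zero modulation
  m0 <- caModulation(rep(c(1, 2, 3), 2), tms, c(9.5, 12.5), c(0, 3))
  expect_equal(m0$dprime, 0)
  ## negating the signal about the baseline median flips the sign
  mneg <- caModulation(-sig, tms, c(9.5, 12.5), c(0, 3))
  expect_equal(mneg$dprime, -m$dprime)
  ## under the printed denominator, scaling the signal by c scales d' by
  ## sqrt(c) (a non-standard property of the as-printed form)
  m4 <- caModulation(4 * sig, tms, c(9.5, 12.5), c(0, 3))
  expect_equal(m4$dprime, 2 * m$dprime, tolerance = 1e-12)
  ## constant offsets never matter
  moff <- caModulation(sig + 100, tms, c(9.5, 12.5), c(0, 3))
  expect_equal(moff$dprime, m$dprime, tolerance = 1e-12)
  ## the conventional pooled variant is scale-invariant instead
  mp1 <- caModulation(sig, tms, c(9.5, 12.5), c(0, 3), variant = "pooled")
  mp4 <- caModulation(4 * sig, tms, c(9.5, 12.5), c(0, 3), variant = "pooled")
  expect_equal(mp4$dprime, mp1$dprime, tolerance = 1e-12)
  ## flat signal: flagged, not an error
  mf <- caModulation(rep(1, 6), tms, c(9.5, 12.5), c(0, 3))
  expect_true(mf$flagged)
  expect_true(is.na(mf$dprime))
})

test_that("duration-modulation regression recovers a planted power law", {
  set.seed(1)
  dur <- rlnorm(400, log(0.25), 0.35)
  d <- exp(-0.25 * log(dur) + rnorm(400, 0, 0.2))
  fit <- durationModulationSlope(d, dur)
  expect_lt(abs(fit$slope + 0.25), 3 * fit$se)
  ## negative-modulation trials are excluded and counted
  d2 <- c(d, -1, -2); dur2 <- c(dur, 0.2, 0.3)
  fit2 <- durationModulationSlope(d2, dur2)
  expect_equal(fit2$nExcluded, 2L)
  expect_equal(fit2$nUsed, 400L)
  expect_error(durationModulationSlope(rep(-1, 20), rep(0.2, 20)), "positive")
  ## duration-independent modulation: CI covers zero most of the time
  covers <- replicate(40, {
    f <- durationModulationSlope(exp(rnorm(120, 0, 0.3)),
                                 rlnorm(120, log(0.25), 0.35))
    abs(f$slope) < 1.96 * f$se
  })
  expect_gte(mean(covers), 0.85)
})

test_that("detection samples are labeled with the stated windows", {
  tm <- seq(-1.95, 0.25, by = 0.1)
  tj <- replicate(10, data.frame(time = tm, cs = rnorm(length(tm))),
                  simplify = FALSE)
  lab <- labelDetectionSamples(tj)
  cc <- attr(lab, "classCounts")
  expect_equal(unname(cc["0"]), 190)      # 19 pre bins x 10 trials
  expect_equal(unname(cc["1"]), 40)       # 4 initiation bins x 10 trials
  ## short reaction time truncates the pre window at door open
  lab2 <- labelDetectionSamples(tj[1], reactionTime = 1.5)
  cc2 <- attr(lab2, "classCounts")
  expect_equal(unname(cc2["0"]), sum(tm >= -1.5 & tm < -0.1))
  expect_equal(attr(lab2, "nTruncated"), 1L)
  expect_error(labelDetectionSamples(list(data.frame(time = 1, cs = 0))),
               "no valid trials")
})

test_that("logistic detector and ROC/AUC behave at their fixed points", {
  ## perfectly separated 1-D input
  sep <- data.frame(time = 0, label = rep(0:1, each = 30),
                    cs = c(rnorm(30, -3), rnorm(30, 3)), trial = 1)
  det <- fitReachDetector(sep, channels = "cs")
  expect_equal(rocAuc(det$scores, det$labels)$auc, 1)
  ## shuffled labels: chance-level AUC
  set.seed(2)
  x <- rnorm(1000)
  lab <- data.frame(time = 0, label = sample(rep(0:1, 500)), cs = x, trial = 1)
  det0 <- fitReachDetector(lab, channels = "cs")
  expect_lt(abs(rocAuc(det0$scores, det0$labels)$auc - 0.5), 0.05)
  expect_error(fitReachDetector(data.frame(time = 0, label = 1, cs = 1)),
               "both classes")

  ## AUC fixed points and the concordant-pair oracle
  expect_equal(rocAuc(rep(1, 20), rep(0:1, 10))$auc, 0.5)
  expect_equal(rocAuc(rep(0:1, 10), rep(0:1, 10))$auc, 1)
  set.seed(3)
  sc <- rnorm(200); y <- rbinom(200, 1, plogis(sc))
  pairAUC <- function(s, l) {
    ps <- s[l == 1]; ns <- s[l == 0]
    (sum(outer(ps, ns, ">")) + 0.5 * sum(outer(ps, ns, "=="))) /
      (length(ps) * length(ns))
  }
  expect_equal(rocAuc(sc, y)$auc, pairAUC(sc, y), tolerance = 1e-12)
  ## ROC curve is monotone from (0,0) to (1,1)
  roc <- rocAuc(sc, y)$roc
  expect_true(all(diff(roc$fpr) >= 0) && all(diff(roc$tpr) >= 0))
  expect_equal(unlist(roc[nrow(roc), ]), c(fpr = 1, tpr = 1))
  ## independent implementation cross-check
  if (requireNamespace("pROC", quietly = TRUE)) {
    pr <- pROC::auc(pROC::roc(y, sc, quiet = TRUE, direction = "<"))
    expect_equal(rocAuc(sc, y)$auc, as.numeric(pr), tolerance = 1e-12)
  }
})

test_that("prediction time course summarizes initiation-vs-pre probability", {
  tm <- seq(-1.95, 0.25, by = 0.1)
  tj <- replicate(5, data.frame(time = tm, cs = rnorm(length(tm))),
                  simplify = FALSE)
  det <- list(coef = c("(Intercept)" = 0.4, cs = 0), channels = "cs")
  pt <- predictionTimecourse(det, tj)
  expect_true(all(abs(pt$trials[[1]]$prob - plogis(0.4)) < 1e-12))
  expect_equal(pt$sessionSummary, 0)
  ## probabilities bounded in (0, 1) for a real model
  det2 <- list(coef = c("(Intercept)" = 0, cs = 3), channels = "cs")
  pt2 <- predictionTimecourse(det2, tj)
  pr <- unlist(lapply(pt2$trials, `[[`, "prob"))
  expect_true(all(pr > 0 & pr < 1))
})

test_that("median separability has its trivial fixed points and ordering", {
  x <- rnorm(200)
  expect_equal(medianSeparability(x, x), 0)
  expect_equal(medianSeparability(x, x + 1), 1)
  expect_error(medianSeparability(numeric(0), x), "nonempty")
  ## separability grows with the planted shared amplitude
  seps <- vapply(c(0.5, 3.5), function(a) {
    sim <- quickSession(nUnits = c(12, 12), nTrials = 50, seed = 71,
                        aShared = c(early = a, late = a, baseline = a,
                                    perturbed = 0))
    fit <- sessionCCA(sim$session)
    dt <- detectorTrajectories(sim, fit)
    z <- unlist(lapply(dt$trajectories, `[[`, "m2"))
    zs <- (unlist(lapply(dt$trajectories, `[[`, "m2")) - mean(z)) / sd(z)
    tms <- unlist(lapply(dt$trajectories, `[[`, "time"))
    medianSeparability(zs[tms < -0.1], zs[tms >= -0.1 & tms < 0.3])
  }, 0.0)
  expect_gt(seps[2], seps[1])
})
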