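## Compact session configs for tests: short reaction times keep recordings
## small; all other parameters are the package defaults unless overridden.
quickRT <- c(early = 2, late = 0.9, baseline = 1.1, perturbed = 2.5)

quickConfig <- function(stage = "late", nUnits = c(12, 12), nTrials = 30,
                        seed = 1, ...) {
  syntheticConfig(stage = stage, nUnits = nUnits, nTrials = nTrials,
                  seed = seed, rtMean = quickRT, ...)
}

quickSession <- function(...) suppressWarnings(generateSession(quickConfig(...)))

## per-trial trajectories of both regions' top-CV projections, aligned to
## reach start, as detector input
detectorTrajectories <- function(sim, fit, window = c(-2.2, 0.5)) {
  al <- alignTrials(sim$session, "reach_start", window, 100)
  tjA <- projectTrials(fit$model, al[[regions(sim$session)[1]]],
                       regions(sim$session)[1])
  tjB <- projectTrials(fit$model, al[[regions(sim$session)[2]]],
                       regions(sim$session)[2])
  tj <- mapply(function(a, b) data.frame(time = a$time, m2 = a$value,
                                         m1 = b$value),
               tjA, tjB, SIMPLIFY = FALSE)
  tt <- trialTable(sim$session)
  list(trajectories = tj,
       reactionTime = tt$reaction_time[match(al$trials, tt$trial_id)])
}

sessionAUC <- function(stage, seed, nUnits = c(25, 25), nTrials = 100) {
  sim <- quickSession(stage = stage, seed = seed, nUnits = nUnits,
                      nTrials = nTrials)
  fit <- sessionCCA(sim$session)
  dt <- detectorTrajectories(sim, fit)
  lab <- labelDetectionSamples(dt$trajectories, dt$reactionTime)
  det <- fitReachDetector(lab)
  rocAuc(det$scores, det$labels)$auc
}
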