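## Two-region synthetic sessions: inhomogeneous Poisson spiking driven by one
## shared low-dimensional latent (common to M2 and M1, amplitude scaled per
## trial) plus one region-local latent per area, with a planted M2-over-M1
## lead in the local latents. Log-link rate model:
##   lambda_u(t) = baseline_u * exp(wS_u * a_trial * z(t) + wL_u * aL * l(t))
## z(t) is a Gaussian bump peaking at reach start whose width scales with
## reach duration; a_trial = a_stage * (duration / ref)^beta with beta < 0 so
## short (skilled) reaches carry larger shared amplitude.

#' Configuration for the synthetic two-region session generator
#'
#' Defaults encode the study conditions: per-stage mean reach durations
#' (0.30 s early, 0.20 s late, 0.18 s baseline, 0.29 s perturbed), reaction
#' times (32.23 / 0.89 / 1.26 / 3.23 s), and success rates; a duration-coupling
#' exponent beta = -0.25; and a 100 ms lead of the M2 local latent over M1.
#' Amplitude scales are free parameters chosen so that downstream statistics
#' (top-CV cross-validated R2, CA-modulation, detection AUC) land on the scale
#' reported for real recordings (see the methods vignette).
#'
#' @param stage stage label; selects stage-dependent behavioral parameters.
#' @param nUnits integer(2), units per region (M2, M1).
#' @param nTrials number of trials.
#' @param seed RNG seed (fixed seed gives byte-identical sessions).
#' @param baselineHz range of per-unit baseline rates (uniform draw).
#' @param aShared named per-stage shared-latent amplitude.
#' @param aLocal local-latent amplitude (same both regions).
#' @param lagLocalMs lead (ms) of the M2 local latent over the M1 local latent.
#' @param localJitterSdS per-stage, per-trial, per-region jitter sd (s) of
#'   the local latent's bump center; the planted lead holds on average while
#'   single trials vary. Early movements are behaviorally variable (large
#'   jitter), skilled ones stereotyped (small jitter).
#' @param localSeqSdS per-unit spread (s) of fixed local-transient offsets
#'   around the region's local latent time, emulating the sequential
#'   activation of movement-locked neurons; this makes the local signal
#'   high-rank so its timing survives removal of the cross-area subspace.
#' @param sharedLagMs lag (ms) of region B's shared latent behind region A's
#'   (0 by default; used to exercise the lag sweep).
#' @param durationMean,durationSdLog per-stage mean reach duration (s) and
#'   log-normal sd of log duration.
#' @param rtMean,rtShift per-stage mean reaction time (s) and the shift of the
#'   shifted-exponential reaction-time distribution.
#' @param successRate per-stage probability of pellet retrieval.
#' @param beta duration-coupling exponent (shared amplitude ~ duration^beta).
#' @param refDuration reference duration (s) at which a_trial = a_stage.
#' @param itiS inter-trial interval (s) from grasp to the next door-open cue.
#' @param kernelWidthS latent bump width (s) at the reference duration.
#' @param lambdaMax rate ceiling (Hz); rates above it are clipped with warning.
#' @param kShared shared-latent dimensionality (1 by default; >1 adds extra
#'   independent shared bumps at staggered offsets for multi-CV tests).
#' @param symmetricRegions if TRUE both regions reuse the same baseline-rate
#'   and loading draws (spiking stays independent), making the regions
#'   exchangeable -- the appropriate null construction for calibrating the
#'   timing permutation test at zero lag.
#' @return named list of class \code{SyntheticConfig}.
#' @export
syntheticConfig <- function(stage = "late", nUnits = c(30, 30), nTrials = 200,
                            seed = 1,
                            baselineHz = c(2, 15),
                            aShared = c(early = 1.0, late = 3.5,
                                        baseline = 3.5, perturbed = 0),
                            aLocal = 3.0,
                            lagLocalMs = 100,
                            localJitterSdS = c(early = 0.40, late = 0.20,
                                               baseline = 0.20, perturbed = 0.40),
                            localSeqSdS = 0.02,
                            sharedLagMs = 0,
                            durationMean = c(early = 0.30, late = 0.20,
                                             baseline = 0.18, perturbed = 0.29),
                            durationSdLog = 0.35,
                            rtMean = c(early = 32.23, late = 0.89,
                                       baseline = 1.26, perturbed = 3.23),
                            rtShift = 0.15,
                            successRate = c(early = 0.2728, late = 0.5764,
                                            baseline = 0.5675, perturbed = 0.3745),
                            beta = -0.25,
                            refDuration = 0.25,
                            itiS = 8,
                            kernelWidthS = 0.15,
                            lambdaMax = 200,
                            kShared = 1,
                            symmetricRegions = FALSE) {
  cfg <- as.list(environment())
  stopifnot(stage %in% names(aShared), all(aShared >= 0), aLocal >= 0,
            nTrials >= 1, all(durationMean > 0), durationSdLog > 0,
            all(nUnits >= 1), kShared >= 1,
            !symmetricRegions || nUnits[1] == nUnits[2])
  class(cfg) <- "SyntheticConfig"
  cfg
}

.bump <- function(t, center, sigma) exp(-((t - center)^2) / (2 * sigma^2))

#' Generate a synthetic two-region session with known ground truth
#'
#' Draws trial behavior (reaction times, reach durations, success) from the
#' stage's distributions, builds shared and local latent time courses, and
#' samples spikes from the log-link inhomogeneous Poisson model by thinning,
#' with a 1 ms dead time per unit.
#'
#' @param config a [syntheticConfig()] list.
#' @return list with \code{session} (a [SessionData-class]) and \code{truth}:
#'   planted unit-norm shared/local loading vectors per region, per-trial
#'   shared amplitudes, latent bump centers and widths, the local lag,
#'   duration-coupling exponent and the config.
#' @export
generateSession <- function(config = syntheticConfig()) {
  cfg <- config
  set.seed(cfg$seed)
  stg <- cfg$stage
  n <- cfg$nTrials

  ## --- behavior ---
  sdl <- cfg$durationSdLog
  dur <- stats::rlnorm(n, log(cfg$durationMean[[stg]]) - sdl^2 / 2, sdl)
  rt <- cfg$rtShift + stats::rexp(n, 1 / max(cfg$rtMean[[stg]] - cfg$rtShift, 0.05))
  success <- stats::runif(n) < cfg$successRate[[stg]]
  door <- numeric(n); reach <- numeric(n); grasp <- numeric(n)
  t0 <- 5
  for (i in seq_len(n)) {
    door[i] <- t0
    reach[i] <- door[i] + rt[i]
    grasp[i] <- reach[i] + dur[i]
    t0 <- grasp[i] + cfg$itiS
  }
  tEnd <- grasp[n] + 5
  trials <- data.frame(trial_id = seq_len(n), door_open = door,
                       reach_start = reach, grasp_onset = grasp,
                       reach_end = grasp + 0.08, success = success)

  ## --- planted axes and baseline rates ---
  ## shared loadings are mixed-sign and orthogonal to the baseline-rate
  ## vector (balanced shared dynamics: no net population-rate change);
  ## local loadings are all positive (reach-locked local transients are
  ## excitatory population-wide, so the local variance bump is coherent)
  regionNames <- c("M2", "M1")
  unitn <- function(v) v / sqrt(sum(v^2))
  wShared <- list(); wLocal <- list(); baseRate <- list()
  for (r in 1:2) {
    p <- cfg$nUnits[r]
    if (cfg$symmetricRegions && r == 2L) {
      wShared[["M1"]] <- wShared[["M2"]]
      wLocal[["M1"]] <- wLocal[["M2"]]
      baseRate[["M1"]] <- baseRate[["M2"]]
      next
    }
    b <- stats::runif(p, cfg$baselineHz[1], cfg$baselineHz[2])
    ws <- matrix(stats::rnorm(p * cfg$kShared), p, cfg$kShared)
    ws <- ws - outer(b, colSums(ws * b) / sum(b * b))   # b-orthogonal
    ws <- qr.Q(qr(ws))                                  # orthonormal columns
    ws <- qr.Q(qr(ws - outer(b, colSums(ws * b) / sum(b * b))))
    wl <- unitn(abs(stats::rnorm(p)))
    wShared[[regionNames[r]]] <- ws
    wLocal[[regionNames[r]]] <- wl
    baseRate[[regionNames[r]]] <- b
  }
  mkOffsets <- function(p) {
    o <- stats::rnorm(p, 0, cfg$localSeqSdS)
    o - mean(o)   # centered: the region's mean local time is the planted one
  }
  localOffset <- list(M2 = mkOffsets(cfg$nUnits[1]), M1 = mkOffsets(cfg$nUnits[2]))
  if (cfg$symmetricRegions) localOffset$M1 <- localOffset$M2

  aTrial <- cfg$aShared[[stg]] * (dur / cfg$refDuration)^cfg$beta
  sigmaZ <- cfg$kernelWidthS * dur / cfg$refDuration
  dl <- cfg$lagLocalMs / 1000
  zCenter <- list(M2 = reach, M1 = reach + cfg$sharedLagMs / 1000)
  jit <- if (length(cfg$localJitterSdS) > 1L) cfg$localJitterSdS[[stg]]
         else cfg$localJitterSdS
  lCenter <- list(M2 = reach - dl / 2 + stats::rnorm(n, 0, jit),
                  M1 = reach + dl / 2 + stats::rnorm(n, 0, jit))
  ## extra shared dimensions (if any) peak at staggered offsets after reach
  kOff <- if (cfg$kShared > 1) 0.3 * seq(0, cfg$kShared - 1) else 0

  ## --- spikes ---
  W <- 2.0      # latent support half-width (s); bumps treated as 0 outside
  clipped <- FALSE
  spikes <- list()
  for (r in regionNames) {
    p <- cfg$nUnits[[match(r, regionNames)]]
    base <- baseRate[[r]]
    ws <- wShared[[r]]; wl <- wLocal[[r]]
    units <- vector("list", p)
    for (u in seq_len(p)) {
      ePeak <- sum(abs(ws[u, ])) * max(aTrial) + abs(wl[u]) * cfg$aLocal
      lamMax <- min(base[u] * exp(ePeak), cfg$lambdaMax)
      ## baseline spiking outside modulation windows
      nb <- stats::rpois(1, base[u] * tEnd)
      tb <- sort(stats::runif(nb, 0, tEnd))
      inWin <- rep(FALSE, nb)
      for (i in seq_len(n))
        inWin <- inWin | (tb >= reach[i] - W & tb < reach[i] + W)
      tb <- tb[!inWin]
      ## thinned inhomogeneous spiking inside windows
      nc <- stats::rpois(n, lamMax * 2 * W)
      tr <- rep(seq_len(n), nc)
      tt <- reach[tr] - W + stats::runif(sum(nc)) * 2 * W
      ex <- rep(0, length(tt))
      for (j in seq_len(cfg$kShared))
        ex <- ex + ws[u, j] * aTrial[tr] *
          .bump(tt, zCenter[[r]][tr] + kOff[j], sigmaZ[tr])
      ex <- ex + wl[u] * cfg$aLocal *
        .bump(tt, lCenter[[r]][tr] + localOffset[[r]][u], cfg$kernelWidthS)
      lam <- base[u] * exp(ex)
      if (any(lam > cfg$lambdaMax)) { clipped <- TRUE; lam <- pmin(lam, cfg$lambdaMax) }
      tt <- tt[stats::runif(length(tt)) < lam / lamMax]
      st <- sort(c(tb, tt))
      if (length(st) > 1L) st <- st[c(TRUE, diff(st) >= 0.001)]  # 1 ms dead time
      units[[u]] <- st
    }
    spikes[[r]] <- units
  }
  if (clipped) warning("rates clipped at lambdaMax = ", cfg$lambdaMax, " Hz")

  session <- makeSessionData(spikes, trials, regions = regionNames,
                             animal = paste0("synthetic", cfg$seed), stage = stg)
  truth <- list(wShared = wShared, wLocal = wLocal,
                localOffset = localOffset, baseRate = baseRate, aTrial = aTrial,
                sigmaZ = sigmaZ, zCenter = zCenter, lCenter = lCenter,
                lagLocalMs = cfg$lagLocalMs, sharedLagMs = cfg$sharedLagMs,
                beta = cfg$beta, config = cfg)
  list(session = session, truth = truth)
}

#' Angle between a planted shared axis and a fitted CV axis
#'
#' Principal angle (degrees, in [0, 90]) between the generator's shared
#' loading vector for a region and the top-CV weight vector of a fitted
#' [CCAModel-class], a recovery metric for the synthetic pipeline.
#'
#' @param truth ground-truth list from [generateSession()].
#' @param model fitted [CCAModel-class].
#' @param region region label.
#' @param cv CV index (default 1).
#' @return angle in degrees.
#' @export
plantedAxisAngle <- function(truth, model, region, cv = 1) {
  w <- ccaWeights(model, region)[, cv]
  planted <- truth$wShared[[region]][, 1]
  if (length(w) != length(planted)) stop("dimension mismatch")
  subspaceAngle(cbind(w), cbind(planted))
}

#' Write a synthetic session to a directory of plain-text files
#'
#' Writes the spikes/trials TSVs plus a \code{ground_truth.yaml} with the
#' planted axes and parameters.
#'
#' @param sim result of [generateSession()].
#' @param dir output directory (created if missing).
#' @return invisibly, \code{dir}.
#' @export
writeSyntheticSession <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeSessionTSV(sim$session, file.path(dir, "spikes.tsv"),
                  file.path(dir, "trials.tsv"))
  gt <- sim$truth
  yaml::write_yaml(list(
    wShared = lapply(gt$wShared, function(m) unname(as.numeric(m[, 1]))),
    wLocal = lapply(gt$wLocal, as.numeric),
    aTrial = as.numeric(gt$aTrial),
    lagLocalMs = gt$lagLocalMs, sharedLagMs = gt$sharedLagMs, beta = gt$beta,
    stage = gt$config$stage, seed = gt$config$seed
  ), file.path(dir, "ground_truth.yaml"))
  invisible(dir)
}
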