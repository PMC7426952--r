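## Coupling of cross-area activity to reach behavior: reach/baseline windows,
## the d-prime CA-modulation statistic, its duration relationship, and
## logistic-regression detection of reach initiation with ROC/AUC.

#' Reach and baseline analysis windows for a trial
#'
#' The reach period runs from 0.1 s before reach onset to 0.1 s after grasp
#' onset; the baseline period has equal length and ends 1 s before the reach
#' period starts.
#'
#' @param reachStart,graspOnset event times (s).
#' @return list: \code{reach = c(start, end)}, \code{baseline = c(start, end)}.
#' @export
reachWindows <- function(reachStart, graspOnset) {
  if (graspOnset < reachStart) stop("grasp before reach start")
  reach <- c(reachStart - 0.1, graspOnset + 0.1)
  len <- diff(reach)
  bEnd <- reach[1] - 1.0
  list(reach = reach, baseline = c(bEnd - len, bEnd))
}

#' Single-trial CA-modulation (d-prime) of a cross-area signal
#'
#' Subtracts the baseline-period median from both segments, then computes
#' d' = (mu_reach - mu_baseline) / ((1/2) * sqrt(sigma_reach + sigma_baseline))
#' with sigma the sample standard deviation of each segment -- the published
#' form of the denominator (the sum of standard deviations under the square
#' root, halved). \code{variant = "pooled"} instead uses the conventional
#' sqrt((sigma_r^2 + sigma_b^2) / 2) for sensitivity analysis.
#'
#' @param signal cross-area activity trajectory (one value per bin).
#' @param times bin-center times (s), same length.
#' @param reachWindow,baselineWindow numeric(2) windows (s), half-open on the
#'   right; both must contain at least 2 bins.
#' @param variant "printed" (default) or "pooled".
#' @return list: \code{dprime} (NA with \code{flagged = TRUE} when both
#'   segment standard deviations are 0), \code{muReach}, \code{muBaseline},
#'   \code{sigmaReach}, \code{sigmaBaseline}, windows.
#' @export
caModulation <- function(signal, times, reachWindow, baselineWindow,
                         variant = c("printed", "pooled")) {
  variant <- match.arg(variant)
  inWin <- function(w) times >= w[1] & times < w[2]
  rSeg <- signal[inWin(reachWindow)]
  bSeg <- signal[inWin(baselineWindow)]
  if (length(rSeg) < 2L || length(bSeg) < 2L)
    stop("both windows must contain at least 2 bins")
  med <- stats::median(bSeg)
  rSeg <- rSeg - med; bSeg <- bSeg - med
  muR <- mean(rSeg); muB <- mean(bSeg)
  sR <- stats::sd(rSeg); sB <- stats::sd(bSeg)
  flagged <- (sR + sB) == 0
  denom <- if (variant == "printed") 0.5 * sqrt(sR + sB)
           else sqrt((sR^2 + sB^2) / 2)
  d <- if (flagged) NA_real_ else (muR - muB) / denom
  list(dprime = d, muReach = muR, muBaseline = muB,
       sigmaReach = sR, sigmaBaseline = sB,
       reachWindow = reachWindow, baselineWindow = baselineWindow,
       variant = variant, flagged = flagged)
}

#' Per-trial CA-modulation table for a session
#'
#' Projects the session's activity around each trial's reach onto a CV axis
#' and computes the d-prime modulation with [caModulation()]. Trials whose
#' baseline window precedes the recording start are dropped and counted.
#'
#' @param session a [SessionData-class]
#' @param model a [CCAModel-class]
#' @param region region whose CS signal is analyzed.
#' @param cv CV index (default 1, the top CV).
#' @param binWidthMs bin width (ms).
#' @param variant d-prime denominator variant (see [caModulation()]).
#' @return data.frame(trial, dprime, reach_duration, stage, animal, flagged);
#'   attribute \code{"nDropped"} counts dropped trials.
#' @export
modulationTable <- function(session, model, region, cv = 1, binWidthMs = 100,
                            variant = "printed") {
  tr <- trialTable(session)
  span <- range(unlist(session@spikes, use.names = FALSE))
  rows <- list(); nDropped <- 0L
  for (i in seq_len(nrow(tr))) {
    if (is.na(tr$grasp_onset[i])) { nDropped <- nDropped + 1L; next }
    w <- reachWindows(tr$reach_start[i], tr$grasp_onset[i])
    if (w$baseline[1] < span[1] || w$reach[2] > span[2]) {
      nDropped <- nDropped + 1L; next
    }
    bp <- binSpikes(session@spikes[[region]],
                    c(w$baseline[1], w$reach[2]), binWidthMs)
    sig <- ccaProject(model, counts(bp), region, cv)
    m <- caModulation(sig, binTimes(bp), w$reach, w$baseline, variant = variant)
    rows[[length(rows) + 1L]] <- data.frame(
      trial = tr$trial_id[i], dprime = m$dprime,
      reach_duration = tr$grasp_onset[i] - tr$reach_start[i],
      stage = session@stage, animal = session@animal, flagged = m$flagged)
  }
  out <- do.call(rbind, rows)
  attr(out, "nDropped") <- nDropped
  out
}

#' Log-log regression of CA-modulation on reach duration
#'
#' Regresses log(d') on log(reach duration) with learning stage as an
#' additive covariate (and animal, when more than one is present). Only
#' trials with positive modulation enter; excluded trials are counted.
#'
#' @param dprime,duration per-trial modulation and reach duration (s).
#' @param stage per-trial stage labels.
#' @param animal optional per-trial animal ids.
#' @return list: \code{slope}, \code{t}, \code{p} (two-sided), \code{se},
#'   \code{nUsed}, \code{nExcluded}, the fitted \code{lm} object.
#' @export
durationModulationSlope <- function(dprime, duration, stage = NULL,
                                    animal = NULL) {
  keep <- !is.na(dprime) & dprime > 0 & !is.na(duration)
  nExcl <- sum(!keep)
  if (sum(keep) < 10L) stop("need at least 10 trials with positive modulation")
  df <- data.frame(y = log(dprime[keep]), x = log(duration[keep]))
  form <- y ~ x
  if (!is.null(stage) && length(unique(stage[keep])) > 1L) {
    df$stage <- factor(stage[keep]); form <- y ~ x + stage
  }
  if (!is.null(animal) && length(unique(animal[keep])) > 1L) {
    df$animal <- factor(animal[keep])
    form <- stats::update(form, . ~ . + animal)
  }
  fit <- stats::lm(form, data = df)
  cf <- summary(fit)$coefficients
  list(slope = cf["x", "Estimate"], se = cf["x", "Std. Error"],
       t = cf["x", "t value"], p = cf["x", "Pr(>|t|)"],
       nUsed = sum(keep), nExcluded = nExcl, fit = fit)
}

#' Label CS activity bins as pre-reach or reach-initiation
#'
#' Bins in the pre-reach period (-2 to -0.1 s before reach start) are labeled
#' 0 and bins in the initiation period (-0.1 to +0.3 s) are labeled 1,
#' concatenated across trials. Pre-reach windows truncate at the door-open
#' cue when the reaction time is under 2 s (truncations counted).
#'
#' @param trajectories list of per-trial data.frames (\code{time} relative to
#'   reach start, one column per CS channel) as from [projectTrials()] on
#'   reach-start-aligned tensors.
#' @param reactionTime per-trial reaction times (s) for truncation (optional).
#' @return data.frame: \code{trial}, \code{time}, \code{label}, channel
#'   columns; attributes \code{"classCounts"}, \code{"nTruncated"},
#'   \code{"nDropped"}.
#' @export
labelDetectionSamples <- function(trajectories, reactionTime = NULL) {
  rows <- list(); nTrunc <- 0L; nDrop <- 0L
  for (i in seq_along(trajectories)) {
    tj <- trajectories[[i]]
    lo <- -2
    if (!is.null(reactionTime) && reactionTime[i] < 2) {
      lo <- -reactionTime[i]; nTrunc <- nTrunc + 1L
    }
    pre <- tj$time >= lo & tj$time < -0.1
    ini <- tj$time >= -0.1 & tj$time < 0.3
    if (!any(pre) || !any(ini)) { nDrop <- nDrop + 1L; next }
    sel <- pre | ini
    d <- tj[sel, , drop = FALSE]
    d$label <- as.integer(ini[sel])
    d$trial <- i
    rows[[length(rows) + 1L]] <- d
  }
  if (!length(rows)) stop("no valid trials")
  out <- do.call(rbind, rows)
  attr(out, "classCounts") <- table(out$label)
  attr(out, "nTruncated") <- nTrunc
  attr(out, "nDropped") <- nDrop
  out
}

#' Fit a logistic-regression reach-initiation detector
#'
#' Maximum-likelihood logistic regression of the bin labels on one or two CS
#' channels. Perfect separation triggers a small-ridge refit (flagged).
#'
#' @param samples data.frame from [labelDetectionSamples()].
#' @param channels names of the predictor columns (default: all columns that
#'   are not \code{time}, \code{label}, \code{trial}).
#' @return list: \code{coef} (intercept first), \code{channels},
#'   \code{scores} in-sample predicted probabilities, \code{labels},
#'   \code{ridged} flag.
#' @export
fitReachDetector <- function(samples, channels = NULL) {
  if (is.null(channels))
    channels <- setdiff(names(samples), c("time", "label", "trial"))
  if (!length(channels)) stop("need at least one input channel")
  y <- samples$label
  if (length(unique(y)) < 2L) stop("both classes must be present")
  X <- as.matrix(samples[, channels, drop = FALSE])
  ridged <- FALSE
  fit <- withCallingHandlers(
    stats::glm.fit(cbind(1, X), y, family = stats::binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        ridged <<- TRUE
      invokeRestart("muffleWarning")
    })
  cf <- fit$coefficients
  if (ridged || any(!is.finite(cf)) || max(abs(cf)) > 1e3) {
    ridged <- TRUE
    gfit <- glmnet::glmnet(cbind(X, 0), y, family = "binomial", alpha = 0,
                           lambda = 1e-3)
    cf <- c(gfit$a0, as.numeric(gfit$beta)[seq_len(ncol(X))])
  }
  eta <- drop(cbind(1, X) %*% cf)
  list(coef = stats::setNames(cf, c("(Intercept)", channels)),
       channels = channels, scores = stats::plogis(eta), labels = y,
       ridged = ridged)
}

#' ROC curve and AUC
#'
#' AUC via the rank (Mann-Whitney) statistic, equivalent to trapezoidal
#' integration of the ROC with ties averaged; ROC points are computed over
#' all score thresholds.
#'
#' @param scores numeric classifier scores.
#' @param labels 0/1 (or logical) class labels; both classes required.
#' @return list: \code{auc}, \code{roc} data.frame(fpr, tpr) monotone.
#' @export
rocAuc <- function(scores, labels) {
  labels <- as.integer(as.logical(labels))
  nP <- sum(labels == 1L); nN <- sum(labels == 0L)
  if (nP == 0L || nN == 0L) stop("both classes must be present")
  rk <- rank(scores)                      # ties averaged
  auc <- (sum(rk[labels == 1L]) - nP * (nP + 1) / 2) / (nP * nN)
  ord <- order(scores, decreasing = TRUE)
  tp <- cumsum(labels[ord] == 1L); fp <- cumsum(labels[ord] == 0L)
  last <- c(diff(scores[ord]) != 0, TRUE)   # keep last of each tie run
  roc <- data.frame(fpr = c(0, fp[last] / nN), tpr = c(0, tp[last] / nP))
  list(auc = auc, roc = roc)
}

#' Single-trial reach-initiation prediction time course
#'
#' Applies a fitted detector to each trial's CS trajectory; the per-trial
#' summary is the mean predicted probability over the initiation window
#' minus the mean over the pre-reach window, and the session summary is the
#' mean of those.
#'
#' @param detector a fit from [fitReachDetector()].
#' @param trajectories list of per-trial data.frames (time + channel columns,
#'   time relative to reach start).
#' @param reactionTime optional per-trial reaction times for pre-window
#'   truncation, as in [labelDetectionSamples()].
#' @return list: \code{trials} list of data.frame(time, prob),
#'   \code{trialSummary} per-trial probability differences,
#'   \code{sessionSummary}.
#' @export
predictionTimecourse <- function(detector, trajectories, reactionTime = NULL) {
  cf <- detector$coef
  out <- vector("list", length(trajectories))
  summ <- rep(NA_real_, length(trajectories))
  for (i in seq_along(trajectories)) {
    tj <- trajectories[[i]]
    X <- as.matrix(tj[, detector$channels, drop = FALSE])
    prob <- stats::plogis(drop(cbind(1, X) %*% cf))
    out[[i]] <- data.frame(time = tj$time, prob = prob)
    lo <- -2
    if (!is.null(reactionTime) && reactionTime[i] < 2) lo <- -reactionTime[i]
    pre <- tj$time >= lo & tj$time < -0.1
    ini <- tj$time >= -0.1 & tj$time < 0.3
    if (any(pre) && any(ini)) summ[i] <- mean(prob[ini]) - mean(prob[pre])
  }
  list(trials = out, trialSummary = summ,
       sessionSummary = mean(summ, na.rm = TRUE))
}

#' Median separability of pre-reach versus initiation CS activity
#'
#' Difference of medians, median(initiation) - median(pre-reach), of the
#' session-z-scored CS signal.
#'
#' @param pre,init CS values in the pre-reach and initiation windows.
#' @return numeric difference of medians.
#' @export
medianSeparability <- function(pre, init) {
  if (!length(pre) || !length(init)) stop("both sets must be nonempty")
  stats::median(init) - stats::median(pre)
}
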