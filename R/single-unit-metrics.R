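## Per-neuron metrics: trial-averaged PETHs, the circular-shuffle modulation
## test, and pairwise normalized cross-correlations between regions.

#' Trial-averaged peri-event time histogram
#'
#' Elementwise mean across trials of one unit's binned counts, in spikes per
#' bin (divide by the bin width for a rate).
#'
#' @param trialCounts trials x bins numeric matrix of one unit's counts.
#' @return numeric vector of length n_bins.
#' @export
computePeth <- function(trialCounts) {
  trialCounts <- as.matrix(trialCounts)
  if (nrow(trialCounts) < 1L) stop("need at least one trial")
  colMeans(trialCounts)
}

#' Circular-shuffle test for event-locked modulation
#'
#' Tests whether a unit's PETH modulation exceeds what circular rotations of
#' each trial's spike-count vector produce. The statistic is the peak absolute
#' deviation of the PETH from its mean; each shuffle rotates every trial by an
#' independent uniform offset and recomputes it. The p-value uses the +1
#' correction so it can never be 0 (floor 1/(nShuffles + 1)).
#'
#' @param trialCounts trials x bins matrix of one unit's counts (>= 2 bins).
#' @param nShuffles number of circular shuffles (default 10000).
#' @param alpha significance level (default 0.000125).
#' @param seed RNG seed.
#' @return list: \code{p}, \code{significant}, observed \code{statistic},
#'   \code{peth}, \code{peakBin}.
#' @export
circularShuffleTest <- function(trialCounts, nShuffles = 10000,
                                alpha = 0.000125, seed = 1) {
  X <- as.matrix(trialCounts)
  nb <- ncol(X); nt <- nrow(X)
  if (nb < 2L) stop("need at least 2 bins per trial")
  peth <- colMeans(X)
  sObs <- max(abs(peth - mean(peth)))
  if (all(X == 0))
    return(list(p = 1, significant = FALSE, statistic = 0, peth = peth,
                peakBin = NA_integer_))
  set.seed(seed)
  sNull <- numeric(nShuffles)
  rowIdx <- rep(seq_len(nt), nb)
  colBase <- rep(seq_len(nb) - 1L, each = nt)
  for (s in seq_len(nShuffles)) {
    off <- sample.int(nb, nt, replace = TRUE) - 1L
    rot <- matrix(X[cbind(rowIdx, ((colBase + off[rowIdx]) %% nb) + 1L)], nt, nb)
    m <- colMeans(rot)
    sNull[s] <- max(abs(m - mean(m)))
  }
  p <- (1 + sum(sNull >= sObs)) / (1 + nShuffles)
  list(p = p, significant = p < alpha, statistic = sObs, peth = peth,
       peakBin = which.max(abs(peth - mean(peth))))
}

#' Normalized cross-correlation of a unit pair
#'
#' Peak Pearson correlation of the two series over timelags in
#' \code{[-maxLagMs, +maxLagMs]} (stepped by one bin, overlapping segments)
#' minus the mean correlation over all those lags. Positive peak lag means
#' series B trails series A. Zero-variance input gives value 0.
#'
#' @param a,b equal-length numeric series (binned counts of the two units).
#' @param binWidthMs bin width (ms); must divide \code{maxLagMs}.
#' @param maxLagMs maximum lag magnitude (ms), default 200.
#' @return list: \code{value} (peak minus mean correlation), \code{peakLagMs},
#'   \code{lagsMs}, \code{r} per lag.
#' @export
normalizedXcorr <- function(a, b, binWidthMs = 100, maxLagMs = 200) {
  if (length(a) != length(b)) stop("series must have equal length")
  L <- round(maxLagMs / binWidthMs)
  if (abs(L * binWidthMs - maxLagMs) > 1e-9)
    stop("binWidthMs must divide maxLagMs")
  n <- length(a)
  lags <- -L:L
  r <- vapply(lags, function(l) {
    if (l >= 0) { x <- a[seq_len(n - l)]; y <- b[seq_len(n - l) + l] }
    else { x <- a[seq_len(n + l) - l]; y <- b[seq_len(n + l)] }
    if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
    stats::cor(x, y)
  }, 0.0)
  if (all(is.na(r)))
    return(list(value = 0, peakLagMs = 0, lagsMs = lags * binWidthMs, r = r))
  value <- max(r, na.rm = TRUE) - mean(r, na.rm = TRUE)
  list(value = value,
       peakLagMs = lags[which.max(r)] * binWidthMs,
       lagsMs = lags * binWidthMs, r = r)
}

#' Regression of pairwise cross-correlation on mean CCA weight magnitude
#'
#' Ordinary least-squares simple regression of a pair's normalized
#' cross-correlation value on the mean absolute CCA weight of the two units,
#' with a two-sided t-test on the slope.
#'
#' @param xcorrValue numeric vector of pairwise normalized cross-correlations.
#' @param meanWeight numeric vector of mean absolute CCA weights per pair.
#' @return list: \code{slope}, \code{intercept}, \code{r.squared}, \code{t},
#'   \code{p}, \code{n}.
#' @export
xcorrWeightRegression <- function(xcorrValue, meanWeight) {
  if (length(xcorrValue) != length(meanWeight)) stop("length mismatch")
  if (length(xcorrValue) < 3L) stop("need at least 3 pairs")
  fit <- stats::lm(xcorrValue ~ meanWeight)
  sm <- summary(fit)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r.squared = sm$r.squared,
       t = sm$coefficients[2, "t value"],
       p = sm$coefficients[2, "Pr(>|t|)"],
       n = length(xcorrValue))
}
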