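## Local (non-shared) dynamics: projection onto the orthogonal complement of
## the cross-area subspace, per-trial median timing, and the timing/coupling
## permutation tests.

#' Decompose population activity into shared and local components
#'
#' Orthonormalizes the significant-CV weight columns to define the cross-area
#' subspace (CS); the shared component of each centered population vector is
#' its projection onto that span and the local component is the residual
#' (projection onto the orthogonal complement). Magnitudes satisfy the
#' Pythagorean identity shared^2 + local^2 = total^2.
#'
#' @param X bins x units centered matrix (rows are population vectors).
#' @param W n_units x k matrix of significant-CV weights (k < n_units).
#' @return data.frame with per-bin \code{sharedMag}, \code{localMag},
#'   \code{totalMag}; attribute \code{"k"} gives the CS dimension.
#' @export
localProjection <- function(X, W) {
  X <- as.matrix(X); W <- as.matrix(W)
  if (ncol(X) != nrow(W)) stop("unit counts of X and W disagree")
  if (ncol(W) < 1L) stop("need at least one significant CV")
  qw <- qr(W)
  if (qw$rank >= ncol(X))
    stop("weights span the full unit space; no orthogonal complement")
  Q <- qr.Q(qw)[, seq_len(qw$rank), drop = FALSE]
  P <- X %*% Q
  resid <- X - P %*% t(Q)
  out <- data.frame(sharedMag = sqrt(rowSums(P^2)),
                    localMag = sqrt(rowSums(resid^2)),
                    totalMag = sqrt(rowSums(X^2)))
  attr(out, "k") <- ncol(Q)
  out
}

#' Magnitude-weighted median timing of a trajectory
#'
#' The smallest bin-center time at which the cumulative magnitude reaches half
#' the total: a robust, parameter-free single-trial timing summary for
#' nonnegative activity trajectories.
#'
#' @param mag nonnegative magnitude per bin.
#' @param times bin-center times (s).
#' @return time (s); \code{NA} for an all-zero trajectory (caller should
#'   exclude and count such trials).
#' @export
trialMedianTiming <- function(mag, times) {
  if (length(mag) != length(times)) stop("length mismatch")
  if (any(mag < 0)) stop("magnitudes must be nonnegative")
  tot <- sum(mag)
  if (tot == 0) return(NA_real_)
  times[which(cumsum(mag) >= tot / 2)[1]]
}

#' Per-trial local timing of both regions
#'
#' Projects each trial's aligned, centered population activity of both
#' regions onto the orthogonal complement of the cross-area subspace, z-scores
#' the local-magnitude trajectories across the session (negative values
#' clipped at 0 for weighting), and returns the per-trial magnitude-weighted
#' median timing and the M2 - M1 timing difference.
#'
#' @param fit result of [sessionCCA()].
#' @param nCV number of CVs defining the CS (use the significant count).
#' @param zscore z-score local magnitudes across the session before timing
#'   (default TRUE).
#' @return data.frame(trial, tA, tB, diff) with NA-timing trials dropped and
#'   counted in attribute \code{"nExcluded"}.
#' @export
localTimingTable <- function(fit, nCV = 1, zscore = TRUE) {
  rg <- regions(fit$model)
  nb <- nrow(counts(fit$tensorsA[[1]]))
  tm <- binTimes(fit$tensorsA[[1]])
  mags <- list()
  for (side in c("A", "B")) {
    X <- fit[[paste0("X", side)]]
    W <- fit$model@weights[[rg[match(side, c("A", "B"))]]][, seq_len(nCV), drop = FALSE]
    lm_ <- localProjection(X, W)$localMag
    if (zscore) {
      lm_ <- drop(zscorePerUnit(matrix(lm_, ncol = 1)))
      lm_ <- pmax(lm_, 0)
    }
    mags[[side]] <- matrix(lm_, nrow = nb)   # bins x trials
  }
  nT <- ncol(mags$A)
  tA <- vapply(seq_len(nT), function(i) trialMedianTiming(mags$A[, i], tm), 0.0)
  tB <- vapply(seq_len(nT), function(i) trialMedianTiming(mags$B[, i], tm), 0.0)
  ok <- !is.na(tA) & !is.na(tB)
  out <- data.frame(trial = fit$map$trial[seq(1, by = nb, length.out = nT)][ok],
                    tA = tA[ok], tB = tB[ok], diff = tA[ok] - tB[ok])
  attr(out, "nExcluded") <- sum(!ok)
  out
}

#' Permutation test for inter-area timing differences
#'
#' Statistic: mean per-trial timing difference (region A minus region B). The
#' null randomly swaps the two regions' labels independently within each
#' trial (sign-flipping each difference). One-sided p with the +1 correction;
#' \code{alternative = "less"} tests an A-leads (negative-difference)
#' hypothesis.
#'
#' @param diffs per-trial paired timing differences (s), NA pairs excluded
#'   and counted.
#' @param nPerm number of permutations (default 1e5).
#' @param seed RNG seed.
#' @param alternative "less" (default), "greater", or "two.sided".
#' @return list: \code{p}, observed \code{statistic} (s), \code{nPerm},
#'   \code{nExcluded}, \code{null} summary quantiles.
#' @export
timingPermutationTest <- function(diffs, nPerm = 1e5, seed = 1,
                                  alternative = c("less", "greater", "two.sided")) {
  alternative <- match.arg(alternative)
  nExcl <- sum(is.na(diffs))
  d <- diffs[!is.na(diffs)]
  if (length(d) < 2) stop("need at least 2 complete pairs")
  obs <- mean(d)
  set.seed(seed)
  null <- numeric(nPerm)
  chunk <- max(1L, floor(2e6 / length(d)))
  s <- 1L
  while (s <= nPerm) {
    e <- min(s + chunk - 1L, nPerm)
    signs <- matrix(sample(c(-1, 1), (e - s + 1L) * length(d), replace = TRUE),
                    ncol = length(d))
    null[s:e] <- as.numeric(signs %*% d) / length(d)
    s <- e + 1L
  }
  p <- switch(alternative,
    less = (1 + sum(null <= obs)) / (1 + nPerm),
    greater = (1 + sum(null >= obs)) / (1 + nPerm),
    two.sided = (1 + sum(abs(null) >= abs(obs))) / (1 + nPerm))
  list(p = p, statistic = obs, nPerm = nPerm, nExcluded = nExcl,
       null = stats::quantile(null, c(0.025, 0.5, 0.975)))
}

#' Permutation test for a learning change in inter-area temporal coupling
#'
#' Statistic: mean(late diffs) - mean(early diffs). The null randomly
#' reassigns the pooled timing differences to the two stages (group sizes
#' preserved). With an A-before-B lead (negative differences), coupling
#' tightening makes the statistic positive, so the default alternative is
#' \code{"greater"}.
#'
#' @param early,late per-trial M2 - M1 timing differences (s) per stage.
#' @param nPerm number of permutations (default 1e5).
#' @param seed RNG seed.
#' @param alternative "greater" (default), "less", or "two.sided".
#' @return list: \code{p}, \code{statistic}, \code{nPerm}.
#' @export
couplingChangeTest <- function(early, late, nPerm = 1e5, seed = 1,
                               alternative = c("greater", "less", "two.sided")) {
  alternative <- match.arg(alternative)
  early <- early[!is.na(early)]; late <- late[!is.na(late)]
  if (!length(early) || !length(late)) stop("both stages must be nonempty")
  obs <- mean(late) - mean(early)
  pool <- c(early, late)
  nE <- length(early); nL <- length(late)
  set.seed(seed)
  null <- vapply(seq_len(nPerm), function(i) {
    idx <- sample.int(nE + nL, nL)
    mean(pool[idx]) - mean(pool[-idx])
  }, 0.0)
  p <- switch(alternative,
    greater = (1 + sum(null >= obs)) / (1 + nPerm),
    less = (1 + sum(null <= obs)) / (1 + nPerm),
    two.sided = (1 + sum(abs(null) >= abs(obs))) / (1 + nPerm))
  list(p = p, statistic = obs, nPerm = nPerm)
}
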