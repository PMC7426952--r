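## Cross-area subspace identification: CCA between the two populations,
## cross-validated R2, trial-shuffle significance, weight stability,
## subspace angles, and the bin-width x lag sweep.

## Internal CCA core on centered matrices. Projections have unit sample
## variance; correlations are clamped to [0, 1] and nonincreasing.
.ccaCore <- function(X, Y) {
  n <- nrow(X)
  p <- ncol(X); q <- ncol(Y)
  Sxx <- crossprod(X) / (n - 1)
  Syy <- crossprod(Y) / (n - 1)
  Sxy <- crossprod(X, Y) / (n - 1)
  diag(Sxx) <- diag(Sxx) + 1e-12 * sum(diag(Sxx)) / p
  diag(Syy) <- diag(Syy) + 1e-12 * sum(diag(Syy)) / q
  Rx <- chol(Sxx); Ry <- chol(Syy)
  Z <- backsolve(Rx, Sxy, transpose = TRUE)        # Rx^{-T} Sxy
  Z2 <- t(backsolve(Ry, t(Z), transpose = TRUE))   # ... Ry^{-1}
  sv <- svd(Z2)
  k <- min(p, q)
  list(cor = pmin(pmax(sv$d[seq_len(k)], 0), 1),
       A = backsolve(Rx, sv$u[, seq_len(k), drop = FALSE]),
       B = backsolve(Ry, sv$v[, seq_len(k), drop = FALSE]))
}

#' Fit CCA between two simultaneously recorded populations
#'
#' Finds paired linear combinations (canonical variables, CVs) of the two
#' regions' unit activity that are maximally correlated, subject to each
#' region's projections being mutually uncorrelated with unit variance.
#' Zero-variance units are dropped (weights reported as 0) and further rank
#' deficiency is removed by pivoted QR, both with a warning. CV signs are not
#' identified by CCA; when \code{orientRows} is given, each CV pair is jointly
#' flipped so the region-A projection averaged over those rows is >= 0.
#'
#' @param XA,XB numeric matrices (rows = time bins, columns = units), equal
#'   row counts; centering is performed internally and the removed column
#'   means are stored in the model.
#' @param binWidthMs,lagMs metadata recorded in the model.
#' @param orientRows optional integer vector of rows (e.g. reach-initiation
#'   bins) used to orient CV signs.
#' @param regionNames character(2) labels for (A, B).
#' @return a [CCAModel-class]
#' @export
fitCCA <- function(XA, XB, binWidthMs = 100, lagMs = 0, orientRows = NULL,
                   regionNames = c("M2", "M1")) {
  XA <- as.matrix(XA); XB <- as.matrix(XB)
  if (nrow(XA) != nrow(XB)) stop("XA and XB must have the same number of rows")
  if (nrow(XA) <= max(ncol(XA), ncol(XB)))
    stop("need more time bins than units in either region")
  prep <- function(X) {
    mu <- colMeans(X)
    Xc <- sweep(X, 2, mu)
    keep <- apply(Xc, 2, stats::sd) > 1e-12
    if (!all(keep)) warning(sum(!keep), " zero-variance unit(s) dropped")
    Xk <- Xc[, keep, drop = FALSE]
    qrx <- qr(Xk)
    if (qrx$rank < ncol(Xk)) {
      warning("rank-deficient input: ", ncol(Xk) - qrx$rank, " dimension(s) dropped")
      sub <- qrx$pivot[seq_len(qrx$rank)]
      keep[which(keep)[-sub]] <- FALSE
      Xk <- Xc[, keep, drop = FALSE]
    }
    list(X = Xk, mu = mu, keep = keep)
  }
  a <- prep(XA); b <- prep(XB)
  if (nrow(a$X) <= max(ncol(a$X), ncol(b$X)))
    stop("need more time bins than units in either region")
  fit <- .ccaCore(a$X, b$X)
  if (!is.null(orientRows)) {
    pa <- a$X[orientRows, , drop = FALSE] %*% fit$A
    s <- sign(colMeans(pa))
    s[s == 0] <- 1
    fit$A <- sweep(fit$A, 2, s, "*")
    fit$B <- sweep(fit$B, 2, s, "*")
  }
  expand <- function(keep, W) {
    out <- matrix(0, length(keep), ncol(W))
    out[keep, ] <- W
    out
  }
  wts <- list(expand(a$keep, fit$A), expand(b$keep, fit$B))
  names(wts) <- regionNames
  mns <- list(a$mu, b$mu); names(mns) <- regionNames
  kpt <- list(a$keep, b$keep); names(kpt) <- regionNames
  new("CCAModel", regions = regionNames, weights = wts, cors = fit$cor,
      means = mns, kept = kpt, binWidth = binWidthMs, lag = lagMs)
}

#' Project population activity onto a fitted CV axis
#'
#' Centers the data with the model's stored column means and applies the
#' (sign-oriented) CV weight vector(s) of the requested region.
#'
#' @param model a [CCAModel-class]
#' @param X bins x units matrix (uncentered) for that region.
#' @param region region label.
#' @param cv CV index or indices (default 1).
#' @return numeric matrix, bins x length(cv) (drops to a vector for one CV).
#' @export
ccaProject <- function(model, X, region, cv = 1) {
  if (!region %in% model@regions) stop("unknown region: ", region)
  X <- as.matrix(X)
  if (ncol(X) != length(model@means[[region]]))
    stop("unit count does not match model")
  P <- sweep(X, 2, model@means[[region]]) %*%
    model@weights[[region]][, cv, drop = FALSE]
  if (length(cv) == 1L) drop(P) else P
}

## per-trial CV projections; returns list of data.frame(time, value)
#' Project aligned per-trial tensors onto a CV axis
#'
#' @param model a [CCAModel-class]
#' @param tensors list of per-trial [BinnedPopulation-class] for one region.
#' @param region region label.
#' @param cv CV index.
#' @return list of per-trial data.frames with \code{time} (s, relative to the
#'   alignment event) and \code{value}.
#' @export
projectTrials <- function(model, tensors, region, cv = 1) {
  lapply(tensors, function(bp)
    data.frame(time = binTimes(bp),
               value = ccaProject(model, counts(bp), region, cv)))
}

#' Cross-validated per-CV R2 of paired population data
#'
#' Rows are randomly partitioned into folds ignoring trial structure; for each
#' fold a CCA model is fit to the remaining folds and the held-out rows of
#' both regions are projected; R2 is the squared Pearson correlation of the
#' paired held-out projections, matched across folds by CV index, averaged
#' over folds.
#'
#' @param XA,XB bins x units matrices (uncentered OK; folds self-center).
#' @param folds number of folds (default 10).
#' @param seed RNG seed for the fold partition.
#' @return numeric vector of per-CV mean R2.
#' @export
crossvalR2 <- function(XA, XB, folds = 10, seed = 1) {
  XA <- as.matrix(XA); XB <- as.matrix(XB)
  if (folds < 2) stop("folds must be >= 2")
  n <- nrow(XA)
  if (n < folds) stop("fewer rows than folds")
  set.seed(seed)
  foldId <- sample(rep(seq_len(folds), length.out = n))
  r2 <- cpp_cv_r2(XA, XB, as.integer(foldId), as.integer(folds))
  colMeans(r2, na.rm = TRUE)
}

#' CV significance against trial-shuffled CCA nulls
#'
#' The null distribution is the top-CV R2 of CCA fit to data in which region
#' B's trials are randomly permuted before concatenation (region A kept in
#' order), preserving within-trial structure and trial-averaged modulation
#' while destroying moment-to-moment inter-area correspondence. Each true
#' CV's cross-validated R2 is compared with the null's 95th percentile.
#' By default the null statistic is cross-validated and taken as the best
#' cross-validated R2 over the shuffled fit's CVs, so that "at least one
#' significant CV" is exchangeable with the null under no shared signal
#' (exact ~5 percent family positive rate -- cross-validated R2 values are
#' not ordered across CVs, so a top-training-CV null would be anticonservative
#' for the family test); \code{nullType = "training"} uses the faster
#' training-fit top canonical correlation squared instead.
#'
#' @param tensorsA,tensorsB equal-length lists of per-trial
#'   [BinnedPopulation-class] (or matrices) with a common bin count per trial.
#' @param nShuffles number of trial permutations (identity re-drawn).
#' @param percentile null percentile defining significance (default 95).
#' @param folds cross-validation folds.
#' @param seed RNG seed.
#' @param nullType \code{"crossval"} (default) or \code{"training"}.
#' @return list: \code{r2} per-CV cross-validated R2, \code{null} vector,
#'   \code{threshold}, \code{significant} logical per CV, \code{nSignificant},
#'   \code{exclude} (TRUE when no CV is significant, the dataset-exclusion
#'   rule), plus settings.
#' @export
trialShuffleSignificance <- function(tensorsA, tensorsB, nShuffles = 10000,
                                     percentile = 95, folds = 10, seed = 1,
                                     nullType = c("crossval", "training")) {
  nullType <- match.arg(nullType)
  nT <- length(tensorsA)
  if (nT != length(tensorsB)) stop("regions disagree on trial count")
  if (nT < 2) stop("trial shuffle needs at least 2 trials")
  ccA <- concatAndCenter(tensorsA)
  ccB <- concatAndCenter(tensorsB)
  nb <- nrow(ccA$X) / nT
  if (nb != round(nb) || nrow(ccB$X) != nrow(ccA$X))
    stop("trials must share a common bin count across regions")
  set.seed(seed)
  n <- nrow(ccA$X)
  foldId <- sample(rep(seq_len(folds), length.out = n))
  obs <- colMeans(cpp_cv_r2(ccA$X, ccB$X, as.integer(foldId),
                            as.integer(folds)), na.rm = TRUE)
  perms <- matrix(0L, nShuffles, nT)
  for (s in seq_len(nShuffles)) {
    repeat {
      p <- sample.int(nT)
      if (!all(p == seq_len(nT))) break
    }
    perms[s, ] <- p
  }
  null <- cpp_shuffle_null(ccA$X, ccB$X, perms, as.integer(nb),
                           as.integer(foldId), as.integer(folds),
                           nullType == "crossval")
  null <- null[is.finite(null)]
  thr <- stats::quantile(null, percentile / 100, names = FALSE)
  sig <- obs > thr
  list(r2 = obs, null = null, threshold = thr, significant = sig,
       nSignificant = sum(sig), exclude = !any(sig),
       nShuffles = nShuffles, percentile = percentile, folds = folds,
       nullType = nullType)
}

#' CCA weight stability over random timebin subsets
#'
#' Refits the model on random subsets of a fraction of timebins and reports
#' per-unit weight differences from the full-data model, after aligning each
#' subset CV's sign to the full model (maximizing the weight-vector dot
#' product over both regions).
#'
#' @param XA,XB bins x units matrices.
#' @param nSubsets number of random subsets (default 10).
#' @param frac fraction of timebins per subset (default 0.9).
#' @param seed RNG seed.
#' @return list with arrays \code{deltaA}, \code{deltaB} (units x CVs x
#'   subsets) of subset-minus-full weight differences, and the full-data
#'   weight matrices \code{fullA}, \code{fullB}.
#' @export
weightStability <- function(XA, XB, nSubsets = 10, frac = 0.9, seed = 1) {
  XA <- as.matrix(XA); XB <- as.matrix(XB)
  full <- fitCCA(XA, XB)
  fa <- full@weights[[1]]; fb <- full@weights[[2]]
  k <- length(full@cors)
  set.seed(seed)
  dA <- array(NA_real_, c(nrow(fa), k, nSubsets))
  dB <- array(NA_real_, c(nrow(fb), k, nSubsets))
  n <- nrow(XA)
  for (s in seq_len(nSubsets)) {
    idx <- sort(sample.int(n, floor(frac * n)))
    m <- fitCCA(XA[idx, , drop = FALSE], XB[idx, , drop = FALSE])
    wa <- m@weights[[1]]; wb <- m@weights[[2]]
    kk <- min(k, length(m@cors))
    for (j in seq_len(kk)) {
      sgn <- sign(sum(wa[, j] * fa[, j]) + sum(wb[, j] * fb[, j]))
      if (sgn == 0) sgn <- 1
      dA[, j, s] <- sgn * wa[, j] - fa[, j]
      dB[, j, s] <- sgn * wb[, j] - fb[, j]
    }
  }
  list(deltaA = dA, deltaB = dB, fullA = fa, fullB = fb)
}

#' Principal angle between subspaces
#'
#' Largest principal angle (degrees) between the column spans of two bases.
#' For two vectors this is the vector angle folded into [0, 90]; for a vector
#' versus a subspace, the angle between the vector and its projection onto
#' the subspace.
#'
#' @param U,V numeric matrices whose columns span the subspaces (same row
#'   count; columns linearly independent within each basis).
#' @return angle in degrees, in [0, 90].
#' @export
subspaceAngle <- function(U, V) {
  U <- as.matrix(U); V <- as.matrix(V)
  if (nrow(U) != nrow(V)) stop("dimension mismatch")
  qu <- qr(U); qv <- qr(V)
  if (qu$rank < ncol(U) || qv$rank < ncol(V))
    stop("basis columns must be linearly independent")
  Qu <- qr.Q(qu)[, seq_len(qu$rank), drop = FALSE]
  Qv <- qr.Q(qv)[, seq_len(qv$rank), drop = FALSE]
  s <- svd(crossprod(Qu, Qv))$d
  smin <- min(s[seq_len(min(ncol(Qu), ncol(Qv)))])
  acos(pmin(pmax(smin, 0), 1)) * 180 / pi
}

#' Sweep CCA generalization over bin widths and inter-region lags
#'
#' For every (bin width, lag) cell, region B's peri-event window is shifted
#' by the lag before binning (positive lag = region B's window later, i.e. it
#' compensates a region-B delay), both regions are concatenated, and the
#' cross-validated top-CV R2 is recorded. Lags step by one bin.
#'
#' @param session a [SessionData-class]
#' @param binWidths bin widths (ms), default c(100, 75, 50).
#' @param lagRangeMs lag range (ms), default c(-500, 500).
#' @param event,window alignment event and window (s).
#' @param folds,seed cross-validation settings.
#' @return list: \code{grid} data.frame(binwidth, lag, r2, nTrials) and
#'   \code{best} (the argmax row).
#' @export
lagBinwidthSweep <- function(session, binWidths = c(100, 75, 50),
                             lagRangeMs = c(-500, 500),
                             event = "grasp_onset", window = c(-1, 1),
                             folds = 10, seed = 1) {
  regB <- regions(session)[2]
  rows <- list()
  for (bw in binWidths) {
    lags <- seq(-floor(abs(lagRangeMs[1]) / bw), floor(lagRangeMs[2] / bw)) * bw
    for (lag in lags) {
      al <- tryCatch(
        alignTrials(session, event, window, bw,
                    lagMs = stats::setNames(lag, regB)),
        error = function(e) NULL)
      if (is.null(al)) {
        rows[[length(rows) + 1L]] <-
          data.frame(binwidth = bw, lag = lag, r2 = NA_real_, nTrials = 0L)
        next
      }
      XA <- concatAndCenter(al[[regions(session)[1]]])$X
      XB <- concatAndCenter(al[[regB]])$X
      r2 <- tryCatch(crossvalR2(XA, XB, folds = folds, seed = seed)[1],
                     error = function(e) NA_real_)
      rows[[length(rows) + 1L]] <-
        data.frame(binwidth = bw, lag = lag, r2 = r2,
                   nTrials = length(al$trials))
    }
  }
  grid <- do.call(rbind, rows)
  best <- grid[which.max(grid$r2), ]
  list(grid = grid, best = best)
}

#' Fit the session-level cross-area model
#'
#' Convenience wrapper: aligns both regions to the event, concatenates and
#' centers, fits CCA with signs oriented so the mean region-A projection in
#' the reach-initiation portion of the window is nonnegative, and returns the
#' model together with the matrices and tensors for downstream analyses.
#'
#' @param session a [SessionData-class]
#' @param event,window,binWidthMs alignment settings (defaults: grasp onset,
#'   -1..+1 s, 100 ms).
#' @param lagMs inter-region lag (ms) applied to region B.
#' @param orientWindow time window (s, relative to the event) whose bins
#'   orient CV signs.
#' @return list: \code{model}, centered matrices \code{XA}, \code{XB},
#'   per-trial tensors \code{tensorsA}, \code{tensorsB}, row map \code{map},
#'   and the alignment drop report.
#' @export
sessionCCA <- function(session, event = "grasp_onset", window = c(-1, 1),
                       binWidthMs = 100, lagMs = 0,
                       orientWindow = c(-0.6, 0.2)) {
  rg <- regions(session)
  al <- alignTrials(session, event, window, binWidthMs,
                    lagMs = stats::setNames(lagMs, rg[2]))
  ccA <- concatAndCenter(al[[rg[1]]])
  ccB <- concatAndCenter(al[[rg[2]]])
  orientRows <- which(ccA$map$time >= orientWindow[1] &
                      ccA$map$time <= orientWindow[2])
  model <- fitCCA(ccA$X, ccB$X, binWidthMs = binWidthMs, lagMs = lagMs,
                  orientRows = orientRows, regionNames = rg)
  ## store the uncentered means so ccaProject works on raw counts
  model@means[[rg[1]]] <- ccA$means
  model@means[[rg[2]]] <- ccB$means
  list(model = model, XA = ccA$X, XB = ccB$X,
       tensorsA = al[[rg[1]]], tensorsB = al[[rg[2]]],
       map = ccA$map, dropped = al$dropped)
}
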