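## Group-level inference: two-level hierarchical bootstrap, factor-analysis
## shared-over-total variance (EM), and an OLS utility for the
## covariate-adjusted regressions.

#' Hierarchical (two-level) bootstrap test
#'
#' Nonparametric group inference that respects clustering by animal: each
#' resample draws animals with replacement, then draws each sampled animal's
#' values with replacement, and computes the statistic (by default the
#' difference of condition means, or the mean when there is one condition).
#' The one-sided p is the proportion of resamples on the non-hypothesized
#' side, floored at 1/n; the two-sided p doubles the smaller tail, floored at
#' 2/n (the floors at n = 1e4 are 0.0001 and 0.0002).
#'
#' @param value numeric observations.
#' @param animal animal id per observation.
#' @param condition optional condition label per observation (exactly 2
#'   levels for the default statistic); condition 2 minus condition 1.
#' @param statistic optional function(data.frame(value, animal, condition))
#'   -> scalar replacing the default.
#' @param n number of resamples (default 1e4).
#' @param sided 1 or 2.
#' @param alternative for one-sided tests, "greater" (default; hypothesis is
#'   statistic > 0) or "less".
#' @param seed RNG seed.
#' @return list: \code{mean}, \code{sd} (of the resampled statistic),
#'   \code{p}, \code{n}, \code{observed} statistic on the original data.
#' @export
hierarchicalBootstrap <- function(value, animal, condition = NULL,
                                  statistic = NULL, n = 1e4, sided = 1,
                                  alternative = c("greater", "less"),
                                  seed = 1) {
  alternative <- match.arg(alternative)
  if (!length(value)) stop("empty data")
  df <- data.frame(value = value, animal = as.character(animal),
                   condition = if (is.null(condition)) "all"
                               else as.character(condition))
  if (any(!stats::complete.cases(df))) stop("missing values in input")
  condLev <- sort(unique(df$condition))
  if (is.null(statistic)) {
    statistic <- if (length(condLev) == 2L) {
      function(d) mean(d$value[d$condition == condLev[2]]) -
                  mean(d$value[d$condition == condLev[1]])
    } else function(d) mean(d$value)
  }
  animals <- unique(df$animal)
  if (length(condLev) > 1L)
    for (cl in condLev)
      if (!length(unique(df$animal[df$condition == cl])))
        stop("empty group: ", cl)
  byA <- split(df, df$animal)
  set.seed(seed)
  resampleOnce <- function() {
    aSel <- sample(animals, length(animals), replace = TRUE)
    do.call(rbind, lapply(aSel, function(a) {
      d <- byA[[a]]
      ## resample within animal, preserving its condition composition
      idx <- unlist(lapply(split(seq_len(nrow(d)), d$condition),
                           function(ii) ii[sample.int(length(ii),
                                                      length(ii),
                                                      replace = TRUE)]),
                    use.names = FALSE)
      d[idx, , drop = FALSE]
    }))
  }
  stat <- vapply(seq_len(n), function(i) {
    for (try in 1:100) {
      s <- statistic(resampleOnce())
      if (is.finite(s)) return(s)
    }
    stop("statistic repeatedly non-finite under resampling")
  }, 0.0)
  obs <- statistic(df)
  propLE <- mean(stat <= 0)
  propGE <- mean(stat >= 0)
  if (sided == 1) {
    p <- if (alternative == "greater") propLE else propGE
    p <- max(p, 1 / n)
  } else {
    p <- min(1, max(2 * min(propLE, propGE), 2 / n))
  }
  list(mean = mean(stat), sd = stats::sd(stat), p = p, n = n,
       observed = obs, sided = sided, alternative = alternative)
}

#' Factor-analysis shared-over-total variance per unit
#'
#' Fits the factor-analysis model x ~ N(mu, U U' + Psi) (Psi diagonal) by
#' expectation-maximization and returns each unit's shared variance
#' (diag(U U')), private variance (diag(Psi)) and shared-over-total ratio.
#' Only rotation-invariant quantities are contract-bearing; U is reported up
#' to rotation. Private variances are floored at 1e-6 of the unit variance
#' for EM stability, and the log-likelihood is nondecreasing across
#' iterations.
#'
#' @param X bins x units matrix of binned counts or rates (rows >> units).
#' @param k number of latent factors (default 3).
#' @param maxIter,tol EM iteration cap and relative log-likelihood tolerance.
#' @param seed RNG seed for the random start.
#' @return list: \code{U}, \code{mu}, \code{sharedVar}, \code{privateVar},
#'   \code{ratio} (in [0, 1] per unit), \code{logLik} trace,
#'   \code{converged}, \code{droppedUnits} (zero-variance columns).
#' @export
faSharedVariance <- function(X, k = 3, maxIter = 500, tol = 1e-8, seed = 1) {
  X <- as.matrix(X)
  vars <- apply(X, 2, stats::var)
  dropped <- which(vars == 0 | is.na(vars))
  if (length(dropped)) X <- X[, -dropped, drop = FALSE]
  p <- ncol(X); nr <- nrow(X)
  if (k >= p) stop("k must be smaller than the number of units")
  if (nr <= p) stop("need more rows than units")
  mu <- colMeans(X)
  S <- stats::cov(sweep(X, 2, mu))
  floorPsi <- 1e-6 * diag(S)
  set.seed(seed)
  ## PCA-based init with small jitter
  eg <- eigen(S, symmetric = TRUE)
  U <- eg$vectors[, seq_len(k), drop = FALSE] %*%
    diag(sqrt(pmax(eg$values[seq_len(k)], 1e-8)), k) +
    matrix(stats::rnorm(p * k, sd = 1e-3), p, k)
  psi <- pmax(diag(S) - rowSums(U^2), floorPsi)
  const <- -0.5 * p * log(2 * pi)
  ll <- function(U, psi) {
    Sig <- tcrossprod(U) + diag(psi, p)
    R <- chol(Sig)
    ld <- 2 * sum(log(diag(R)))
    tr <- sum(diag(chol2inv(R) %*% S))
    nr * (const - 0.5 * (ld + tr))
  }
  trace <- ll(U, psi)
  converged <- FALSE
  for (it in seq_len(maxIter)) {
    ## E-step: posterior factor moments via Woodbury-free small-k algebra
    PsiInvU <- U / psi
    M <- diag(k) + crossprod(U, PsiInvU)           # I + U' Psi^-1 U
    Minv <- solve(M)
    beta <- Minv %*% t(PsiInvU)                    # E[z|x] = beta (x - mu)
    SB <- S %*% t(beta)                            # p x k
    Ezz <- Minv + beta %*% SB                      # E[zz'] averaged
    ## M-step
    U <- SB %*% solve(Ezz)
    psi <- pmax(diag(S) - rowSums(U * SB), floorPsi)
    lcur <- ll(U, psi)
    trace <- c(trace, lcur)
    if (abs(lcur - trace[length(trace) - 1]) <
        tol * abs(lcur) + 1e-12) { converged <- TRUE; break }
  }
  if (!converged) warning("EM did not converge in ", maxIter, " iterations")
  shared <- rowSums(U^2)
  list(U = U, mu = mu, sharedVar = shared, privateVar = psi,
       ratio = shared / (shared + psi), logLik = trace,
       converged = converged, droppedUnits = dropped)
}

#' OLS regression with animal/stage covariates
#'
#' Ordinary least-squares fit with two-sided t-tests on all coefficients;
#' shared utility behind the cross-correlation-versus-weight and
#' modulation-drop-versus-weight regressions. Rank-deficient designs are an
#' error naming the collinear columns.
#'
#' @param outcome numeric response.
#' @param covariates data.frame of predictors (factors allowed).
#' @return list: \code{coefficients} table (estimate, se, t, p),
#'   \code{r.squared}, the \code{lm} fit.
#' @export
groupSummaryRegression <- function(outcome, covariates) {
  df <- data.frame(.y = outcome, covariates, check.names = FALSE)
  mm <- stats::model.matrix(.y ~ ., data = df)
  qrm <- qr(mm)
  if (qrm$rank < ncol(mm)) {
    bad <- colnames(mm)[qrm$pivot[(qrm$rank + 1):ncol(mm)]]
    stop("rank-deficient design; collinear columns: ",
         paste(bad, collapse = ", "))
  }
  fit <- stats::lm(.y ~ ., data = df)
  sm <- summary(fit)
  list(coefficients = sm$coefficients, r.squared = sm$r.squared, fit = fit)
}
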