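## brute-force oracle: maximize cor(Xa, Yb) over unit vectors by multi-start
## general-purpose optimization, independent of the CCA path
bruteForceRho1 <- function(X, Y, nStarts = 6) {
  p <- ncol(X); q <- ncol(Y)
  obj <- function(par) {
    a <- par[1:p]; b <- par[(p + 1):(p + q)]
    if (sum(a^2) < 1e-12 || sum(b^2) < 1e-12) return(0)
    -abs(cor(X %*% a, Y %*% b))
  }
  best <- -Inf
  for (s in seq_len(nStarts)) {
    par0 <- rnorm(p + q)
    opt <- optim(par0, obj, method = "BFGS",
                 control = list(maxit = 500, reltol = 1e-12))
    best <- max(best, -opt$value)
  }
  best
}

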