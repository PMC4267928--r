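#' Control parameters for the REML engine
#'
#' @param gridMin,gridMax bounds of the log10-spaced search grid for the
#'   variance ratio delta = sigma2Random / sigma2Residual.
#' @param gridStep grid spacing in log10 units.
#' @param tol relative tolerance of the one-dimensional polish.
#' @param boundaryTol log-likelihood slack under which the zero-variance
#'   boundary is preferred over an interior optimum.
#' @return list of control values.
#' @export
remlControl <- function(gridMin = 1e-8, gridMax = 1e8, gridStep = 0.5,
                        tol = 1e-10, boundaryTol = 1e-8) {
  list(gridMin = gridMin, gridMax = gridMax, gridStep = gridStep,
       tol = tol, boundaryTol = boundaryTol)
}

#' REML for a mixed model with one random term plus residual
#'
#' Fits \code{y = X beta + u + e} with \code{Var(u) = sigma1^2 K} over the
#' observation space, or \code{y = X beta + Z u + e} with iid
#' \code{u ~ N(0, sigma1^2 I)} for an incidence matrix \code{Z}; residuals
#' are iid \code{N(0, sigmaE^2)}. The restricted likelihood is profiled
#' over the variance ratio \code{delta = sigma1^2 / sigmaE^2} (the residual
#' variance has a closed-form update), maximized by a log-spaced grid
#' search polished with Brent's method, and compared against the
#' \code{delta = 0} boundary. For the genomic parameterization \code{K} is
#' eigendecomposed once, so repeated fits on the same panel can pass a
#' precomputed decomposition via \code{Keig}.
#'
#' Failures (singular systems, non-finite likelihoods) never raise; they
#' return a fit with \code{converged = FALSE} so non-convergence can be
#' counted downstream.
#'
#' @param y response vector.
#' @param X fixed-effect design matrix (full column rank).
#' @param Z incidence matrix of iid random effects (mutually exclusive
#'   with \code{K}).
#' @param K covariance structure of a random effect living on the
#'   observations themselves (e.g. \code{Z Z'} of a marker panel).
#' @param Keig optional precomputed \code{eigen(K, symmetric = TRUE)}.
#' @param computePev compute the full prediction-error variance matrix of
#'   the BLUPs (skippable for speed in cross-validation loops).
#' @param control see \code{\link{remlControl}}.
#' @return a \linkS4class{RemlFit}.
#' @export
#' @examples
#' set.seed(1)
#' g <- rnorm(40, 0, 2); y <- rep(g, each = 2) + rnorm(80)
#' Z <- kronecker(diag(40), matrix(1, 2, 1))
#' fit <- remlFit(y, matrix(1, 80, 1), Z = Z)
#' varComp(fit)
remlFit <- function(y, X, Z = NULL, K = NULL, Keig = NULL,
                    computePev = TRUE, control = remlControl()) {
  X <- as.matrix(X)
  n <- length(y)
  p <- ncol(X)
  if (nrow(X) != n) stop("dimension mismatch between y and X")
  if (is.null(Z) == is.null(K) && is.null(Keig)) {
    stop("supply exactly one of Z or K")
  }
  if (!all(is.finite(y))) stop("response must be finite")
  if (stats::sd(y) == 0) {
    return(failedRemlFit(n, p, reason = "constant response"))
  }

  ## degenerate noiseless data: the fixed effects reproduce y exactly, the
  ## restricted likelihood diverges; return the exact-fit limit instead
  ols <- stats::lm.fit(X, y)
  rss0 <- sum(ols$residuals^2)
  if (rss0 <= 1e-10 * sum((y - mean(y))^2)) {
    s2 <- rss0 / (n - p)
    XtXi <- chol2inv(chol(crossprod(X)))
    m <- if (!is.null(Z)) ncol(Z) else n
    return(new("RemlFit", sigma2Random = 0, sigma2Residual = s2,
               delta = 0, boundary = TRUE, converged = TRUE,
               logLik = Inf, beta = unname(ols$coefficients),
               betaVcov = s2 * XtXi, blup = rep(0, m),
               pev = if (computePev) matrix(0, m, m) else
                 matrix(numeric(), 0L, 0L),
               vbarBlue = NA_real_, vbarBlup = if (computePev) 0 else
                 NA_real_, nobs = as.integer(n)))
  }

  if (!is.null(K) || !is.null(Keig)) {
    prof <- makeEigenProfiler(y, X, K, Keig)
  } else {
    prof <- makeLowRankProfiler(y, X, Z)
  }
  if (is.null(prof)) return(failedRemlFit(n, p))

  opt <- profileOptimum(prof$loglik, control)
  if (!opt$ok) return(failedRemlFit(n, p))

  fin <- tryCatch(prof$finalize(opt$delta, computePev),
                  error = function(e) NULL)
  if (is.null(fin) || !is.finite(fin$sigma2e)) return(failedRemlFit(n, p))

  vblup <- if (computePev && nrow(fin$pev) > 1L) {
    meanVarianceDifference(fin$pev)
  } else NA_real_
  new("RemlFit",
      sigma2Random = opt$delta * fin$sigma2e,
      sigma2Residual = fin$sigma2e,
      delta = opt$delta,
      boundary = opt$boundary,
      converged = TRUE,
      logLik = opt$value,
      beta = drop(fin$beta),
      betaVcov = fin$betaVcov,
      blup = fin$blup,
      pev = fin$pev,
      vbarBlue = NA_real_,
      vbarBlup = vblup,
      nobs = as.integer(n))
}

failedRemlFit <- function(n, p, reason = "optimization failure") {
  new("RemlFit", sigma2Random = NA_real_, sigma2Residual = NA_real_,
      delta = NA_real_, boundary = FALSE, converged = FALSE,
      logLik = NA_real_, beta = rep(NA_real_, p),
      betaVcov = matrix(NA_real_, p, p), blup = numeric(),
      pev = matrix(numeric(), 0L, 0L), vbarBlue = NA_real_,
      vbarBlup = NA_real_, nobs = as.integer(n))
}

## ---- profiled restricted likelihood, eigen (genomic K) path -------------

makeEigenProfiler <- function(y, X, K, Keig) {
  n <- length(y); p <- ncol(X)
  eg <- if (is.null(Keig)) {
    tryCatch(eigen(K, symmetric = TRUE), error = function(e) NULL)
  } else Keig
  if (is.null(eg)) return(NULL)
  d <- pmax(eg$values, 0)
  U <- eg$vectors
  yt <- drop(crossprod(U, y))
  Xt <- crossprod(U, X)

  core <- function(delta) {
    w <- 1 / (delta * d + 1)
    A <- crossprod(Xt, w * Xt)
    ch <- tryCatch(chol(A), error = function(e) NULL)
    if (is.null(ch)) return(NULL)
    b <- crossprod(Xt, w * yt)
    beta <- backsolve(ch, forwardsolve(t(ch), b))
    rss <- sum(w * yt^2) - sum(beta * b)
    if (!is.finite(rss) || rss <= 0) return(NULL)
    s2 <- rss / (n - p)
    ll <- -0.5 * ((n - p) * (log(2 * pi * s2) + 1) +
                    sum(log1p(delta * d)) + 2 * sum(log(diag(ch))))
    list(ll = ll, beta = beta, s2 = s2, A = A, w = w)
  }

  list(
    loglik = function(delta) {
      r <- core(delta)
      if (is.null(r)) -Inf else r$ll
    },
    finalize = function(delta, computePev) {
      r <- core(delta)
      if (is.null(r)) stop("singular system at the optimum")
      betaVcov <- r$s2 * solve(r$A)
      resT <- yt - drop(Xt %*% r$beta)
      ## BLUP of g: delta * K %*% H^{-1} res, in the eigen basis
      gRot <- (delta * d * r$w) * resT
      ghat <- drop(U %*% gRot)
      names(ghat) <- rownames(X)
      pevM <- matrix(numeric(), 0L, 0L)
      if (computePev) {
        s2g <- delta * r$s2
        ## V^{ -1} = U diag(w) U' / s2 ; G = s2g * K
        Vi <- U %*% (r$w * t(U)) / r$s2
        G <- U %*% ((s2g * d) * t(U))
        ViX <- Vi %*% X
        AXi <- solve(crossprod(X, ViX))
        P <- Vi - ViX %*% AXi %*% t(ViX)
        pevM <- symm(G - G %*% P %*% G)
      }
      list(beta = r$beta, betaVcov = betaVcov, sigma2e = r$s2,
           blup = ghat, pev = pevM)
    })
}

## ---- profiled restricted likelihood, low-rank incidence path ------------

makeLowRankProfiler <- function(y, X, Z) {
  Z <- as.matrix(Z)
  n <- length(y); p <- ncol(X); m <- ncol(Z)
  Cxx <- crossprod(X); Cxz <- crossprod(X, Z); Czz <- crossprod(Z)
  Cxy <- crossprod(X, y); Czy <- crossprod(Z, y); Cyy <- sum(y^2)

  core <- function(delta) {
    if (delta <= 0) {
      A <- Cxx
      ch <- tryCatch(chol(A), error = function(e) NULL)
      if (is.null(ch)) return(NULL)
      beta <- backsolve(ch, forwardsolve(t(ch), Cxy))
      rss <- Cyy - sum(beta * Cxy)
      ldH <- 0
    } else {
      S <- Czz + diag(1 / delta, m)
      chS <- tryCatch(chol(S), error = function(e) NULL)
      if (is.null(chS)) return(NULL)
      SiCzy <- backsolve(chS, forwardsolve(t(chS), Czy))
      SiCzx <- backsolve(chS, forwardsolve(t(chS), t(Cxz)))
      A <- Cxx - Cxz %*% SiCzx
      ch <- tryCatch(chol(symm(A)), error = function(e) NULL)
      if (is.null(ch)) return(NULL)
      b <- Cxy - Cxz %*% SiCzy
      beta <- backsolve(ch, forwardsolve(t(ch), b))
      rss <- (Cyy - sum(Czy * SiCzy)) - sum(beta * b)
      ldH <- m * log(delta) + 2 * sum(log(diag(chS)))
    }
    if (!is.finite(rss) || rss <= 0) return(NULL)
    s2 <- rss / (n - p)
    ll <- -0.5 * ((n - p) * (log(2 * pi * s2) + 1) + ldH +
                    2 * sum(log(diag(ch))))
    list(ll = ll, beta = beta, s2 = s2, A = A)
  }

  list(
    loglik = function(delta) {
      r <- core(delta)
      if (is.null(r)) -Inf else r$ll
    },
    finalize = function(delta, computePev) {
      r <- core(delta)
      if (is.null(r)) stop("singular system at the optimum")
      betaVcov <- r$s2 * solve(symm(r$A))
      res <- y - drop(X %*% r$beta)
      if (delta <= 0) {
        ublup <- rep(0, m)
        pevM <- if (computePev) matrix(0, m, m) else matrix(numeric(), 0L, 0L)
      } else {
        ## dense finish: H^{-1} = I - Z S^{-1} Z'
        S <- Czz + diag(1 / delta, m)
        Hi <- diag(n) - Z %*% solve(S, t(Z))
        ublup <- drop(delta * crossprod(Z, Hi %*% res))
        pevM <- matrix(numeric(), 0L, 0L)
        if (computePev) {
          s2u <- delta * r$s2
          Vi <- Hi / r$s2
          ViX <- Vi %*% X
          AXi <- solve(crossprod(X, ViX))
          ZtP <- crossprod(Z, Vi - ViX %*% AXi %*% t(ViX))
          pevM <- symm(diag(s2u, m) - s2u^2 * (ZtP %*% Z))
        }
      }
      names(ublup) <- colnames(Z)
      list(beta = r$beta, betaVcov = betaVcov, sigma2e = r$s2,
           blup = ublup, pev = pevM)
    })
}

## grid + Brent maximization of the profiled restricted likelihood over
## delta >= 0, with explicit comparison against the zero boundary
profileOptimum <- function(ll, control) {
  lgrid <- seq(log10(control$gridMin), log10(control$gridMax),
               by = control$gridStep)
  vals <- vapply(lgrid, function(l) ll(10^l), numeric(1))
  ll0 <- ll(0)
  if (all(!is.finite(vals)) && !is.finite(ll0)) {
    return(list(ok = FALSE))
  }
  best <- which.max(vals)
  lo <- lgrid[max(1L, best - 1L)]
  hi <- lgrid[min(length(lgrid), best + 1L)]
  opt <- tryCatch(
    stats::optimize(function(l) ll(10^l), interval = c(lo, hi),
                    maximum = TRUE, tol = 1e-8),
    error = function(e) NULL)
  if (is.null(opt)) {
    lhat <- lgrid[best]; vhat <- vals[best]
  } else {
    lhat <- opt$maximum; vhat <- opt$objective
    if (is.finite(vals[best]) && vals[best] > vhat) {
      lhat <- lgrid[best]; vhat <- vals[best]
    }
  }
  if (!is.finite(vhat) || (is.finite(ll0) && ll0 >= vhat - control$boundaryTol)) {
    if (!is.finite(ll0)) return(list(ok = FALSE))
    return(list(ok = TRUE, delta = 0, value = ll0, boundary = TRUE))
  }
  list(ok = TRUE, delta = 10^lhat, value = vhat,
       boundary = 10^lhat <= control$gridMin * 10)
}

#' REML for a genomic variance with a fixed residual covariance
#'
#' Fits \code{y = X beta + g + e} with \code{Var(g) = sigmaU2 K} and
#' \code{Var(e) = R0} held fixed (typically the stage-1 variance matrix of
#' the adjusted means carried forward). Only \code{sigmaU2} is estimated,
#' which keeps the independent-genotype structure (\code{K = I})
#' identifiable.
#'
#' @param y response.
#' @param X fixed-effect design.
#' @param K genotype covariance structure.
#' @param R0 fixed residual covariance matrix.
#' @param control see \code{\link{remlControl}}.
#' @return a \linkS4class{RemlFit} (with \code{sigma2Residual = NA}; the
#'   residual covariance is \code{R0}, not a scalar).
#' @export
remlFitFixedR <- function(y, X, K, R0, control = remlControl()) {
  X <- as.matrix(X)
  n <- length(y); p <- ncol(X)
  scale0 <- mean(diag(R0))
  llAt <- function(s) {
    V <- s * K + R0
    ch <- tryCatch(chol(V), error = function(e) NULL)
    if (is.null(ch)) return(-Inf)
    Vi <- chol2inv(ch)
    A <- crossprod(X, Vi %*% X)
    chA <- tryCatch(chol(A), error = function(e) NULL)
    if (is.null(chA)) return(-Inf)
    b <- crossprod(X, Vi %*% y)
    beta <- backsolve(chA, forwardsolve(t(chA), b))
    res <- y - drop(X %*% beta)
    q <- sum(res * (Vi %*% res))
    -0.5 * ((n - p) * log(2 * pi) + 2 * sum(log(diag(ch))) +
              2 * sum(log(diag(chA))) + q)
  }
  lgrid <- seq(log10(scale0) - 8, log10(scale0) + 8, by = 0.5)
  vals <- vapply(lgrid, function(l) llAt(10^l), numeric(1))
  ll0 <- llAt(0)
  best <- which.max(vals)
  opt <- tryCatch(stats::optimize(function(l) llAt(10^l),
                                  interval = c(lgrid[max(1L, best - 1L)],
                                               lgrid[min(length(lgrid), best + 1L)]),
                                  maximum = TRUE, tol = 1e-8),
                  error = function(e) NULL)
  if (all(!is.finite(vals)) && !is.finite(ll0)) {
    return(failedRemlFit(n, p))
  }
  if (is.null(opt) || (is.finite(vals[best]) && vals[best] > opt$objective)) {
    shat <- 10^lgrid[best]; vhat <- vals[best]
  } else {
    shat <- 10^opt$maximum; vhat <- opt$objective
  }
  boundary <- FALSE
  if (is.finite(ll0) && ll0 >= vhat - control$boundaryTol) {
    shat <- 0; vhat <- ll0; boundary <- TRUE
  }
  ## finalize at shat
  V <- shat * K + R0
  Vi <- chol2inv(chol(V))
  A <- crossprod(X, Vi %*% X)
  Ai <- solve(A)
  beta <- drop(Ai %*% crossprod(X, Vi %*% y))
  res <- y - drop(X %*% beta)
  G <- shat * K
  ghat <- drop(G %*% (Vi %*% res))
  ViX <- Vi %*% X
  P <- Vi - ViX %*% Ai %*% t(ViX)
  pevM <- symm(G - G %*% P %*% G)
  new("RemlFit", sigma2Random = shat, sigma2Residual = NA_real_,
      delta = NA_real_, boundary = boundary, converged = TRUE,
      logLik = vhat, beta = beta, betaVcov = Ai,
      blup = stats::setNames(ghat, rownames(K)),
      pev = pevM, vbarBlue = NA_real_,
      vbarBlup = if (n > 1) meanVarianceDifference(pevM) else NA_real_,
      nobs = as.integer(n))
}

#' Solve the mixed-model equations at fixed variance components
#'
#' Henderson-equation solution for \code{y = X beta + g + e},
#' \code{Var(g) = sigmaU2 K}, \code{Var(e) = sigmaE2 I}, written in the
#' variance form so singular \code{K} (e.g. \code{Z Z'} with fewer markers
#' than genotypes) is handled: BLUEs by generalized least squares, BLUPs as
#' \code{G V^{-1} (y - X beta)}, and the prediction-error variance as the
#' genotype block of the inverted coefficient matrix,
#' \code{G - G P G}.
#'
#' @param y response.
#' @param X fixed-effect design.
#' @param K genotype covariance structure.
#' @param sigmaU2,sigmaE2 fixed variance components (sigmaE2 > 0).
#' @return list with \code{beta}, \code{betaVcov}, \code{blup}, \code{pev}.
#' @export
solveMME <- function(y, X, K, sigmaU2, sigmaE2) {
  if (sigmaE2 <= 0) stop("sigmaE2 must be > 0")
  if (sigmaU2 < 0) stop("sigmaU2 must be >= 0")
  X <- as.matrix(X)
  n <- length(y)
  G <- sigmaU2 * K
  V <- G + diag(sigmaE2, n)
  Vi <- chol2inv(chol(V))
  A <- crossprod(X, Vi %*% X)
  Ai <- tryCatch(solve(A), error = function(e) stop("singular coefficient matrix"))
  beta <- drop(Ai %*% crossprod(X, Vi %*% y))
  res <- y - drop(X %*% beta)
  ghat <- drop(G %*% (Vi %*% res))
  ViX <- Vi %*% X
  P <- Vi - ViX %*% Ai %*% t(ViX)
  pevM <- symm(G - G %*% P %*% G)
  list(beta = beta, betaVcov = Ai, blup = ghat, pev = pevM)
}

#' Mean variance of a difference
#'
#' Average of \code{var(d_i - d_j) = v_ii + v_jj - 2 v_ij} over all
#' \code{n (n - 1) / 2} unordered pairs, computed from a variance matrix of
#' adjusted means (vbar) or from a BLUP prediction-error variance matrix
#' (vbar_BLUP).
#'
#' @param V variance matrix, n >= 2.
#' @return the mean pairwise difference variance.
#' @export
#' @examples
#' meanVarianceDifference(diag(3))  # independent equal-variance means: 2v
meanVarianceDifference <- function(V) {
  n <- nrow(V)
  if (is.null(n) || n < 2L) stop("need a variance matrix for >= 2 entities")
  2 * (n * sum(diag(V)) - sum(V)) / (n * (n - 1))
}
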