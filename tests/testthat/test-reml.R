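test_that("REML on a balanced one-way layout matches the ANOVA closed form", {
  ## balanced case: sigma_e^2 = MSE, sigma_g^2 = max(0, (MSB - MSE) / r)
  oneWay <- function(seed, sg2) {
    set.seed(seed)
    n <- 6L; r <- 2L
    g <- rnorm(n, 0, sqrt(sg2))
    y <- rep(g, each = r) + rnorm(n * r, 0, 1)
    Z <- kronecker(diag(n), matrix(1, r, 1L))
    fit <- remlFit(y, matrix(1, n * r, 1L), Z = Z)
    aovTab <- anova(stats::aov(y ~ factor(rep(seq_len(n), each = r))))
    msb <- aovTab$`Mean Sq`[1L]; mse <- aovTab$`Mean Sq`[2L]
    list(fit = fit, msb = msb, mse = mse, r = r)
  }
  ## interior solution
  o <- oneWay(seed = 3L, sg2 = 9)
  expect_true(converged(o$fit))
  expect_false(isBoundary(o$fit))
  expect_equal(unname(varComp(o$fit)["residual"]), o$mse, tolerance = 1e-5)
  expect_equal(unname(varComp(o$fit)["random"]),
               max(0, (o$msb - o$mse) / o$r), tolerance = 1e-5)
  ## boundary solution reachable under zero genetic signal
  hits <- vapply(1:30, function(s) {
    isBoundary(oneWay(seed = 100 + s, sg2 = 0)$fit)
  }, logical(1))
  expect_gt(sum(hits), 0L)
  b <- oneWay(seed = 104L, sg2 = 0)  # MSB < MSE draw
  if (isBoundary(b$fit)) {
    expect_equal(unname(varComp(b$fit)["random"]), 0)
  }
})

test_that("the incidence and eigendecomposition paths agree", {
  set.seed(11)
  n <- 8L; r <- 3L
  g <- rnorm(n, 0, 2)
  y <- rep(g, each = r) + rnorm(n * r)
  X <- matrix(1, n * r, 1L)
  Z <- kronecker(diag(n), matrix(1, r, 1L))
  f1 <- remlFit(y, X, Z = Z)
  f2 <- remlFit(y, X, K = tcrossprod(Z))
  expect_equal(varComp(f1), varComp(f2), tolerance = 1e-6)
  expect_equal(f1@beta, f2@beta, tolerance = 1e-6)
  expect_equal(f1@logLik, f2@logLik, tolerance = 1e-6)
  ## BLUPs: incidence path predicts the n iid effects, eigen path their
  ## image on the observations
  expect_equal(unname(drop(Z %*% blup(f1))), unname(blup(f2)),
               tolerance = 1e-5)
})

test_that("the stage-1 model agrees with an lme4 fit of the same model", {
  tr <- smallTrial(sigmaB2 = 4, sigmaE2 = 10, seed = 21L)
  rec <- trialRecords(tr)
  geno <- sort(unique(rec$genotype))
  dat <- data.frame(y = rec$yield,
                    genotype = factor(rec$genotype, levels = geno),
                    replicate = factor(rec$replicate),
                    blockId = factor(paste(rec$replicate, rec$block)))
  ref <- lme4::lmer(y ~ 0 + genotype + replicate + (1 | blockId),
                    data = dat, REML = TRUE)
  vc <- as.data.frame(lme4::VarCorr(ref))

  am <- stage1AdjustedMeans(tr)
  expect_equal(am@sigma2Block, vc$vcov[vc$grp == "blockId"],
               tolerance = 1e-4)
  expect_equal(am@sigma2Residual, vc$vcov[vc$grp == "Residual"],
               tolerance = 1e-4)
  fe <- lme4::fixef(ref)
  pRef <- unname(fe[seq_along(geno)] + fe[length(fe)] / 2)
  expect_equal(unname(adjustedMeans(am)), pRef, tolerance = 1e-4)
})

test_that("REML is invariant to adding a constant to the response", {
  set.seed(31)
  n <- 10L; r <- 2L
  y <- rep(rnorm(n, 0, 2), each = r) + rnorm(n * r)
  X <- matrix(1, n * r, 1L)
  Z <- kronecker(diag(n), matrix(1, r, 1L))
  f1 <- remlFit(y, X, Z = Z)
  f2 <- remlFit(y + 100, X, Z = Z)
  expect_equal(varComp(f1), varComp(f2), tolerance = 1e-6)
  expect_equal(blup(f1), blup(f2), tolerance = 1e-6)
})

test_that("REML recovers simulating variance components without gross bias", {
  nSim <- 120L
  n <- 60L; r <- 2L
  X <- matrix(1, n * r, 1L)
  Z <- kronecker(diag(n), matrix(1, r, 1L))
  est <- t(vapply(seq_len(nSim), function(s) {
    set.seed(1000 + s)
    y <- rep(rnorm(n, 0, 2), each = r) + rnorm(n * r, 0, 1)
    varComp(remlFit(y, X, Z = Z))
  }, numeric(2)))
  ## truth sigma_g^2 = 4, sigma_e^2 = 1; means within 3 Monte-Carlo SEs
  for (j in 1:2) {
    se <- stats::sd(est[, j]) / sqrt(nSim)
    expect_lt(abs(mean(est[, j]) - c(4, 1)[j]), 3 * se)
  }
  ## no gross under-optimization: restricted likelihood at the estimate is
  ## at least its value at the true simulating parameters
  set.seed(2000)
  y <- rep(rnorm(n, 0, 2), each = r) + rnorm(n * r, 0, 1)
  fit <- remlFit(y, X, Z = Z)
  prof <- gpacc:::makeLowRankProfiler(y, X, Z)
  expect_gte(fit@logLik, prof$loglik(4 / 1) - 1e-6)
})

test_that("non-convergence and degenerate inputs are flagged, not raised", {
  n <- 6L
  yConst <- rep(1, n)
  fit <- remlFit(yConst, matrix(1, n, 1L), K = diag(n))
  expect_false(converged(fit))
  expect_true(is.na(varComp(fit)["random"]))
  expect_error(remlFit(rnorm(4), matrix(1, 5, 1), K = diag(4)), "dimension")
})

test_that("mixed-model equations reproduce known limits and identities", {
  set.seed(41)
  n <- 5L
  y <- rnorm(n, 2, 1.5)
  X <- matrix(1, n, 1L)
  K <- diag(n)

  ## total shrinkage at zero genetic variance
  s0 <- solveMME(y, X, K, sigmaU2 = 0, sigmaE2 = 1)
  expect_equal(s0$blup, rep(0, n))
  expect_equal(s0$pev, matrix(0, n, n))

  ## scalar shrinkage: ghat_i = h2 (y_i - ybar) in the balanced iid case
  s1 <- solveMME(y, X, K, sigmaU2 = 3, sigmaE2 = 2)
  h2 <- 3 / (3 + 2)
  expect_equal(s1$blup, h2 * (y - mean(y)), tolerance = 1e-8)

  ## infinite-variance limit: BLUPs approach centered BLUEs
  sInf <- solveMME(y, X, K, sigmaU2 = 1e9, sigmaE2 = 1)
  expect_equal(sInf$blup, y - mean(y), tolerance = 1e-6)

  ## explicit Henderson coefficient-matrix cross-check (nonsingular K)
  set.seed(42)
  Kp <- randomPsd(n, jitter = 0.5)
  su2 <- 1.7; se2 <- 0.9
  s2 <- solveMME(y, X, Kp, su2, se2)
  Zi <- diag(n)
  Cmat <- rbind(
    cbind(crossprod(X) / se2, crossprod(X, Zi) / se2),
    cbind(crossprod(Zi, X) / se2, crossprod(Zi) / se2 + solve(su2 * Kp)))
  rhs <- c(crossprod(X, y) / se2, crossprod(Zi, y) / se2)
  sol <- solve(Cmat, rhs)
  expect_equal(unname(s2$beta), sol[1L], tolerance = 1e-8)
  expect_equal(unname(s2$blup), sol[-1L], tolerance = 1e-8)
  ## the genotype block of the inverted coefficient matrix IS the PEV
  expect_equal(s2$pev, solve(Cmat)[-1L, -1L], tolerance = 1e-8)
})

test_that("ridge-regression marker BLUP equals the genomic-covariance BLUP", {
  set.seed(51)
  n <- 12L; q <- 25L
  mk <- smallMarkers(n = n, q = q, seed = 51L)
  Z <- markerCodes(mk)
  y <- rnorm(n, 5, 2)
  X <- matrix(1, n, 1L)
  su2 <- 0.05; se2 <- 1.3
  gb <- solveMME(y, X, tcrossprod(Z), su2, se2)
  ## marker formulation: u = (Z'Z + lambda I)^-1 Z' (y - X beta)
  lambda <- se2 / su2
  res <- y - drop(X %*% gb$beta)
  u <- solve(crossprod(Z) + diag(lambda, q), crossprod(Z, res))
  expect_equal(unname(gb$blup), unname(drop(Z %*% u)), tolerance = 1e-8)
})

test_that("mean variance of a difference matches pairwise algebra", {
  expect_equal(meanVarianceDifference(diag(3) * 2.5), 5)
  ## compound symmetry: v on the diagonal, c off -> 2 (v - c)
  V <- matrix(0.4, 5L, 5L); diag(V) <- 1.9
  expect_equal(meanVarianceDifference(V), 2 * (1.9 - 0.4))
  ## brute force over all pairs on a random PSD matrix
  set.seed(61)
  W <- randomPsd(6L)
  pairs <- utils::combn(6L, 2L)
  brute <- mean(apply(pairs, 2L, function(ij) {
    W[ij[1], ij[1]] + W[ij[2], ij[2]] - 2 * W[ij[1], ij[2]]
  }))
  expect_equal(meanVarianceDifference(W), brute)
  expect_error(meanVarianceDifference(matrix(1, 1, 1)), ">= 2")
})
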