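test_that("noiseless trials give exact adjusted means", {
  mk <- smallMarkers(n = 12L, q = 20L)
  truth <- simulateBreedingValues(mk, 0.5, seed = 1L)
  des <- generateAlphaDesign(12L, 2L, 4L, seed = 2L,
                             genotypes = genotypeIds(mk))
  tr <- simulateTrial(des, truth, sigmaB2 = 0, sigmaE2 = 0, seed = 3L)
  am <- stage1AdjustedMeans(tr)
  expect_true(converged(am))
  g <- breedingValues(truth)
  p <- adjustedMeans(am)
  ## differences reproduce true breeding-value differences exactly
  expect_equal(unname(p - p[1L]), unname(g[names(p)] - g[names(p)][1L]),
               tolerance = 1e-8)
})

test_that("balanced complete blocks reduce adjusted means to raw means", {
  mk <- smallMarkers(n = 10L, q = 20L, seed = 7L)
  truth <- simulateBreedingValues(mk, 0.4, seed = 8L)
  ## blockSize = n makes each replicate one complete block
  des <- generateAlphaDesign(10L, 2L, 10L, seed = 9L,
                             genotypes = genotypeIds(mk))
  tr <- simulateTrial(des, truth, sigmaB2 = 0, sigmaE2 = 6, seed = 10L)
  am <- stage1AdjustedMeans(tr)
  rec <- trialRecords(tr)
  raw <- tapply(rec$yield, rec$genotype, mean)
  p <- adjustedMeans(am)
  expect_equal(unname(p - mean(p)),
               as.numeric(raw[names(p)] - mean(raw)), tolerance = 1e-6)
  ## and vbar collapses to the balanced closed form 2 sigma_e^2 / r
  expect_equal(am@vbar, 2 * am@sigma2Residual / 2, tolerance = 1e-6)
})

test_that("adjusted means have the scenario's dimensions and symmetry", {
  tr <- smallTrial(seed = 30L)
  am <- stage1AdjustedMeans(tr)
  expect_length(adjustedMeans(am), 30L)
  expect_equal(dim(meansVcov(am)), c(30L, 30L))
  expect_equal(meansVcov(am), t(meansVcov(am)), tolerance = 1e-10)
  ## vbar is invariant to genotype relabeling (it averages over all pairs)
  perm <- sample(30L)
  expect_equal(meanVarianceDifference(meansVcov(am)[perm, perm]), am@vbar)
})

test_that("genomic stage 2 recovers simulating parameters on average", {
  n <- 60L
  mk <- smallMarkers(n = n, q = 80L, seed = 40L)
  K <- tcrossprod(markerCodes(mk))
  Keig <- eigen(K, symmetric = TRUE)
  su2 <- 0.1; se2 <- 8
  nSim <- 150L
  est <- t(vapply(seq_len(nSim), function(s) {
    set.seed(3000 + s)
    u <- rnorm(80L, 0, sqrt(su2))
    p <- 10 + drop(markerCodes(mk) %*% u) + rnorm(n, 0, sqrt(se2))
    fit <- remlFit(p, matrix(1, n, 1L), K = K, Keig = Keig,
                   computePev = FALSE)
    varComp(fit)
  }, numeric(2)))
  for (j in 1:2) {
    se <- stats::sd(est[, j]) / sqrt(nSim)
    expect_lt(abs(mean(est[, j]) - c(su2, se2)[j]), 3 * se)
  }
})

test_that("two-stage prediction is exact on noiseless data", {
  mk <- smallMarkers(n = 25L, q = 40L, seed = 50L)
  truth <- simulateBreedingValues(mk, 0.5, seed = 51L)
  des <- generateAlphaDesign(25L, 2L, 5L, seed = 52L,
                             genotypes = genotypeIds(mk))
  tr <- simulateTrial(des, truth, sigmaB2 = 0, sigmaE2 = 0, seed = 53L)
  am <- stage1AdjustedMeans(tr)
  fit <- stage2Fit(am, "genomic", markers = mk)
  expect_gt(stats::cor(blup(fit), breedingValues(truth)[names(blup(fit))]),
            0.999)
})

test_that("independent structure is the vcov-weighted special case of genomic", {
  set.seed(60)
  n <- 20L
  R0 <- diag(2, n)
  g <- rnorm(n, 0, 2)
  p <- 5 + g + rnorm(n, 0, sqrt(2))
  names(p) <- sprintf("G%03d", 1:n)
  am <- new("AdjustedMeans", p = p, vcov = R0, sigma2Block = 0,
            sigma2Residual = 2, vbar = meanVarianceDifference(R0),
            converged = TRUE)
  cc <- 1.5
  fitInd <- stage2Fit(am, "independent")
  fitGen <- stage2Fit(am, "genomic", K = diag(cc^2, n), weighting = "vcov")
  ## Var(g) = c^2 I sigma_u^2 is a reparameterization of I sigma_g^2
  expect_equal(fitInd@sigma2Random, cc^2 * fitGen@sigma2Random,
               tolerance = 1e-4)
  expect_equal(blup(fitInd), blup(fitGen), tolerance = 1e-5)
  ## the unweighted iid-residual variant is not identifiable
  expect_error(stage2Fit(am, "independent", weighting = "simple"),
               "identifiable")
})

test_that("boundary stage-2 fits shrink everything to zero", {
  set.seed(70)
  n <- 40L
  mk <- smallMarkers(n = n, q = 30L, seed = 70L)
  ## pure noise: genetic variance should hit the boundary
  hit <- FALSE
  for (s in 1:12) {
    set.seed(700 + s)
    p <- stats::setNames(rnorm(n, 0, 3), genotypeIds(mk))
    am <- new("AdjustedMeans", p = p, vcov = diag(9, n), sigma2Block = 0,
              sigma2Residual = 9, vbar = 18, converged = TRUE)
    fit <- stage2Fit(am, "genomic", markers = mk)
    if (isBoundary(fit)) {
      hit <- TRUE
      expect_equal(unname(blup(fit)), rep(0, n))
      expect_equal(varComp(fit)[["random"]], 0)
      break
    }
  }
  expect_true(hit)
})

test_that("shrinkage orders the two mean difference variances", {
  tr <- smallTrial(seed = 80L, sigmaU2 = 0.3)
  am <- stage1AdjustedMeans(tr)
  mk <- smallMarkers(seed = 80L)
  fit <- stage2Fit(am, "genomic", markers = mk)
  expect_false(is.na(fit@vbarBlup))
  expect_lte(fit@vbarBlup, fit@vbarBlue + 1e-8)
  expect_gte(fit@vbarBlup, 0)
  ## PEV diagonal bounded by the prior genotype variance
  G <- fit@sigma2Random * tcrossprod(markerCodes(mk))
  expect_true(all(diag(pev(fit)) <= diag(G) + 1e-6))
  expect_true(all(diag(pev(fit)) >= -1e-8))
})

test_that("the plot model flags the genetic-variance boundary", {
  ## strong signal: interior solution
  tr <- smallTrial(seed = 90L, sigmaU2 = 1, sigmaE2 = 5)
  fit <- fitPlotModel(tr, computePev = TRUE)
  expect_true(converged(fit))
  expect_false(isBoundary(fit))
  expect_gt(varComp(fit)[["genotype"]], 0)
  expect_equal(dim(pev(fit)), c(30L, 30L))
  expect_false(is.na(fit@vbarBlup))

  ## zero genetic signal: boundary reachable
  mk <- smallMarkers(n = 25L, q = 30L, seed = 91L)
  hits <- vapply(1:8, function(s) {
    truth <- simulateBreedingValues(mk, 0, seed = s)
    des <- generateAlphaDesign(25L, 2L, 5L, seed = s + 50L,
                               genotypes = genotypeIds(mk))
    tr0 <- simulateTrial(des, truth, sigmaB2 = 2, sigmaE2 = 10,
                         seed = s + 100L)
    isBoundary(fitPlotModel(tr0))
  }, logical(1))
  expect_gt(sum(hits), 0L)
})

test_that("plot-model PEV agrees with the stage-agnostic MME computation", {
  tr <- smallTrial(seed = 95L, sigmaU2 = 0.5, sigmaB2 = 0, sigmaE2 = 8)
  fit <- fitPlotModel(tr, computePev = TRUE)
  rec <- trialRecords(tr)
  geno <- sort(unique(rec$genotype))
  ## with sigma_b^2 at (near) zero the model collapses to a one-random-term
  ## model solvable by solveMME on the genotype incidence
  if (varComp(fit)[["block"]] < 1e-6) {
    Zg <- stats::model.matrix(~ 0 + factor(rec$genotype, levels = geno))
    X <- stats::model.matrix(~ factor(rec$replicate))
    mme <- solveMME(rec$yield, X, tcrossprod(Zg),
                    varComp(fit)[["genotype"]], varComp(fit)[["residual"]])
    pevObs <- mme$pev
    ## map observation-level PEV back to genotype level
    M <- Zg / 2  # each genotype seen twice
    mapped <- gpacc:::symm(t(M) %*% pevObs %*% M)
    dimnames(mapped) <- dimnames(pev(fit))
    expect_equal(pev(fit), mapped, tolerance = 1e-4)
  }
  succeed()
})
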