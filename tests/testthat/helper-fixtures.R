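## Small fixtures built in code; sizes chosen so unit tests stay fast while
## keeping the alpha-design structure (incomplete blocks, 2 replicates).

smallMarkers <- function(n = 30L, q = 50L, seed = 42L, dh = TRUE) {
  simulateMarkerMatrix(n, q, dhMode = dh, seed = seed)
}

smallTrial <- function(n = 30L, q = 50L, sigmaU2 = 0.2, sigmaB2 = 3,
                       sigmaE2 = 12, blockSize = 6L, r = 2L, seed = 42L,
                       markers = smallMarkers(n, q, seed)) {
  truth <- simulateBreedingValues(markers, sigmaU2, seed = seed + 1L)
  des <- generateAlphaDesign(n, r, blockSize, seed = seed + 2L,
                             genotypes = genotypeIds(markers))
  simulateTrial(des, truth, mu = 0, gamma = rep(0, r), sigmaB2 = sigmaB2,
                sigmaE2 = sigmaE2, seed = seed + 3L)
}

smallConfig <- function(scenarioId = 1L, n = 30L, q = 50L, sigmaU2 = 0.2,
                        k = 5, nDatasets = 2L, seed = 77L) {
  scenarioConfig(scenarioId, n, q, sigmaU2, 48.6728, errorSD = 6.977,
                 blockSize = 6L, outlierMultiplier = k,
                 nDatasets = nDatasets, seed = seed)
}

## explicit centering operator, for brute-force trace oracles
explicitPu <- function(n) (diag(n) - matrix(1 / n, n, n)) / (n - 1)

## brute-force trace of a matrix product via elementwise sums
bruteTrace <- function(A, B) sum(t(A) * B)

## random symmetric positive definite matrix
randomPsd <- function(n, jitter = 0.1) {
  A <- matrix(stats::rnorm(n * n), n)
  crossprod(A) / n + diag(jitter, n)
}
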