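#' Simulate a biallelic marker panel
#'
#' Markers are drawn independently: each marker gets a sampling allele
#' frequency uniform in \code{[mafLow, mafHigh]}, then genotype codes are
#' drawn per line. In doubled-haploid mode (the default; both maize panels
#' the simulator emulates are DH lines) codes are +1/-1 with probability
#' f/(1-f); otherwise Hardy-Weinberg genotypes are drawn and heterozygotes
#' coded 0. Columns that come out constant are redrawn so every marker has
#' positive minor allele frequency.
#'
#' @param n number of genotypes.
#' @param q number of markers.
#' @param mafLow,mafHigh allele-frequency bounds, 0 < mafLow <= mafHigh <= 0.5.
#' @param dhMode logical; doubled-haploid coding without heterozygotes.
#' @param seed integer seed.
#' @return a \linkS4class{MarkerMatrix}.
#' @export
#' @examples
#' simulateMarkerMatrix(6L, 10L, seed = 1L)
simulateMarkerMatrix <- function(n, q, mafLow = 0.05, mafHigh = 0.5,
                                 dhMode = TRUE, seed = 1L) {
  if (mafLow <= 0 || mafHigh > 0.5 || mafLow > mafHigh) {
    stop("need 0 < mafLow <= mafHigh <= 0.5")
  }
  if (n < 1L || q < 1L) stop("n and q must be >= 1")
  set.seed(seed)
  freq <- stats::runif(q, mafLow, mafHigh)
  drawCol <- function(f) {
    if (dhMode) {
      ifelse(stats::runif(n) < f, 1, -1)
    } else {
      u <- stats::runif(n)
      ifelse(u < f^2, 1, ifelse(u < f^2 + 2 * f * (1 - f), 0, -1))
    }
  }
  Z <- vapply(freq, drawCol, numeric(n))
  ## redraw monomorphic columns (possible at small n)
  repeat {
    const <- which(apply(Z, 2L, function(col) max(col) == min(col)))
    if (!length(const)) break
    for (j in const) Z[, j] <- drawCol(freq[j])
  }
  dimnames(Z) <- list(sprintf("G%03d", seq_len(n)), sprintf("M%05d", seq_len(q)))
  new("MarkerMatrix", Z = Z, alleleFreq = freq)
}

#' Simulate marker effects and true breeding values
#'
#' Marker effects \code{u ~ iid N(0, sigmaU2)}; breeding values
#' \code{g = Z u}, so that \code{Var(g) = Z Z' sigmaU2} over repeated draws.
#'
#' @param markers a \linkS4class{MarkerMatrix}.
#' @param sigmaU2 marker-effect variance (>= 0).
#' @param seed integer seed.
#' @return a \linkS4class{BreedingValues}.
#' @export
simulateBreedingValues <- function(markers, sigmaU2, seed = 1L) {
  if (sigmaU2 < 0) stop("sigmaU2 must be >= 0")
  Z <- markerCodes(markers)
  set.seed(seed)
  u <- stats::rnorm(ncol(Z), 0, sqrt(sigmaU2))
  g <- drop(Z %*% u)
  names(g) <- rownames(Z)
  new("BreedingValues", u = u, g = g)
}

#' Generate a resolvable incomplete-block (alpha) design
#'
#' Each replicate contains every genotype exactly once, distributed over
#' \code{ceiling(n / blockSize)} incomplete blocks whose sizes differ by at
#' most one plot (177 genotypes in blocks of 18 gives 7 blocks of 18 and 3
#' of 17). Genotype-to-block allocation is randomized independently within
#' each replicate.
#'
#' @param n number of genotypes.
#' @param r number of complete replicates.
#' @param blockSize plots per incomplete block.
#' @param seed integer seed.
#' @param genotypes optional genotype ids (default \code{G001, ...}).
#' @return data.frame with columns genotype, replicate, block, plot.
#' @export
#' @examples
#' d <- generateAlphaDesign(177L, 2L, 18L, seed = 1L)
#' table(d$replicate, d$block)
generateAlphaDesign <- function(n, r = 2L, blockSize = 18L, seed = 1L,
                                genotypes = sprintf("G%03d", seq_len(n))) {
  if (blockSize > n) stop("blockSize must not exceed n")
  if (blockSize < 2L || r < 1L) stop("need blockSize >= 2 and r >= 1")
  nBlocks <- ceiling(n / blockSize)
  sizes <- rep(floor(n / nBlocks), nBlocks)
  extra <- n - sum(sizes)
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  set.seed(seed)
  out <- lapply(seq_len(r), function(k) {
    perm <- sample(genotypes)
    data.frame(genotype = perm,
               replicate = k,
               block = rep(seq_len(nBlocks), times = sizes),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  out$plot <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Simulate alpha-design trial data from the plot model
#'
#' Yields follow
#' \code{y = mu + gamma[replicate] + b[block within replicate] + g[genotype]
#' + e[plot]} with \code{b ~ iid N(0, sigmaB2)} and
#' \code{e ~ iid N(0, sigmaE2)}. All generated components are stored on the
#' returned object so the identity is checkable.
#'
#' @param design data.frame from \code{\link{generateAlphaDesign}}.
#' @param truth a \linkS4class{BreedingValues} covering every genotype in
#'   the design.
#' @param mu general mean.
#' @param gamma fixed replicate effects (recycled scalar 0 by default).
#' @param sigmaB2,sigmaE2 block and plot-error variances (>= 0).
#' @param seed integer seed.
#' @return a \linkS4class{TrialData}.
#' @export
simulateTrial <- function(design, truth, mu = 0, gamma = NULL,
                          sigmaB2 = 0, sigmaE2 = 1, seed = 1L) {
  if (sigmaB2 < 0 || sigmaE2 < 0) stop("variances must be >= 0")
  r <- max(design$replicate)
  if (is.null(gamma)) gamma <- rep(0, r)
  if (length(gamma) != r) stop("gamma must have one entry per replicate")
  g <- breedingValues(truth)
  if (!all(design$genotype %in% names(g))) {
    stop("truth must cover every genotype in the design")
  }
  set.seed(seed)
  blocks <- unique(design[, c("replicate", "block")])
  blocks$effect <- stats::rnorm(nrow(blocks), 0, sqrt(sigmaB2))
  e <- stats::rnorm(nrow(design), 0, sqrt(sigmaE2))
  bkey <- paste(blocks$replicate, blocks$block)
  b <- blocks$effect[match(paste(design$replicate, design$block), bkey)]
  rec <- design
  rec$yield <- mu + gamma[rec$replicate] + b + unname(g[rec$genotype]) + e
  new("TrialData", records = rec, mu = mu, gamma = gamma,
      blockEffects = blocks, plotErrors = e, truth = truth,
      outlier = list())
}

#' Contaminate one plot observation with an outlier
#'
#' Picks one plot record uniformly at random and increases its yield by
#' exactly \code{k * sigmaE}; every other record is untouched, so the
#' contaminated trial is the common-random-numbers twin of its input.
#'
#' @param trial an uncontaminated \linkS4class{TrialData}.
#' @param k outlier multiplier (> 0).
#' @param sigmaE plot-error SD defining the shift scale.
#' @param seed integer seed for the position draw.
#' @return contaminated \linkS4class{TrialData}.
#' @export
injectOutlier <- function(trial, k, sigmaE, seed = 1L) {
  if (length(trial@outlier)) stop("trial is already contaminated")
  if (k <= 0) stop("k must be > 0")
  set.seed(seed)
  idx <- sample.int(nrow(trial@records), 1L)
  shift <- k * sigmaE
  trial@records$yield[idx] <- trial@records$yield[idx] + shift
  trial@outlier <- list(record = idx, shift = shift)
  validObject(trial)
  trial
}
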