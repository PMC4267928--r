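#' @import methods
NULL

#' ScenarioConfig: one simulation scenario
#'
#' Bundles the dimensions and variance components that define one simulated
#' trial series: number of genotypes and markers, marker-effect variance
#' (yield^2 per allele substitution), plot-error variance and its SD
#' (yield units), incomplete-block variance, replication, and the outlier
#' multiplier applied to a single plot observation.
#'
#' The printed error SD (6.977 / 7.340) and error variance (48.6728 /
#' 53.8715) of the maize trials the simulator emulates agree only to about
#' three significant digits, so the validity check tolerates a 1% relative
#' discrepancy between \code{errorSD} and \code{sqrt(errorVariance)};
#' simulation uses the variance, outlier shifts use the SD.
#'
#' @slot scenarioId integer label (1-10 for the presets).
#' @slot nGenotypes number of genotypes.
#' @slot nMarkers number of biallelic markers.
#' @slot markerVariance variance of iid marker effects, sigma_u^2.
#' @slot errorVariance plot-error variance, sigma_e^2.
#' @slot errorSD plot-error SD used for the outlier shift.
#' @slot blockVariance incomplete-block variance, sigma_b^2.
#' @slot nReplicates complete replicates r.
#' @slot blockSize plots per incomplete block.
#' @slot outlierMultiplier k; the contaminated twin gets one yield shifted
#'   by \code{k * errorSD}. \code{k = 0} means uncontaminated.
#' @slot nDatasets datasets simulated per scenario.
#' @slot seed master seed of the scenario stream.
#' @export
setClass("ScenarioConfig",
  representation(
    scenarioId = "integer",
    nGenotypes = "integer",
    nMarkers = "integer",
    markerVariance = "numeric",
    errorVariance = "numeric",
    errorSD = "numeric",
    blockVariance = "numeric",
    nReplicates = "integer",
    blockSize = "integer",
    outlierMultiplier = "numeric",
    nDatasets = "integer",
    seed = "integer"
  )
)

setValidity("ScenarioConfig", function(object) {
  msg <- character()
  if (object@markerVariance < 0) msg <- c(msg, "markerVariance must be >= 0")
  if (object@errorVariance <= 0) msg <- c(msg, "errorVariance must be > 0")
  if (object@blockVariance < 0) msg <- c(msg, "blockVariance must be >= 0")
  if (abs(object@errorSD - sqrt(object@errorVariance)) >
      0.01 * object@errorSD) {
    msg <- c(msg, "errorSD must equal sqrt(errorVariance) to within 1%")
  }
  if (!object@outlierMultiplier %in% c(0, 5, 8, 10)) {
    msg <- c(msg, "outlierMultiplier must be one of 0, 5, 8, 10")
  }
  if (object@nReplicates < 1L) msg <- c(msg, "nReplicates must be >= 1")
  if (object@blockSize < 2L) msg <- c(msg, "blockSize must be >= 2")
  if (length(msg)) msg else TRUE
})

#' MarkerMatrix: biallelic marker panel
#'
#' Marker covariates coded -1/0/+1 (homozygote / heterozygote or missing /
#' other homozygote). Doubled-haploid panels carry no zeros. Rows are
#' genotypes, columns markers; no column may be constant (MAF > 0).
#'
#' @slot Z numeric matrix of marker codes with genotype ids as rownames.
#' @slot alleleFreq sampling allele frequency per marker, in (0, 1).
#' @export
setClass("MarkerMatrix",
  representation(Z = "matrix", alleleFreq = "numeric")
)

setValidity("MarkerMatrix", function(object) {
  msg <- character()
  if (!all(object@Z %in% c(-1, 0, 1))) {
    msg <- c(msg, "marker codes must be -1, 0 or 1")
  }
  rng <- apply(object@Z, 2L, function(col) max(col) - min(col))
  if (any(rng == 0)) msg <- c(msg, "constant marker columns are not allowed")
  if (length(object@alleleFreq) != ncol(object@Z)) {
    msg <- c(msg, "alleleFreq must have one entry per marker")
  }
  if (is.null(rownames(object@Z))) msg <- c(msg, "Z must carry genotype ids")
  if (length(msg)) msg else TRUE
})

#' BreedingValues: marker effects and the true breeding values they imply
#'
#' Marker effects \code{u ~ iid N(0, sigma_u^2)}; true breeding values
#' \code{g = Z u} exactly (checked at construction).
#'
#' @slot u marker effects.
#' @slot g true breeding values, named by genotype.
#' @export
setClass("BreedingValues",
  representation(u = "numeric", g = "numeric")
)

#' TrialData: one simulated alpha-design field trial
#'
#' Plot records plus every stochastic component used to generate them, so
#' the plot-model identity
#' \code{yield = mu + gamma[rep] + b[block] + g[genotype] + e[plot]}
#' is checkable record by record. A contaminated copy differs from its
#' uncontaminated twin in exactly one yield, by exactly \code{k * errorSD}.
#'
#' @slot records data.frame with columns genotype, replicate, block, plot,
#'   yield.
#' @slot mu general mean.
#' @slot gamma fixed replicate effects (one per replicate).
#' @slot blockEffects data.frame with columns replicate, block, effect.
#' @slot plotErrors residual plot errors, aligned with \code{records}.
#' @slot truth \linkS4class{BreedingValues} used to generate the yields.
#' @slot outlier empty list, or \code{list(record =, shift =)} for a
#'   contaminated trial.
#' @export
setClass("TrialData",
  representation(
    records = "data.frame",
    mu = "numeric",
    gamma = "numeric",
    blockEffects = "data.frame",
    plotErrors = "numeric",
    truth = "BreedingValues",
    outlier = "list"
  )
)

setValidity("TrialData", function(object) {
  msg <- character()
  rec <- object@records
  need <- c("genotype", "replicate", "block", "plot", "yield")
  if (!all(need %in% names(rec))) {
    return(paste("records must have columns", paste(need, collapse = ", ")))
  }
  tab <- table(rec$genotype, rec$replicate)
  if (any(tab != 1L)) {
    msg <- c(msg, "each genotype must appear exactly once per replicate")
  }
  ## reconstruct yields when generating components are stored
  if (length(object@plotErrors) == nrow(rec) && length(object@truth@g)) {
    be <- object@blockEffects
    bkey <- paste(be$replicate, be$block)
    b <- be$effect[match(paste(rec$replicate, rec$block), bkey)]
    y <- object@mu + object@gamma[rec$replicate] + b +
      object@truth@g[rec$genotype] + object@plotErrors
    if (length(object@outlier)) {
      y[object@outlier$record] <- y[object@outlier$record] +
        object@outlier$shift
    }
    if (!isTRUE(all.equal(unname(y), rec$yield, tolerance = 1e-10))) {
      msg <- c(msg, "stored yields do not reconstruct from stored components")
    }
  }
  if (length(msg)) msg else TRUE
})

#' AdjustedMeans: stage-1 genotype means and their precision
#'
#' Adjusted (BLUE) genotype means from the plot model with genotype and
#' replicate fixed and incomplete blocks random, together with their full
#' variance-covariance matrix, the stage-1 variance components, and the
#' mean variance of a difference of two adjusted means (vbar).
#'
#' @slot p named vector of adjusted means.
#' @slot vcov variance matrix of the means.
#' @slot sigma2Block REML block variance.
#' @slot sigma2Residual REML plot-error variance.
#' @slot vbar mean variance of a difference of two adjusted means.
#' @slot converged logical.
#' @export
setClass("AdjustedMeans",
  representation(
    p = "numeric",
    vcov = "matrix",
    sigma2Block = "numeric",
    sigma2Residual = "numeric",
    vbar = "numeric",
    converged = "logical"
  )
)

setValidity("AdjustedMeans", function(object) {
  msg <- character()
  n <- length(object@p)
  if (!all(dim(object@vcov) == n)) {
    msg <- c(msg, "vcov must be n x n for n means")
  }
  if (n > 1 && !isTRUE(all.equal(object@vcov, t(object@vcov),
                                 tolerance = 1e-8))) {
    msg <- c(msg, "vcov must be symmetric")
  }
  if (length(msg)) msg else TRUE
})

#' RemlFit: a fitted two-variance-component mixed model
#'
#' Result of profiled REML for \code{Var(y) = sigma1^2 M + sigmaE^2 I}
#' where \code{M = Z Z'} (incidence of iid effects) or a genomic covariance
#' \code{K}. Boundary solutions (sigma1^2 = 0) are returned with
#' \code{boundary = TRUE}; failures set \code{converged = FALSE} instead of
#' raising, so non-convergence can be counted.
#'
#' @slot sigma2Random variance of the random term (sigma_u^2 or sigma_b^2).
#' @slot sigma2Residual residual variance.
#' @slot delta fitted variance ratio sigma2Random / sigma2Residual.
#' @slot boundary TRUE when the random variance is at the zero boundary.
#' @slot converged logical.
#' @slot logLik restricted log-likelihood at the optimum.
#' @slot beta fixed-effect estimates.
#' @slot betaVcov their variance matrix.
#' @slot blup predicted random effects.
#' @slot pev prediction-error variance matrix of \code{blup} (may be 0 x 0
#'   when not requested).
#' @slot vbarBlue mean variance of a difference of two adjusted means
#'   (filled by the stage that owns the BLUEs; NA otherwise).
#' @slot vbarBlup mean variance of a difference of two BLUPs.
#' @slot nobs number of observations.
#' @export
setClass("RemlFit",
  representation(
    sigma2Random = "numeric",
    sigma2Residual = "numeric",
    delta = "numeric",
    boundary = "logical",
    converged = "logical",
    logLik = "numeric",
    beta = "numeric",
    betaVcov = "matrix",
    blup = "numeric",
    pev = "matrix",
    vbarBlue = "numeric",
    vbarBlup = "numeric",
    nobs = "integer"
  )
)

#' PlotModelFit: REML fit of the plot model with independent genotypes
#'
#' The alpha-design plot model with fixed replicates, random incomplete
#' blocks and iid random genotype effects. This is the fit whose genetic
#' variance feeds the heritability measures that assume independent
#' genotypes (methods 1-3).
#'
#' @slot sigma2Genotype REML genetic variance.
#' @slot sigma2Block REML block variance.
#' @slot sigma2Residual REML plot-error variance.
#' @slot boundaryGenotype TRUE when the genetic variance hit zero.
#' @slot converged logical.
#' @slot blup named genotype BLUPs.
#' @slot pev full PEV matrix of the genotype BLUPs (0 x 0 unless requested).
#' @slot vbarBlup mean variance of a difference of two genotype BLUPs
#'   (NA unless \code{pev} was computed).
#' @slot logLik REML log-likelihood (as reported by the backend).
#' @slot nobs number of plots.
#' @export
setClass("PlotModelFit",
  representation(
    sigma2Genotype = "numeric",
    sigma2Block = "numeric",
    sigma2Residual = "numeric",
    boundaryGenotype = "logical",
    converged = "logical",
    blup = "numeric",
    pev = "matrix",
    vbarBlup = "numeric",
    logLik = "numeric",
    nobs = "integer"
  )
)

#' GenomicModel: covariance structures entering the direct estimators
#'
#' Holds the genotype covariance \code{G} (either \code{Z Z' sigma_u^2} or
#' \code{I sigma_g^2}) and the residual covariance \code{R} of the adjusted
#' means; \code{V = G + R}, the centering operator \code{Pu}, the
#' intercept-sweeping projector \code{Q} and \code{C = G V^{-1} Q} are
#' derived on demand by the estimator functions.
#'
#' @slot G genotype covariance matrix.
#' @slot R residual covariance matrix.
#' @export
setClass("GenomicModel", representation(G = "matrix", R = "matrix"))

setValidity("GenomicModel", function(object) {
  msg <- character()
  if (!all(dim(object@G) == dim(object@R))) {
    msg <- c(msg, "G and R must have identical dimensions")
  }
  if (nrow(object@G) != ncol(object@G)) msg <- c(msg, "G must be square")
  if (!isTRUE(all.equal(object@G, t(object@G), tolerance = 1e-8))) {
    msg <- c(msg, "G must be symmetric")
  }
  if (!isTRUE(all.equal(object@R, t(object@R), tolerance = 1e-8))) {
    msg <- c(msg, "R must be symmetric")
  }
  if (length(msg)) msg else TRUE
})
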