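#' REML fit of the alpha-design plot model with independent genotypes
#'
#' Fits \code{yield ~ replicate (fixed) + block-within-replicate (random) +
#' genotype (random iid) + plot error} by REML. This is the model whose
#' genetic variance, plot-error variance and genotype BLUPs feed the
#' heritability measures that assume independent genotypes (methods 1-3);
#' a zero-boundary genetic variance makes those heritabilities zero and
#' the indirect accuracies incomputable.
#'
#' The fit is delegated to \code{lme4::lmer}. Convergence warnings are
#' captured into the \code{converged} flag rather than raised. Because
#' lme4 only exposes diagonal conditional variances, the full
#' prediction-error variance matrix of the genotype BLUPs (needed for the
#' mean variance of a BLUP difference) is recomputed from the estimated
#' variance components by direct inversion of the marginal covariance.
#'
#' @param trial a \linkS4class{TrialData}.
#' @param computePev compute the full genotype PEV matrix.
#' @return a \linkS4class{PlotModelFit}.
#' @export
fitPlotModel <- function(trial, computePev = FALSE) {
  rec <- trialRecords(trial)
  geno <- sort(unique(rec$genotype))
  dat <- data.frame(
    y = rec$yield,
    genotype = factor(rec$genotype, levels = geno),
    replicate = factor(rec$replicate),
    blockId = factor(paste(rec$replicate, rec$block, sep = ":"))
  )
  conv <- TRUE
  fit <- withCallingHandlers(
    tryCatch(
      lme4::lmer(y ~ replicate + (1 | blockId) + (1 | genotype),
                 data = dat, REML = TRUE,
                 control = lme4::lmerControl(calc.derivs = FALSE,
                                             check.conv.singular = "ignore")),
      error = function(e) NULL),
    warning = function(w) {
      conv <<- FALSE
      invokeRestart("muffleWarning")
    })
  if (is.null(fit)) {
    return(new("PlotModelFit", sigma2Genotype = NA_real_,
               sigma2Block = NA_real_, sigma2Residual = NA_real_,
               boundaryGenotype = FALSE, converged = FALSE,
               blup = numeric(), pev = matrix(numeric(), 0L, 0L),
               vbarBlup = NA_real_, logLik = NA_real_,
               nobs = nrow(rec)))
  }
  if (!is.null(fit@optinfo$conv$opt) && fit@optinfo$conv$opt != 0) conv <- FALSE
  vc <- as.data.frame(lme4::VarCorr(fit))
  s2g <- vc$vcov[vc$grp == "genotype"]
  s2b <- vc$vcov[vc$grp == "blockId"]
  s2e <- vc$vcov[vc$grp == "Residual"]
  boundary <- s2g <= 1e-8 * s2e
  gblup <- lme4::ranef(fit)$genotype[, 1L]
  names(gblup) <- rownames(lme4::ranef(fit)$genotype)
  gblup <- gblup[geno]
  pevM <- matrix(numeric(), 0L, 0L)
  vbarB <- NA_real_
  if (computePev) {
    pevM <- plotModelPev(dat, geno, s2g, s2b, s2e)
    vbarB <- meanVarianceDifference(pevM)
  }
  new("PlotModelFit", sigma2Genotype = s2g, sigma2Block = s2b,
      sigma2Residual = s2e, boundaryGenotype = boundary, converged = conv,
      blup = gblup, pev = pevM, vbarBlup = vbarB,
      logLik = as.numeric(stats::logLik(fit)), nobs = nrow(dat))
}

## full PEV matrix of genotype BLUPs at given variance components:
## PEV = G - G Zg' P Zg G with P the REML projection of the marginal model
plotModelPev <- function(dat, geno, s2g, s2b, s2e) {
  n <- nrow(dat)
  Zg <- stats::model.matrix(~ 0 + genotype, dat)
  Zb <- stats::model.matrix(~ 0 + blockId, dat)
  X <- stats::model.matrix(~ replicate, dat)
  V <- s2g * tcrossprod(Zg) + s2b * tcrossprod(Zb) + diag(s2e, n)
  Vi <- chol2inv(chol(V))
  ViX <- Vi %*% X
  Ai <- solve(crossprod(X, ViX))
  P <- Vi - ViX %*% Ai %*% t(ViX)
  m <- length(geno)
  ZtPZ <- crossprod(Zg, P %*% Zg)
  symm(diag(s2g, m) - s2g^2 * ZtPZ)
}

#' Stage 1: adjusted genotype means from plot data
#'
#' Fits the plot model with genotype and replicate fixed and incomplete
#' blocks random (REML), and returns the genotype BLUEs ("adjusted means"),
#' their full variance matrix, the stage-1 variance components and the mean
#' variance of a difference of two adjusted means.
#'
#' @param trial a \linkS4class{TrialData}.
#' @param control REML control, see \code{\link{remlControl}}.
#' @return an \linkS4class{AdjustedMeans}.
#' @export
stage1AdjustedMeans <- function(trial, control = remlControl()) {
  rec <- trialRecords(trial)
  geno <- sort(unique(rec$genotype))
  n <- length(geno)
  dat <- data.frame(
    genotype = factor(rec$genotype, levels = geno),
    replicate = factor(rec$replicate),
    blockId = factor(paste(rec$replicate, rec$block, sep = ":"))
  )
  X <- stats::model.matrix(~ 0 + genotype + replicate, dat)
  Zb <- stats::model.matrix(~ 0 + blockId, dat)
  fit <- remlFit(rec$yield, X, Z = Zb, computePev = FALSE, control = control)
  if (!converged(fit)) {
    return(new("AdjustedMeans", p = stats::setNames(rep(NA_real_, n), geno),
               vcov = matrix(NA_real_, n, n), sigma2Block = NA_real_,
               sigma2Residual = NA_real_, vbar = NA_real_,
               converged = FALSE))
  }
  idx <- seq_len(n)
  repCoef <- fit@beta[-idx]
  ## report means at the average replicate level
  p <- fit@beta[idx] + sum(repCoef) / nlevels(dat$replicate)
  names(p) <- geno
  vcovP <- fit@betaVcov[idx, idx, drop = FALSE]
  dimnames(vcovP) <- list(geno, geno)
  new("AdjustedMeans", p = p, vcov = vcovP,
      sigma2Block = fit@sigma2Random, sigma2Residual = fit@sigma2Residual,
      vbar = meanVarianceDifference(vcovP), converged = TRUE)
}

#' Stage 2: genomic (or independent-genotype) fit to adjusted means
#'
#' Fits \code{p = phi + g + e} with the genotype covariance either genomic
#' (\code{Var(g) = Z Z' sigma_u^2}) or independent
#' (\code{Var(g) = I sigma_g^2}). Weighting modes: \code{"simple"}
#' estimates an iid residual variance alongside the genetic variance
#' (identifiable only for the genomic structure); \code{"vcov"} carries the
#' stage-1 variance matrix of the adjusted means forward as the fixed
#' residual covariance and estimates the genetic variance alone, which is
#' the only identifiable variant for the independent structure and is its
#' default.
#'
#' @param am an \linkS4class{AdjustedMeans}.
#' @param structure \code{"genomic"} or \code{"independent"}.
#' @param markers a \linkS4class{MarkerMatrix} (genomic structure).
#' @param K optional precomputed \code{Z Z'} (overrides \code{markers}).
#' @param Keig optional precomputed \code{eigen(K, symmetric = TRUE)}.
#' @param weighting \code{"simple"} or \code{"vcov"}; see Details.
#' @param computePev compute the BLUP prediction-error variance matrix.
#' @param control REML control.
#' @return a \linkS4class{RemlFit}; for the genomic structure
#'   \code{sigma2Random} is the marker-effect variance sigma_u^2 on the
#'   \code{Z Z'} scale.
#' @export
stage2Fit <- function(am, structure = c("genomic", "independent"),
                      markers = NULL, K = NULL, Keig = NULL,
                      weighting = NULL, computePev = TRUE,
                      control = remlControl()) {
  structure <- match.arg(structure)
  if (!converged(am)) stop("stage 1 did not converge")
  p <- adjustedMeans(am)
  n <- length(p)
  X <- matrix(1, n, 1L)
  if (structure == "genomic") {
    if (is.null(weighting)) weighting <- "simple"
    if (is.null(K) && is.null(Keig)) {
      if (is.null(markers)) stop("genomic structure needs markers or K")
      K <- tcrossprod(markerCodes(markers))
    }
  } else {
    if (is.null(weighting)) weighting <- "vcov"
    if (weighting == "simple") {
      stop("independent structure with an estimated iid residual is not ",
           "identifiable from one mean per genotype; use weighting = \"vcov\"")
    }
    K <- diag(n)
  }
  fit <- if (weighting == "vcov") {
    remlFitFixedR(p, X, K, meansVcov(am), control = control)
  } else {
    remlFit(p, X, K = K, Keig = Keig, computePev = computePev,
            control = control)
  }
  if (converged(fit) && !is.na(fit@sigma2Residual)) {
    ## fixed-genotype analogue: one mean per genotype, iid residual
    fit@vbarBlue <- 2 * fit@sigma2Residual
  }
  if (length(fit@blup)) names(fit@blup) <- names(p)
  fit
}
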