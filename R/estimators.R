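#' Construct the covariance model behind the direct estimators
#'
#' @param G genotype covariance matrix (\code{Z Z' sigma_u^2} or
#'   \code{I sigma_g^2}).
#' @param R residual covariance matrix (scalar shorthand allowed).
#' @return a \linkS4class{GenomicModel}.
#' @export
#' @examples
#' genomicModel(diag(4) * 2, 1)
genomicModel <- function(G, R) {
  G <- as.matrix(G)
  if (length(R) == 1L) R <- diag(as.numeric(R), nrow(G))
  new("GenomicModel", G = as.matrix(G), R = as.matrix(R))
}

#' Simulated true predictive accuracy
#'
#' Sample Pearson correlation between true and predicted breeding values,
#' the benchmark every estimator is judged against. Undefined (NA) when
#' either vector is constant.
#'
#' @param g true breeding values.
#' @param ghat predicted breeding values.
#' @return correlation in [-1, 1], or NA.
#' @export
trueAccuracy <- function(g, ghat) {
  if (length(g) != length(ghat)) stop("g and ghat must have equal length")
  safeCor(g, ghat)
}

#' Predictive ability
#'
#' Sample Pearson correlation between predicted breeding values and
#' observed phenotypes (adjusted means).
#'
#' @param ghat predicted breeding values.
#' @param p phenotypes.
#' @return correlation, or NA when either side is constant.
#' @export
predictiveAbility <- function(ghat, p) {
  if (length(ghat) != length(p)) stop("ghat and p must have equal length")
  safeCor(ghat, p)
}

#' Heritability, method 1: plot-variance ratio
#'
#' \code{H^2 = sigmaG2 / (sigmaG2 + sigmaE2 / r)}, the plant-breeding
#' standard for replicated trials.
#'
#' @param sigmaG2 genetic variance.
#' @param sigmaE2 plot-error variance.
#' @param r number of replicates.
#' @return heritability in [0, 1].
#' @export
heritabilityM1 <- function(sigmaG2, sigmaE2, r) {
  if (sigmaG2 < 0 || sigmaE2 < 0) stop("variances must be >= 0")
  if (sigmaG2 == 0 && sigmaE2 == 0) stop("both variances are zero")
  if (r < 1) stop("r must be >= 1")
  sigmaG2 / (sigmaG2 + sigmaE2 / r)
}

#' Heritability, method 2: BLUE-based ad hoc measure
#'
#' \code{H^2 = sigmaG2 / (sigmaG2 + vbar / 2)} with \code{vbar} the mean
#' variance of a difference of two adjusted genotype means. Reduces to
#' method 1 on balanced complete-block data, where \code{vbar = 2 sigmaE2 / r}.
#'
#' @param sigmaG2 genetic variance.
#' @param vbar mean variance of a difference of two adjusted means.
#' @return heritability in [0, 1].
#' @export
heritabilityM2 <- function(sigmaG2, vbar) {
  if (sigmaG2 < 0 || vbar < 0) stop("inputs must be >= 0")
  if (sigmaG2 == 0 && vbar == 0) stop("both inputs are zero")
  sigmaG2 / (sigmaG2 + vbar / 2)
}

#' Heritability, method 3: BLUP-based ad hoc measure
#'
#' \code{H^2 = 1 - vbarBlup / (2 sigmaG2)} with \code{vbarBlup} the mean
#' variance of a difference of two genotype BLUPs. The formula admits
#' negative values, which are returned as-is (flagging is the caller's
#' job); a zero genetic variance leaves it undefined.
#'
#' @param sigmaG2 genetic variance (> 0).
#' @param vbarBlup mean variance of a BLUP difference.
#' @return heritability, possibly negative.
#' @export
heritabilityM3 <- function(sigmaG2, vbarBlup) {
  if (vbarBlup < 0) stop("vbarBlup must be >= 0")
  if (sigmaG2 <= 0) stop("sigmaG2 must be > 0 (zero-heritability case)")
  1 - vbarBlup / (2 * sigmaG2)
}

#' Heritability, method 4: expected-variance ratio
#'
#' \code{H^2 = trace(Pu G) / trace(V Pu)} with
#' \code{trace(V Pu) = trace(Pu G) + trace(R Pu)}: the expected genetic
#' sample variance over the expected phenotypic sample variance under the
#' genomic covariance model.
#'
#' @param model a \linkS4class{GenomicModel}.
#' @return heritability in [0, 1].
#' @export
heritabilityM4 <- function(model) {
  eg <- puTrace(model@G)
  ep <- eg + puTrace(model@R)
  if (ep <= 0) stop("expected phenotypic variance is zero")
  eg / ep
}

#' Accuracy (and heritability), method 5: expected-correlation measure
#'
#' \code{H_m5 = trace(Pu C G) / sqrt(trace(Pu G) trace(C' Pu C V))} with
#' \code{V = G + R}, \code{Q = I - 1 (1' V^{-1} 1)^{-1} 1' V^{-1}} and
#' \code{C = G V^{-1} Q}: the model-expected correlation between true and
#' predicted breeding values, which directly defines both the predictive
#' accuracy (\code{H_m5}) and the heritability (\code{H_m5^2}). Equals
#' \code{sqrt(g / (g + e))} for isotropic \code{G = gI}, \code{R = eI},
#' and 1 when \code{R = 0}.
#'
#' @param model a \linkS4class{GenomicModel} with invertible \code{V}.
#' @return accuracy in (0, 1] for positive-definite inputs.
#' @export
accuracyM5 <- function(model) {
  G <- model@G
  V <- G + model@R
  n <- nrow(G)
  Vi <- tryCatch(chol2inv(chol(V)), error = function(e) NULL)
  if (is.null(Vi)) stop("V = G + R is singular")
  trPuG <- puTrace(G)
  if (trPuG <= 0) stop("trace(Pu G) must be > 0")
  w <- drop(Vi %*% rep(1, n))
  A <- G %*% Vi
  C <- A - outer(drop(A %*% rep(1, n)), w) / sum(w)   # C = G V^{-1} Q
  num <- puTrace(C %*% G)
  den <- trPuG * puTrace(C %*% V %*% t(C))            # tr(C' Pu C V)
  num / sqrt(den)
}

#' Accuracy, method 6: regression on the expected genetic variance
#'
#' \code{r = s_(ghat,p) / sqrt(s_ghat^2 E(s_g^2))} with
#' \code{E(s_g^2) = trace(Pu G)} from the fitted genomic covariance. Can
#' overshoot 1 when the plug-in expected genetic variance underestimates
#' the realized one.
#'
#' @param ghat predicted breeding values (cross-validated).
#' @param p phenotypes (adjusted means).
#' @param model a \linkS4class{GenomicModel} (or NULL with
#'   \code{expectedSg2} supplied).
#' @param expectedSg2 optional direct value of \code{E(s_g^2)}.
#' @return accuracy estimate, or NA when incomputable.
#' @export
accuracyM6 <- function(ghat, p, model = NULL, expectedSg2 = NULL) {
  if (is.null(expectedSg2)) expectedSg2 <- puTrace(model@G)
  if (anyNA(ghat) || anyNA(p)) return(NA_real_)
  vg <- stats::var(ghat)
  if (!is.finite(vg) || vg <= 0 || expectedSg2 <= 0) return(NA_real_)
  stats::cov(ghat, p) / sqrt(vg * expectedSg2)
}

#' Accuracy, method 7: mean reliability from the mixed-model equations
#'
#' Per-genotype reliability \code{rho_i^2 = (G_ii - PEV_ii) / G_ii}, using
#' the BLUP identity \code{cov(g_i, ghat_i) = var(ghat_i) = G_ii - PEV_ii};
#' the accuracy is the square root of the mean reliability. Diagonal PEV
#' values exceeding \code{G_ii} (numerical) are clipped to the [0, 1]
#' reliability range.
#'
#' @param fit a \linkS4class{RemlFit} with its PEV matrix, or a PEV matrix.
#' @param model a \linkS4class{GenomicModel} fitted to the same data.
#' @return accuracy in [0, 1].
#' @export
accuracyM7 <- function(fit, model) {
  pevD <- if (is(fit, "RemlFit")) diag(pev(fit)) else diag(as.matrix(fit))
  gD <- diag(model@G)
  if (any(gD <= 0)) stop("diag(G) must be > 0")
  rho2 <- pmin(pmax((gD - pevD) / gD, 0), 1)
  sqrt(mean(rho2))
}

#' Indirect predictive accuracy
#'
#' \code{r_acc = r_(ghat,p) / sqrt(H2)}: cross-validated predictive ability
#' divided by the square root of an estimated heritability (methods 1-4).
#' Returns NA when the heritability is zero or negative (the
#' zero-heritability failure mode) or the ability itself is NA; values
#' outside [0, 1] are legitimate outputs and are flagged downstream as
#' undershoot/overshoot.
#'
#' @param rGhatP predictive ability.
#' @param H2 heritability estimate.
#' @return accuracy estimate, or NA.
#' @export
#' @examples
#' indirectAccuracy(0.4, 0.64)  # 0.5
indirectAccuracy <- function(rGhatP, H2) {
  if (is.na(H2) || H2 <= 0 || is.na(rGhatP)) return(NA_real_)
  rGhatP / sqrt(H2)
}
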