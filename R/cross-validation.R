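#' Build replicated k-fold partitions of the genotypes
#'
#' Five independent random three-fold partitions by default, giving the 15
#' training/validation splits used for cross-validated predictive ability.
#' Fold sizes differ by at most one genotype.
#'
#' @param n number of genotypes.
#' @param k folds per replicate.
#' @param reps independent replicates.
#' @param seed integer seed.
#' @return list of length \code{reps}; each element an integer vector of
#'   fold labels (1..k) per genotype.
#' @export
#' @examples
#' plan <- makeCvFolds(177L, seed = 1L)
#' table(plan[[1]])
makeCvFolds <- function(n, k = 3L, reps = 5L, seed = 1L) {
  if (n < k) stop("need at least k genotypes")
  set.seed(seed)
  lapply(seq_len(reps), function(r) {
    sample(rep_len(seq_len(k), n))
  })
}

#' Cross-validated genomic predictions
#'
#' For every replicate and fold, refits the genomic model
#' \code{p = phi + g + e}, \code{Var(g) = Z Z' sigma_u^2}, by REML on the
#' training genotypes and predicts the held-out ones as
#' \code{ghat_val = G_vt V_tt^{-1} (p_train - phi_hat)}. Each genotype
#' receives exactly one held-out prediction per replicate. Training fits
#' whose genetic variance hits the zero boundary yield constant (zero)
#' predictions and flag the replicate; non-convergent fits flag it too.
#'
#' @param am stage-1 \linkS4class{AdjustedMeans}.
#' @param markers \linkS4class{MarkerMatrix} (or supply \code{K}).
#' @param plan fold plan from \code{\link{makeCvFolds}}.
#' @param K optional precomputed \code{Z Z'}.
#' @param control REML control.
#' @return list with \code{predictions} (n x reps matrix),
#'   \code{zeroVariance} and \code{nonconverged} (logical per replicate).
#' @export
cvPredict <- function(am, markers = NULL, plan, K = NULL,
                      control = remlControl()) {
  p <- adjustedMeans(am)
  n <- length(p)
  if (is.null(K)) K <- tcrossprod(markerCodes(markers))
  reps <- length(plan)
  preds <- matrix(NA_real_, n, reps, dimnames = list(names(p), NULL))
  zeroVar <- logical(reps)
  nonconv <- logical(reps)
  for (r in seq_len(reps)) {
    folds <- plan[[r]]
    for (f in sort(unique(folds))) {
      val <- which(folds == f)
      trn <- which(folds != f)
      fit <- remlFit(p[trn], matrix(1, length(trn), 1L), K = K[trn, trn],
                     computePev = FALSE, control = control)
      if (!converged(fit)) {
        nonconv[r] <- TRUE
        next
      }
      if (isBoundary(fit) || fit@sigma2Random <= 0) {
        zeroVar[r] <- TRUE
        preds[val, r] <- 0
        next
      }
      su2 <- fit@sigma2Random
      Vtt <- su2 * K[trn, trn] + diag(fit@sigma2Residual, length(trn))
      resid <- p[trn] - fit@beta[1L]
      preds[val, r] <- drop(su2 * K[val, trn, drop = FALSE] %*%
                              solve(Vtt, resid))
    }
  }
  list(predictions = preds, zeroVariance = zeroVar, nonconverged = nonconv)
}

#' Cross-validated predictive ability
#'
#' Pearson correlation between held-out predictions and adjusted means,
#' computed per cross-validation replicate over all genotypes and averaged
#' over the computable replicates. A replicate is incomputable when any of
#' its training fits failed, its predictions are constant (zero genetic
#' variance) or contain NA.
#'
#' @param cv result of \code{\link{cvPredict}}.
#' @param p adjusted means (named as the prediction rows).
#' @return list with \code{ability} (mean over computable replicates, NA if
#'   none), \code{perReplicate}, and \code{nIncomputable}.
#' @export
cvPredictiveAbility <- function(cv, p) {
  preds <- cv$predictions
  reps <- ncol(preds)
  perRep <- rep(NA_real_, reps)
  for (r in seq_len(reps)) {
    if (cv$nonconverged[r] || cv$zeroVariance[r]) next
    perRep[r] <- predictiveAbility(preds[, r], p)
  }
  ok <- !is.na(perRep)
  list(ability = if (any(ok)) mean(perRep[ok]) else NA_real_,
       perReplicate = perRep,
       nIncomputable = sum(!ok))
}
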