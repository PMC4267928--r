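#' Analyze one simulated trial with all seven methods
#'
#' Runs the full analysis chain on one dataset: stage-1 adjusted means,
#' the independent-genotype plot-model REML fit (methods 1-3), the genomic
#' stage-2 fit (methods 4-7), replicated three-fold cross-validation
#' (predictive ability for the indirect methods and method 6), and all
#' heritability and accuracy estimators. Failures are recorded in flags,
#' never raised.
#'
#' @param trial a \linkS4class{TrialData}.
#' @param markers the scenario's \linkS4class{MarkerMatrix} (or supply
#'   \code{K}/\code{Keig}).
#' @param cvSeed seed of the fold plan.
#' @param K optional precomputed \code{Z Z'}.
#' @param Keig optional precomputed \code{eigen(K, symmetric = TRUE)}.
#' @param cvReps,cvFolds cross-validation layout.
#' @param control REML control.
#' @return list with \code{row} (one-row data.frame of estimates and
#'   flags) and \code{gBlup} (full-data genomic BLUPs, for benchmarking).
#' @export
analyzeDataset <- function(trial, markers = NULL, cvSeed = 1L, K = NULL,
                           Keig = NULL, cvReps = 5L, cvFolds = 3L,
                           control = remlControl()) {
  rec <- trialRecords(trial)
  r <- max(rec$replicate)
  if (is.null(K) && is.null(Keig)) K <- tcrossprod(markerCodes(markers))
  if (is.null(K)) stop("need K when only Keig is given")
  n <- nrow(K)

  row <- data.frame(
    convStage1 = FALSE, convPlot = FALSE, convGen = FALSE,
    sg2Plot = NA_real_, se2Plot = NA_real_, sb2Plot = NA_real_,
    boundaryPlot = FALSE, su2Gen = NA_real_, se2Gen = NA_real_,
    boundaryGen = FALSE, vbar = NA_real_, vbarBlupPlot = NA_real_,
    h2m1 = NA_real_, h2m2 = NA_real_, h2m3 = NA_real_, h2m4 = NA_real_,
    h2m5 = NA_real_, rGhatP = NA_real_, nCvBad = 0L,
    cvAnyZeroVar = FALSE, cvAllBad = FALSE,
    accm1 = NA_real_, accm2 = NA_real_, accm3 = NA_real_, accm4 = NA_real_,
    accm5 = NA_real_, accm6 = NA_real_, accm7 = NA_real_)
  gBlup <- NULL

  am <- stage1AdjustedMeans(trial, control = control)
  row$convStage1 <- converged(am)

  plotFit <- fitPlotModel(trial, computePev = TRUE)
  row$convPlot <- converged(plotFit)
  if (converged(plotFit)) {
    vcp <- varComp(plotFit)
    row$sg2Plot <- vcp[["genotype"]]
    row$sb2Plot <- vcp[["block"]]
    row$se2Plot <- vcp[["residual"]]
    row$boundaryPlot <- isBoundary(plotFit)
    row$vbarBlupPlot <- plotFit@vbarBlup
  }

  if (!converged(am)) {
    return(list(row = row, gBlup = gBlup))
  }
  p <- adjustedMeans(am)
  row$vbar <- am@vbar

  ## heritabilities assuming independent genotypes (plot model)
  if (converged(plotFit)) {
    sg2 <- row$sg2Plot
    row$h2m1 <- sg2 / (sg2 + row$se2Plot / r)
    row$h2m2 <- sg2 / (sg2 + row$vbar / 2)
    row$h2m3 <- if (sg2 > 0) heritabilityM3(sg2, row$vbarBlupPlot) else NA_real_
  }

  ## genomic stage-2 fit (methods 4-7)
  genFit <- tryCatch(
    stage2Fit(am, "genomic", K = K, Keig = Keig, computePev = TRUE,
              control = control),
    error = function(e) NULL)
  model <- NULL
  if (!is.null(genFit) && converged(genFit)) {
    row$convGen <- TRUE
    row$su2Gen <- genFit@sigma2Random
    row$se2Gen <- genFit@sigma2Residual
    row$boundaryGen <- isBoundary(genFit)
    gBlup <- blup(genFit)
    model <- genomicModel(genFit@sigma2Random * K,
                          diag(genFit@sigma2Residual, n))
    row$h2m4 <- heritabilityM4(model)
    if (!row$boundaryGen && genFit@sigma2Random > 0) {
      m5 <- tryCatch(accuracyM5(model), error = function(e) NA_real_)
      row$accm5 <- m5
      row$h2m5 <- m5^2
      row$accm7 <- tryCatch(accuracyM7(genFit, model),
                            error = function(e) NA_real_)
    }
  }

  ## cross-validated predictive ability (methods 1-4, 6)
  plan <- makeCvFolds(n, k = cvFolds, reps = cvReps, seed = cvSeed)
  cv <- cvPredict(am, plan = plan, K = K, control = control)
  pa <- cvPredictiveAbility(cv, p)
  row$rGhatP <- pa$ability
  row$nCvBad <- pa$nIncomputable
  row$cvAnyZeroVar <- any(cv$zeroVariance)
  row$cvAllBad <- is.na(pa$ability)

  row$accm1 <- indirectAccuracy(row$rGhatP, row$h2m1)
  row$accm2 <- indirectAccuracy(row$rGhatP, row$h2m2)
  row$accm3 <- indirectAccuracy(row$rGhatP, row$h2m3)
  row$accm4 <- indirectAccuracy(row$rGhatP, row$h2m4)

  if (!is.null(model)) {
    esg2 <- puTrace(model@G)
    if (esg2 > 0) {
      m6rep <- rep(NA_real_, length(plan))
      for (ri in seq_along(plan)) {
        if (cv$nonconverged[ri] || cv$zeroVariance[ri]) next
        m6rep[ri] <- accuracyM6(cv$predictions[, ri], p, expectedSg2 = esg2)
      }
      if (any(!is.na(m6rep))) row$accm6 <- mean(m6rep, na.rm = TRUE)
    }
  }
  list(row = row, gBlup = gBlup)
}

## exact variance matrix of the stage-1 genotype BLUEs at given (true)
## variance components; the benchmark heritability's residual covariance
trueMeansVcov <- function(design, sigmaB2, sigmaE2) {
  geno <- sort(unique(design$genotype))
  dat <- data.frame(
    genotype = factor(design$genotype, levels = geno),
    replicate = factor(design$replicate),
    blockId = factor(paste(design$replicate, design$block, sep = ":"))
  )
  X <- stats::model.matrix(~ 0 + genotype + replicate, dat)
  Zb <- stats::model.matrix(~ 0 + blockId, dat)
  n <- nrow(X)
  V <- sigmaB2 * tcrossprod(Zb) + diag(sigmaE2, n)
  A <- crossprod(X, solve(V, X))
  Ai <- solve(A)
  idx <- seq_along(geno)
  out <- Ai[idx, idx, drop = FALSE]
  dimnames(out) <- list(geno, geno)
  symm(out)
}

#' Run one scenario (or a group of scenarios sharing base data)
#'
#' Simulates \code{nDatasets} paired datasets and analyzes the clean and
#' contaminated twin of each. Scenarios that differ only in the outlier
#' multiplier share every random draw (marker panel, marker effects,
#' design, block and plot noise, outlier position), so the paired
#' deviations isolate the outlier effect; this sharing is keyed on the
#' scenario's content, not its position in a list.
#'
#' @param config a \linkS4class{ScenarioConfig}.
#' @param nDatasets number of datasets (default from the config).
#' @param seed master seed (default from the config).
#' @param cvReps,cvFolds cross-validation layout.
#' @param verbose print progress every 25 datasets.
#' @return data.frame with two rows (conditions \code{"clean"} and
#'   \code{"outlier"}) per dataset: benchmark true accuracy and
#'   heritability, all method estimates, and flags.
#' @export
runScenario <- function(config, nDatasets = config@nDatasets,
                        seed = config@seed, cvReps = 5L, cvFolds = 3L,
                        verbose = FALSE) {
  runStudy(list(config), nDatasets = nDatasets, seed = seed,
           cvReps = cvReps, cvFolds = cvFolds, verbose = verbose)
}

#' Run a study over several scenarios
#'
#' Groups the scenarios by shared base data (same sizes and variances,
#' different outlier multiplier), simulates each group's datasets once,
#' analyzes the clean version once per dataset, and contaminates it once
#' per scenario in the group.
#'
#' @param configs list of \linkS4class{ScenarioConfig} objects.
#' @param nDatasets,seed overrides applied to every scenario (NULL keeps
#'   each config's own values).
#' @param cvReps,cvFolds cross-validation layout.
#' @param verbose print progress.
#' @return combined results data.frame, one clean and one outlier row per
#'   scenario and dataset.
#' @export
runStudy <- function(configs, nDatasets = NULL, seed = NULL,
                     cvReps = 5L, cvFolds = 3L, verbose = FALSE) {
  keys <- vapply(configs, baseKey, character(1))
  out <- list()
  for (key in unique(keys)) {
    grp <- configs[keys == key]
    cfg <- grp[[1L]]
    nd <- if (is.null(nDatasets)) cfg@nDatasets else as.integer(nDatasets)
    sd0 <- if (is.null(seed)) cfg@seed else as.integer(seed)
    ki <- keyToInt(key)
    markers <- simulateMarkerMatrix(cfg@nGenotypes, cfg@nMarkers,
                                    seed = mixSeed(sd0, ki, 1L))
    K <- tcrossprod(markerCodes(markers))
    Keig <- eigen(K, symmetric = TRUE)
    gTrueModelG <- cfg@markerVariance * K

    for (j in seq_len(nd)) {
      truth <- simulateBreedingValues(markers, cfg@markerVariance,
                                      seed = mixSeed(sd0, ki, 2L, j))
      design <- generateAlphaDesign(cfg@nGenotypes, cfg@nReplicates,
                                    cfg@blockSize,
                                    seed = mixSeed(sd0, ki, 3L, j),
                                    genotypes = genotypeIds(markers))
      trial <- simulateTrial(design, truth, mu = 0,
                             gamma = rep(0, cfg@nReplicates),
                             sigmaB2 = cfg@blockVariance,
                             sigmaE2 = cfg@errorVariance,
                             seed = mixSeed(sd0, ki, 4L, j))
      outSeed <- mixSeed(sd0, ki, 5L, j)
      cvSeed <- mixSeed(sd0, ki, 6L, j)

      clean <- analyzeDataset(trial, cvSeed = cvSeed, K = K, Keig = Keig,
                              cvReps = cvReps, cvFolds = cvFolds)
      g <- breedingValues(trial)
      trueAcc <- if (is.null(clean$gBlup)) NA_real_ else
        trueAccuracy(unname(g[names(clean$gBlup)]), unname(clean$gBlup))
      Rtrue <- trueMeansVcov(design, cfg@blockVariance, cfg@errorVariance)
      trueH2 <- heritabilityM4(genomicModel(gTrueModelG, Rtrue))

      for (cf in grp) {
        cont <- if (cf@outlierMultiplier > 0) {
          contTrial <- injectOutlier(trial, cf@outlierMultiplier,
                                     cf@errorSD, seed = outSeed)
          analyzeDataset(contTrial, cvSeed = cvSeed, K = K, Keig = Keig,
                         cvReps = cvReps, cvFolds = cvFolds)
        } else clean
        base <- data.frame(scenario = cf@scenarioId, dataset = j,
                           trueAcc = trueAcc, trueH2 = trueH2)
        out[[length(out) + 1L]] <- cbind(
          rbind(cbind(base, condition = "clean", clean$row),
                cbind(base, condition = "outlier", cont$row)))
      }
      if (verbose && j %% 25L == 0L) {
        message("group ", key, ": dataset ", j, "/", nd)
      }
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[order(res$scenario, res$dataset, res$condition), ]
}

#' Mean deviation of estimates from their benchmark
#'
#' \code{MD = mean(estimate - truth)} over pairs where the estimate is
#' computable; \code{SE = sd(deviations) / sqrt(nUsed)}.
#'
#' @param estimates,truths equal-length vectors; NA estimates are excluded
#'   (with the exclusion count reported).
#' @return list with \code{md}, \code{se}, \code{nUsed}, \code{nExcluded}.
#' @export
#' @examples
#' meanDeviation(c(0.8, 0.7), c(0.6, 0.7))
meanDeviation <- function(estimates, truths) {
  if (length(estimates) != length(truths)) stop("length mismatch")
  ok <- !is.na(estimates) & !is.na(truths)
  if (!any(ok)) stop("no computable pairs")
  dev <- estimates[ok] - truths[ok]
  list(md = mean(dev),
       se = if (sum(ok) > 1L) stats::sd(dev) / sqrt(sum(ok)) else NA_real_,
       nUsed = sum(ok), nExcluded = sum(!ok))
}

methodColumn <- function(measure, method) {
  paste0(if (measure == "heritability") "h2m" else "accm", method)
}

#' Count estimator failure modes
#'
#' Undershoot (accuracy < 0), overshoot (accuracy > 1), non-convergence of
#' the mixed models the method needs, zero-heritability boundary (methods
#' 1-4), and zero genetic variance in cross-validation training fits
#' (methods using cross-validation).
#'
#' @param results data.frame from \code{\link{runStudy}}.
#' @param method method number 1-7.
#' @param condition \code{"clean"} or \code{"outlier"}.
#' @return named integer vector of counts.
#' @export
countFlags <- function(results, method, condition = "outlier") {
  d <- results[results$condition == condition, ]
  acc <- d[[methodColumn("accuracy", method)]]
  nonconv <- if (method %in% 1:3) {
    !d$convStage1 | !d$convPlot
  } else {
    !d$convStage1 | !d$convGen
  }
  zeroH <- if (method %in% 1:3) {
    d$convPlot & d$boundaryPlot
  } else if (method == 4L) {
    d$convGen & d$boundaryGen
  } else rep(FALSE, nrow(d))
  zeroGV <- if (method %in% c(1:4, 6L)) d$cvAnyZeroVar else rep(FALSE, nrow(d))
  c(undershoot = sum(acc < 0, na.rm = TRUE),
    overshoot = sum(acc > 1, na.rm = TRUE),
    nonconverged = sum(nonconv, na.rm = TRUE),
    zeroHeritability = sum(zeroH, na.rm = TRUE),
    zeroGeneticVariance = sum(zeroGV, na.rm = TRUE),
    notComputable = sum(is.na(acc)))
}

#' Summarize mean deviations and failure counts
#'
#' One row per scenario, condition, measure (heritability for methods 1-5,
#' accuracy for methods 1-7) and method: the mean deviation from the
#' simulated-truth benchmark, its SE, sample sizes and flag counts, plus
#' quartiles of the deviations.
#'
#' @param results data.frame from \code{\link{runStudy}}.
#' @return summary data.frame.
#' @export
deviationSummary <- function(results) {
  out <- list()
  for (sc in unique(results$scenario)) {
    rs <- results[results$scenario == sc, ]
    for (cond in unique(rs$condition)) {
      d <- rs[rs$condition == cond, ]
      for (measure in c("heritability", "accuracy")) {
        methods <- if (measure == "heritability") 1:5 else 1:7
        truth <- if (measure == "heritability") d$trueH2 else d$trueAcc
        for (m in methods) {
          est <- d[[methodColumn(measure, m)]]
          ok <- !is.na(est) & !is.na(truth)
          if (any(ok)) {
            md <- meanDeviation(est[ok], truth[ok])
            qs <- stats::quantile(est[ok] - truth[ok], c(0.25, 0.5, 0.75),
                                  names = FALSE)
          } else {
            md <- list(md = NA_real_, se = NA_real_, nUsed = 0L,
                       nExcluded = sum(!ok))
            qs <- rep(NA_real_, 3L)
          }
          fl <- countFlags(rs, m, cond)
          out[[length(out) + 1L]] <- data.frame(
            scenario = sc, condition = cond, measure = measure, method = m,
            md = md$md, se = md$se, nUsed = md$nUsed,
            nExcluded = sum(!ok),
            q25 = qs[1L], median = qs[2L], q75 = qs[3L],
            undershoot = fl[["undershoot"]], overshoot = fl[["overshoot"]],
            nonconverged = fl[["nonconverged"]],
            zeroHeritability = fl[["zeroHeritability"]],
            zeroGeneticVariance = fl[["zeroGeneticVariance"]])
        }
      }
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Pairwise method comparison of accuracy deviations
#'
#' For every method pair within a scenario and condition: Pearson
#' correlation of the per-dataset deviations from the benchmark accuracy,
#' and a paired t-test (unadjusted p; apply \code{stats::p.adjust} for a
#' Bonferroni correction if desired) of the difference in deviations,
#' paired by dataset.
#'
#' @param results data.frame from \code{\link{runStudy}}.
#' @param condition \code{"clean"} or \code{"outlier"}.
#' @param minShared minimum number of jointly computable datasets.
#' @return data.frame with one row per scenario and method pair.
#' @export
compareMethods <- function(results, condition = "outlier", minShared = 3L) {
  out <- list()
  for (sc in unique(results$scenario)) {
    d <- results[results$scenario == sc & results$condition == condition, ]
    devs <- sapply(1:7, function(m) d[[methodColumn("accuracy", m)]] - d$trueAcc)
    for (a in 1:6) for (b in (a + 1):7) {
      ok <- !is.na(devs[, a]) & !is.na(devs[, b])
      if (sum(ok) < minShared) next
      da <- devs[ok, a]; db <- devs[ok, b]
      if (isTRUE(all.equal(da, db))) {
        corAB <- 1; tStat <- 0; pVal <- 1; dfT <- sum(ok) - 1
      } else {
        corAB <- safeCor(da, db)
        tt <- tryCatch(stats::t.test(da, db, paired = TRUE),
                       error = function(e) NULL)
        tStat <- if (is.null(tt)) NA_real_ else unname(tt$statistic)
        pVal <- if (is.null(tt)) NA_real_ else tt$p.value
        dfT <- if (is.null(tt)) NA_real_ else unname(tt$parameter)
      }
      out[[length(out) + 1L]] <- data.frame(
        scenario = sc, methodA = a, methodB = b, n = sum(ok),
        correlation = corAB, t = tStat, df = dfT, p = pVal)
    }
  }
  if (!length(out)) stop("insufficient jointly computable datasets")
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
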