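#' Accessors for gpacc classes
#'
#' Small accessor functions in place of direct slot access.
#'
#' @param x a gpacc object.
#' @return the requested component.
#' @name accessors
NULL

#' @rdname accessors
setMethod("nGenotypes", "ScenarioConfig", function(x) x@nGenotypes)
#' @rdname accessors
setMethod("nMarkers", "ScenarioConfig", function(x) x@nMarkers)
#' @rdname accessors
setMethod("nGenotypes", "MarkerMatrix", function(x) nrow(x@Z))
#' @rdname accessors
setMethod("nMarkers", "MarkerMatrix", function(x) ncol(x@Z))
#' @rdname accessors
setMethod("genotypeIds", "MarkerMatrix", function(x) rownames(x@Z))
#' @rdname accessors
setMethod("markerCodes", "MarkerMatrix", function(x) x@Z)
#' @rdname accessors
setMethod("breedingValues", "BreedingValues", function(x) x@g)
#' @rdname accessors
setMethod("breedingValues", "TrialData", function(x) x@truth@g)
#' @rdname accessors
setMethod("trialRecords", "TrialData", function(x) x@records)
#' @rdname accessors
setMethod("adjustedMeans", "AdjustedMeans", function(x) x@p)
#' @rdname accessors
setMethod("meansVcov", "AdjustedMeans", function(x) x@vcov)
#' @rdname accessors
setMethod("converged", "AdjustedMeans", function(x) x@converged)
#' @rdname accessors
setMethod("converged", "RemlFit", function(x) x@converged)
#' @rdname accessors
setMethod("converged", "PlotModelFit", function(x) x@converged)
#' @rdname accessors
setMethod("varComp", "AdjustedMeans", function(x) {
  c(block = x@sigma2Block, residual = x@sigma2Residual)
})
#' @rdname accessors
setMethod("varComp", "RemlFit", function(x) {
  c(random = x@sigma2Random, residual = x@sigma2Residual)
})
#' @rdname accessors
setMethod("varComp", "PlotModelFit", function(x) {
  c(genotype = x@sigma2Genotype, block = x@sigma2Block,
    residual = x@sigma2Residual)
})
#' @rdname accessors
setMethod("blup", "RemlFit", function(x) x@blup)
#' @rdname accessors
setMethod("blup", "PlotModelFit", function(x) x@blup)
#' @rdname accessors
setMethod("pev", "RemlFit", function(x) x@pev)
#' @rdname accessors
setMethod("pev", "PlotModelFit", function(x) x@pev)
#' @rdname accessors
setMethod("isBoundary", "RemlFit", function(x) x@boundary)
#' @rdname accessors
setMethod("isBoundary", "PlotModelFit", function(x) x@boundaryGenotype)

setMethod("show", "ScenarioConfig", function(object) {
  cat("ScenarioConfig", object@scenarioId, "\n")
  cat("  genotypes:", object@nGenotypes, " markers:", object@nMarkers, "\n")
  cat(sprintf("  sigma_u^2 = %.6g, sigma_e^2 = %.6g (SD %.4g), sigma_b^2 = %.6g\n",
              object@markerVariance, object@errorVariance, object@errorSD,
              object@blockVariance))
  cat(sprintf("  alpha-design: %d replicates, blocks of %d plots\n",
              object@nReplicates, object@blockSize))
  cat(sprintf("  outlier: %g x error SD; %d datasets, seed %d\n",
              object@outlierMultiplier, object@nDatasets, object@seed))
})

setMethod("show", "MarkerMatrix", function(object) {
  cat("MarkerMatrix:", nrow(object@Z), "genotypes x", ncol(object@Z),
      "markers\n")
  codes <- sort(unique(as.vector(object@Z)))
  cat("  codes:", paste(codes, collapse = ", "),
      if (!0 %in% codes) "(doubled haploid)" else "", "\n")
})

setMethod("show", "TrialData", function(object) {
  rec <- object@records
  cat("TrialData:", length(unique(rec$genotype)), "genotypes,",
      max(rec$replicate), "replicates,", nrow(rec), "plots\n")
  if (length(object@outlier)) {
    cat(sprintf("  contaminated: record %d shifted by %.4g\n",
                object@outlier$record, object@outlier$shift))
  } else {
    cat("  uncontaminated\n")
  }
})

setMethod("show", "AdjustedMeans", function(object) {
  cat("AdjustedMeans for", length(object@p), "genotypes\n")
  cat(sprintf("  sigma_b^2 = %.4g, sigma_e^2 = %.4g, vbar = %.4g\n",
              object@sigma2Block, object@sigma2Residual, object@vbar))
})

setMethod("show", "RemlFit", function(object) {
  cat("RemlFit (", object@nobs, "obs )\n")
  cat(sprintf("  sigma2Random = %.6g%s, sigma2Residual = %.6g\n",
              object@sigma2Random,
              if (object@boundary) " [boundary]" else "",
              object@sigma2Residual))
  cat(sprintf("  REML logLik = %.4f, converged: %s\n",
              object@logLik, object@converged))
})

setMethod("show", "PlotModelFit", function(object) {
  cat("PlotModelFit (", object@nobs, "plots )\n")
  cat(sprintf("  sigma_g^2 = %.6g%s, sigma_b^2 = %.6g, sigma_e^2 = %.6g\n",
              object@sigma2Genotype,
              if (object@boundaryGenotype) " [boundary]" else "",
              object@sigma2Block, object@sigma2Residual))
  cat("  converged:", object@converged, "\n")
})

setMethod("show", "GenomicModel", function(object) {
  cat("GenomicModel on", nrow(object@G), "genotypes\n")
  cat(sprintf("  tr(Pu G) = %.4g, tr(Pu R) = %.4g\n",
              puTrace(object@G), puTrace(object@R)))
})
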