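#' @rdname accessors
#' @export
setGeneric("nGenotypes", function(x) standardGeneric("nGenotypes"))

#' @rdname accessors
#' @export
setGeneric("nMarkers", function(x) standardGeneric("nMarkers"))

#' @rdname accessors
#' @export
setGeneric("genotypeIds", function(x) standardGeneric("genotypeIds"))

#' @rdname accessors
#' @export
setGeneric("markerCodes", function(x) standardGeneric("markerCodes"))

#' @rdname accessors
#' @export
setGeneric("breedingValues", function(x) standardGeneric("breedingValues"))

#' @rdname accessors
#' @export
setGeneric("trialRecords", function(x) standardGeneric("trialRecords"))

#' @rdname accessors
#' @export
setGeneric("adjustedMeans", function(x) standardGeneric("adjustedMeans"))

#' @rdname accessors
#' @export
setGeneric("meansVcov", function(x) standardGeneric("meansVcov"))

#' @rdname accessors
#' @export
setGeneric("varComp", function(x) standardGeneric("varComp"))

#' @rdname accessors
#' @export
setGeneric("converged", function(x) standardGeneric("converged"))

#' @rdname accessors
#' @export
setGeneric("blup", function(x) standardGeneric("blup"))

#' @rdname accessors
#' @export
setGeneric("pev", function(x) standardGeneric("pev"))

#' @rdname accessors
#' @export
setGeneric("isBoundary", function(x) standardGeneric("isBoundary"))
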