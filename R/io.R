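## Plain-text round trips for the main objects and result tables.

schemaHeader <- "# gpacc table schema 1"

writeDelimWithHeader <- function(df, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(schemaHeader, con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
}

readDelimWithHeader <- function(path) {
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' Write / read a trial's plot table
#'
#' The delimited plot table (genotype, replicate, block, plot, yield) round
#' trips losslessly; the generating components (true breeding values, block
#' effects, plot errors) are simulation-internal and are not serialized, so
#' a re-read trial carries records only.
#'
#' @param trial a \linkS4class{TrialData}.
#' @param path file path.
#' @return \code{readTrialData} returns a \linkS4class{TrialData} with
#'   empty truth slots.
#' @export
writeTrialData <- function(trial, path) {
  writeDelimWithHeader(trialRecords(trial), path)
  invisible(path)
}

#' @rdname writeTrialData
#' @export
readTrialData <- function(path) {
  rec <- readDelimWithHeader(path)
  rec$genotype <- as.character(rec$genotype)
  new("TrialData", records = rec, mu = 0,
      gamma = rep(0, max(rec$replicate)),
      blockEffects = data.frame(replicate = integer(), block = integer(),
                                effect = numeric()),
      plotErrors = numeric(), truth = new("BreedingValues"),
      outlier = list())
}

#' Write / read a marker matrix
#'
#' Delimited table with a genotype-id column followed by one column per
#' marker; codes -1/0/1.
#'
#' @param markers a \linkS4class{MarkerMatrix}.
#' @param path file path.
#' @return \code{readMarkerMatrix} returns a \linkS4class{MarkerMatrix};
#'   allele frequencies are recomputed from the codes.
#' @export
writeMarkerMatrix <- function(markers, path) {
  Z <- markerCodes(markers)
  df <- data.frame(genotype = rownames(Z), Z, check.names = FALSE)
  writeDelimWithHeader(df, path)
  invisible(path)
}

#' @rdname writeMarkerMatrix
#' @export
readMarkerMatrix <- function(path) {
  df <- readDelimWithHeader(path)
  Z <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(Z) <- "double"
  rownames(Z) <- as.character(df$genotype)
  new("MarkerMatrix", Z = Z, alleleFreq = colMeans(Z == 1) + colMeans(Z == 0) / 2)
}

#' Write / read an adjusted-means table
#'
#' @param am an \linkS4class{AdjustedMeans}.
#' @param path file path.
#' @return \code{readAdjustedMeansTable} returns a data.frame (genotype,
#'   mean, se); the full variance matrix is not serialized.
#' @export
writeAdjustedMeans <- function(am, path) {
  df <- data.frame(genotype = names(adjustedMeans(am)),
                   mean = unname(adjustedMeans(am)),
                   se = sqrt(diag(meansVcov(am))))
  writeDelimWithHeader(df, path)
  invisible(path)
}

#' @rdname writeAdjustedMeans
#' @export
readAdjustedMeansTable <- function(path) {
  readDelimWithHeader(path)
}

#' Write / read a scenario configuration (YAML)
#'
#' @param config a \linkS4class{ScenarioConfig}.
#' @param path file path.
#' @return \code{readScenarioConfig} returns a
#'   \linkS4class{ScenarioConfig}.
#' @export
writeScenarioConfig <- function(config, path) {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    stop("the yaml package is required for config files")
  }
  fields <- c("scenarioId", "nGenotypes", "nMarkers", "markerVariance",
              "errorVariance", "errorSD", "blockVariance", "nReplicates",
              "blockSize", "outlierMultiplier", "nDatasets", "seed")
  lst <- lapply(fields, function(f) slot(config, f))
  names(lst) <- fields
  yaml::write_yaml(lst, path)
  invisible(path)
}

#' @rdname writeScenarioConfig
#' @export
readScenarioConfig <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    stop("the yaml package is required for config files")
  }
  lst <- yaml::read_yaml(path)
  do.call(scenarioConfig, lst)
}

#' Write study result files
#'
#' Writes the per-dataset results table, the per-scenario deviation
#' summary and the flag-count table as tab-delimited files with a schema
#' header. An empty result set yields headers-only files.
#'
#' @param results data.frame from \code{\link{runStudy}} (possibly empty).
#' @param dir output directory (created if missing).
#' @return invisibly, the paths written.
#' @export
writeReport <- function(results, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, c("results.tsv", "summary.tsv", "flags.tsv"))
  writeDelimWithHeader(results, paths[1L])
  if (nrow(results)) {
    summ <- deviationSummary(results)
    flags <- do.call(rbind, lapply(unique(results$scenario), function(sc) {
      do.call(rbind, lapply(c("clean", "outlier"), function(cond) {
        do.call(rbind, lapply(1:7, function(m) {
          data.frame(scenario = sc, condition = cond, method = m,
                     t(countFlags(results[results$scenario == sc, ], m, cond)))
        }))
      }))
    }))
  } else {
    summ <- data.frame(scenario = integer(), condition = character(),
                       measure = character(), method = integer(),
                       md = numeric(), se = numeric(), nUsed = integer())
    flags <- data.frame(scenario = integer(), condition = character(),
                        method = integer(), undershoot = integer(),
                        overshoot = integer(), nonconverged = integer())
  }
  writeDelimWithHeader(summ, paths[2L])
  writeDelimWithHeader(flags, paths[3L])
  invisible(paths)
}

#' @rdname writeReport
#' @param path a results.tsv written by \code{writeReport}.
#' @export
readResults <- function(path) {
  readDelimWithHeader(path)
}
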