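#' Construct a simulation scenario
#'
#' @param scenarioId integer label.
#' @param nGenotypes,nMarkers panel dimensions.
#' @param markerVariance variance of iid marker effects.
#' @param errorVariance plot-error variance.
#' @param errorSD plot-error SD used for the outlier shift; defaults to
#'   \code{sqrt(errorVariance)}.
#' @param blockVariance incomplete-block variance. The trials the simulator
#'   emulates do not report it, so the default is a stand-in of a quarter of
#'   the plot-error variance.
#' @param nReplicates,blockSize alpha-design layout.
#' @param outlierMultiplier 0 (clean), 5, 8 or 10.
#' @param nDatasets datasets per scenario.
#' @param seed master seed.
#' @return a \linkS4class{ScenarioConfig}.
#' @export
#' @examples
#' scenarioConfig(1L, 177L, 275L, 0.2019, 48.6728, errorSD = 6.977,
#'                outlierMultiplier = 5)
scenarioConfig <- function(scenarioId, nGenotypes, nMarkers, markerVariance,
                           errorVariance, errorSD = sqrt(errorVariance),
                           blockVariance = errorVariance / 4,
                           nReplicates = 2L, blockSize = 18L,
                           outlierMultiplier = 0, nDatasets = 1000L,
                           seed = 101L) {
  new("ScenarioConfig",
      scenarioId = as.integer(scenarioId),
      nGenotypes = as.integer(nGenotypes),
      nMarkers = as.integer(nMarkers),
      markerVariance = as.numeric(markerVariance),
      errorVariance = as.numeric(errorVariance),
      errorSD = as.numeric(errorSD),
      blockVariance = as.numeric(blockVariance),
      nReplicates = as.integer(nReplicates),
      blockSize = as.integer(blockSize),
      outlierMultiplier = as.numeric(outlierMultiplier),
      nDatasets = as.integer(nDatasets),
      seed = as.integer(seed))
}

#' The ten preset simulation scenarios
#'
#' Scenarios 1-6 emulate the small maize panel (177 doubled-haploid
#' genotypes, 275 markers, plot-error variance 48.6728 with SD 6.977);
#' scenarios 7-10 the large panel (698 genotypes, 11,646 markers,
#' plot-error variance 53.8715 with SD 7.340). Marker-effect variances are
#' 0.2019 and 0.005892, divided by 10 in the reduced-heritability scenarios
#' (4-6 and 9-10). Outlier multipliers are 5/8/10 for the small panel and
#' 5/10 for the large one.
#'
#' Scenarios that differ only in the outlier multiplier (1-3, 4-6, 7-8,
#' 9-10) share their base datasets when run through \code{\link{runStudy}}.
#'
#' @param seed master seed stored in every preset.
#' @param nDatasets datasets per scenario.
#' @param blockVariance optional block variance applied to all presets;
#'   default is a quarter of each scenario's plot-error variance.
#' @return list of ten \linkS4class{ScenarioConfig} objects.
#' @export
#' @examples
#' cfg <- makeScenarioConfigs()
#' cfg[[6]]
makeScenarioConfigs <- function(seed = 101L, nDatasets = 1000L,
                                blockVariance = NULL) {
  grid <- data.frame(
    id = 1:10,
    n = c(rep(177L, 6L), rep(698L, 4L)),
    q = c(rep(275L, 6L), rep(11646L, 4L)),
    su2 = c(rep(0.2019, 3L), rep(0.2019 / 10, 3L),
            rep(0.005892, 2L), rep(0.005892 / 10, 2L)),
    se2 = c(rep(48.6728, 6L), rep(53.8715, 4L)),
    sd = c(rep(6.977, 6L), rep(7.340, 4L)),
    k = c(5, 8, 10, 5, 8, 10, 5, 10, 5, 10)
  )
  lapply(seq_len(nrow(grid)), function(i) {
    row <- grid[i, ]
    scenarioConfig(row$id, row$n, row$q, row$su2, row$se2, errorSD = row$sd,
                   blockVariance = if (is.null(blockVariance))
                     row$se2 / 4 else blockVariance,
                   outlierMultiplier = row$k,
                   nDatasets = nDatasets, seed = seed)
  })
}

## scenarios sharing (n, q, sigma_u^2, sigma_e^2, design) share base data;
## the key feeds the RNG stream so sharing survives subsetting and reordering
baseKey <- function(config) {
  paste(config@nGenotypes, config@nMarkers,
        signif(config@markerVariance, 10), signif(config@errorVariance, 10),
        signif(config@blockVariance, 10), config@nReplicates,
        config@blockSize, sep = "|")
}
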