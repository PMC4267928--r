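test_that("study runs are deterministic and correctly paired", {
  cfgA <- smallConfig(scenarioId = 1L, k = 5, nDatasets = 2L)
  cfgB <- smallConfig(scenarioId = 3L, k = 10, nDatasets = 2L)

  res1 <- runStudy(list(cfgA, cfgB))
  res2 <- runStudy(list(cfgA, cfgB))
  expect_identical(res1, res2)

  ## same base data: clean rows identical across the scenario pair,
  ## contaminated rows differ (different outlier magnitude, same plot)
  cleanA <- res1[res1$scenario == 1L & res1$condition == "clean", ]
  cleanB <- res1[res1$scenario == 3L & res1$condition == "clean", ]
  rownames(cleanA) <- rownames(cleanB) <- NULL
  expect_equal(cleanA[, setdiff(names(cleanA), "scenario")],
               cleanB[, setdiff(names(cleanB), "scenario")])
  outA <- res1[res1$scenario == 1L & res1$condition == "outlier", ]
  outB <- res1[res1$scenario == 3L & res1$condition == "outlier", ]
  expect_false(isTRUE(all.equal(outA$accm5, outB$accm5)))

  ## schema: both conditions for every dataset, all method columns present
  expect_equal(nrow(res1), 2L * 2L * 2L)
  expect_true(all(c(paste0("h2m", 1:5), paste0("accm", 1:7),
                    "trueAcc", "trueH2", "rGhatP") %in% names(res1)))
})

test_that("an uncontaminated scenario has identical clean and outlier rows", {
  cfg <- smallConfig(scenarioId = 9L, k = 0, nDatasets = 2L)
  res <- runScenario(cfg)
  clean <- res[res$condition == "clean", ]
  outl <- res[res$condition == "outlier", ]
  rownames(clean) <- rownames(outl) <- NULL
  expect_equal(clean[, setdiff(names(clean), "condition")],
               outl[, setdiff(names(outl), "condition")])
})

test_that("mean deviation matches hand-computed values", {
  expect_equal(meanDeviation(c(1, 2), c(1, 2))$md, 0)
  md <- meanDeviation(0.8, 0.6)
  expect_equal(md$md, 0.2)
  md2 <- meanDeviation(c(0.7, 0.5), c(0.6, 0.6))
  expect_equal(md2$md, 0)
  expect_equal(md2$se, 0.1)
  md3 <- meanDeviation(c(0.7, NA, 0.5), c(0.6, 0.6, 0.6))
  expect_equal(md3$nUsed, 2L)
  expect_equal(md3$nExcluded, 1L)
  expect_error(meanDeviation(NA_real_, 0.5), "no computable")
  expect_error(meanDeviation(1:3, 1:2), "length mismatch")
})

fakeResults <- function(acc, scenario = 6L, condition = "outlier",
                        convStage1 = TRUE, convPlot = TRUE, convGen = TRUE,
                        boundaryPlot = FALSE, boundaryGen = FALSE,
                        cvAnyZeroVar = FALSE) {
  n <- length(acc)
  df <- data.frame(scenario = scenario, dataset = seq_len(n),
                   condition = condition, trueAcc = 0.5, trueH2 = 0.4,
                   convStage1 = convStage1, convPlot = convPlot,
                   convGen = convGen, boundaryPlot = boundaryPlot,
                   boundaryGen = boundaryGen, cvAnyZeroVar = cvAnyZeroVar)
  for (m in 1:7) df[[paste0("accm", m)]] <- acc
  for (m in 1:5) df[[paste0("h2m", m)]] <- 0.4
  df$rGhatP <- 0.3
  df
}

test_that("flag counting distinguishes the failure modes", {
  res <- fakeResults(c(-0.1, 0.5, 1.2, NA))
  fl <- countFlags(res, 1L)
  expect_equal(fl[["undershoot"]], 1L)
  expect_equal(fl[["overshoot"]], 1L)
  expect_equal(fl[["notComputable"]], 1L)
  expect_equal(fl[["nonconverged"]], 0L)

  ok <- countFlags(fakeResults(c(0.2, 0.9, 1.0)), 3L)
  expect_true(all(ok[c("undershoot", "overshoot", "nonconverged",
                       "zeroHeritability", "zeroGeneticVariance")] == 0L))

  ## contaminated-minus-clean differences (the figures' a/b/c annotations)
  clean <- c(undershoot = 2L, overshoot = 1L, nonconverged = 0L)
  cont <- c(undershoot = 5L, overshoot = 1L, nonconverged = 3L)
  expect_equal(cont - clean,
               c(undershoot = 3L, overshoot = 0L, nonconverged = 3L))

  ## method-specific attribution of boundary and convergence failures
  resB <- fakeResults(0.5, boundaryPlot = TRUE, convGen = FALSE)
  expect_equal(countFlags(resB, 1L)[["zeroHeritability"]], 1L)
  expect_equal(countFlags(resB, 4L)[["zeroHeritability"]], 0L)
  expect_equal(countFlags(resB, 4L)[["nonconverged"]], 1L)
  expect_equal(countFlags(resB, 1L)[["nonconverged"]], 0L)
  resZ <- fakeResults(0.5, cvAnyZeroVar = TRUE)
  expect_equal(countFlags(resZ, 2L)[["zeroGeneticVariance"]], 1L)
  expect_equal(countFlags(resZ, 5L)[["zeroGeneticVariance"]], 0L)
})

test_that("deviation summaries cover methods x conditions with exclusions", {
  res <- rbind(fakeResults(c(0.6, 0.7), condition = "clean"),
               fakeResults(c(0.9, NA), condition = "outlier"))
  summ <- deviationSummary(res)
  ## 5 heritability + 7 accuracy methods, 2 conditions, 1 scenario
  expect_equal(nrow(summ), 2L * (5L + 7L))
  row <- summ[summ$condition == "outlier" & summ$measure == "accuracy" &
                summ$method == 1L, ]
  expect_equal(row$md, 0.4)
  expect_equal(row$nUsed, 1L)
  expect_equal(row$nExcluded, 1L)
})

test_that("pairwise comparisons recover built-in relationships", {
  set.seed(9)
  devA <- rnorm(60, 0.05, 0.1)
  res <- fakeResults(devA + 0.5)
  res$accm2 <- devA + 0.5 + 0.1 + rnorm(60, 0, 0.005)
  cmp <- compareMethods(res)
  r12 <- cmp[cmp$methodA == 1L & cmp$methodB == 2L, ]
  expect_gt(r12$correlation, 0.99)
  expect_lt(r12$p, 1e-10)  # constant offset of 0.1 is detected
  ## identical deviations: correlation 1, t = 0
  r13 <- cmp[cmp$methodA == 1L & cmp$methodB == 3L, ]
  expect_equal(r13$correlation, 1)
  expect_equal(r13$t, 0)

  ## independent deviation vectors are near-uncorrelated
  set.seed(10)
  res2 <- fakeResults(rnorm(1000, 0.5, 0.1))
  res2$accm2 <- rnorm(1000, 0.5, 0.1)
  cmp2 <- compareMethods(res2)
  expect_lt(abs(cmp2[cmp2$methodA == 1L & cmp2$methodB == 2L,
                     "correlation"]), 0.1)
})

test_that("reports round-trip and tolerate empty runs", {
  dir <- withr::local_tempdir()
  cfg <- smallConfig(nDatasets = 2L)
  res <- runScenario(cfg)
  paths <- writeReport(res, dir)
  back <- readResults(paths[1L])
  expect_equal(nrow(back), nrow(res))
  ## recomputed summaries from the round-tripped table are identical
  expect_equal(deviationSummary(back), deviationSummary(res),
               tolerance = 1e-8)

  empty <- res[0L, ]
  paths2 <- writeReport(empty, file.path(dir, "empty"))
  expect_true(all(file.exists(paths2)))
  expect_equal(nrow(readResults(paths2[1L])), 0L)
})
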