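test_that("generators are reproducible under a fixed seed", {
  expect_identical(profileValues(simActivity(panel60, seed = 5)$profile),
                   profileValues(simActivity(panel60, seed = 5)$profile))
  expect_identical(
    SummarizedExperiment::assay(
      simProteome(simActivity(panel60, seed = 5)$profile, seed = 6)),
    SummarizedExperiment::assay(
      simProteome(simActivity(panel60, seed = 5)$profile, seed = 6)))
  expect_identical(simTitration(seed = 7)@signal,
                   simTitration(seed = 7)@signal)
  expect_identical(simSurvivalCohort(seed = 8)$time,
                   simSurvivalCohort(seed = 8)$time)
  expect_identical(simCtTable(seed = 9)$ct, simCtTable(seed = 9)$ct)
})

test_that("simPanel reproduces the 60-line nine-tissue layout", {
  expect_length(cellLines(panel60), 60L)
  expect_equal(nlevels(tissues(panel60)), 9L)
  expect_equal(as.vector(table(tissues(panel60))[names(nci60TissueCounts())]),
               unname(as.integer(nci60TissueCounts())))
  solo <- simPanel(c(colon = 3L))
  expect_length(cellLines(solo), 3L)
  expect_true(all(tissues(solo) == "colon"))
  expect_error(simPanel(c(colon = 0L)))
})

test_that("simActivity realizes the requested class correlation", {
  sim <- simActivity(panel60, rho = 0.999, seed = 15)
  own <- profileValues(sim$library)[moaClass(sim$library) ==
                                      sim$compoundClass, ]
  rOwn <- apply(own, 1, function(a)
    cor(a, profileValues(sim$profile)))
  expect_true(all(rOwn > 0.98))
  # near-zero rho: no strong correlations among 91 agents at n = 60
  sim0 <- simActivity(panel60, rho = 1e-6, tissueShift = c(leukemia = 0),
                      seed = 16)
  r0 <- apply(profileValues(sim0$library), 1, function(a)
    cor(a, profileValues(sim0$profile)))
  expect_lt(max(abs(r0)), 0.5)
  # default library: 91 agents, 10 of them microtubule inhibitors
  expect_equal(nrow(profileValues(sim$library)), 91L)
  expect_equal(sum(moaClass(sim$library) == "microtubule"), 10L)
  expect_error(simActivity(panel60, rho = 1.2))
})

test_that("simProteome plants correlates at the requested strength", {
  prof <- simActivity(panel60, seed = 17)$profile
  se <- simProteome(prof, seed = 17)
  md <- S4Vectors::metadata(se)
  expect_length(md$direct, 20L)
  expect_length(md$inverse, 20L)
  cp <- compareProteins(prof, se)
  rd <- cp$r[match(md$direct, cp$feature)]
  ri <- cp$r[match(md$inverse, cp$feature)]
  expect_equal(mean(rd), 0.6, tolerance = 0.17)
  expect_equal(mean(ri), -0.6, tolerance = 0.17)
  # pure null when nothing is planted
  se0 <- simProteome(prof, nDirect = 0, nInverse = 0, seed = 18)
  expect_true(all(SummarizedExperiment::rowData(se0)$planted == "null"))
  expect_error(simProteome(prof, nProteins = 10, nDirect = 8,
                           nInverse = 8))
})

test_that("simTitration follows the dilution arithmetic and model curve", {
  ts <- simTitration(noiseSD = 0, seed = 19)
  expect_length(ts, 14L)
  expect_equal(max(ts@ligandTotal), 3e-4)
  expect_equal(ts@ligandTotal, 3e-4 / 2^(0:13))
  expect_equal(ts@signal,
               predictSignal(ts@ligandTotal, 943e-9, 1, 0.5, 2e-7),
               tolerance = 1e-12)
  expect_equal(attr(ts, "trueKd"), 943e-9)
})

test_that("simSurvivalCohort realizes censoring and hazard structure", {
  noc <- simSurvivalCohort(censorFraction = 0, seed = 20)
  expect_true(all(noc$event == 1))
  # exponential medians scale with the hazard ratio
  big <- simSurvivalCohort(nPerArm = 4000, hazardRatio = 2,
                           censorFraction = 0, seed = 21)
  grp <- dichotomize(big$expression)
  ratio <- median(big$time[grp == "low"]) /
    median(big$time[grp == "high"])
  expect_equal(ratio, 2, tolerance = 0.1)
  # HR = 1: arms exchangeable in distribution
  null <- simSurvivalCohort(nPerArm = 4000, hazardRatio = 1,
                            censorFraction = 0, seed = 22)
  g0 <- dichotomize(null$expression)
  expect_equal(median(null$time[g0 == "low"]) /
                 median(null$time[g0 == "high"]), 1, tolerance = 0.1)
})

test_that("simCtTable encodes the fold change in the treated target Ct", {
  ct <- simCtTable(log2Fold = -2, noiseSD = 0, seed = 23)
  expect_equal(nrow(ct), 12L)
  expect_equal(ddctFold(ct)$log2Fold, -2)
  expect_equal(ddctFold(simCtTable(log2Fold = 0, noiseSD = 0,
                                   seed = 24))$fold, 1)
})
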