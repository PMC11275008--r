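test_that("compareRank puts a self-profile at rank 1 with r = 1", {
  sim <- simActivity(panel60, seed = 3)
  lib <- sim$library
  prof2 <- rbind(profileValues(lib), self = profileValues(sim$profile))
  lib2 <- AgentLibrary(prof2, c(moaClass(lib), self = "query"))
  ranked <- compareRank(sim$profile, lib2)
  expect_equal(ranked$agent[1], "self")
  expect_equal(ranked$r[1], 1)
})

test_that("compareRank excludes thin-overlap agents instead of erroring", {
  sim <- simActivity(panel60, seed = 4)
  prof <- profileValues(sim$library)
  prof["alkylating_01", 3:60] <- NA   # 2 shared lines left
  lib <- AgentLibrary(prof, moaClass(sim$library))
  ranked <- compareRank(sim$profile, lib)
  expect_false("alkylating_01" %in% ranked$agent)
  excl <- attr(ranked, "excluded")
  expect_true("alkylating_01" %in% excl$id)
  expect_match(excl$reason[excl$id == "alkylating_01"], "overlap")
  expect_error(compareRank(sim$profile,
                           AgentLibrary(prof[0, , drop = FALSE],
                                        character(0))),
               "empty")
})

test_that("compareRank ordering is invariant under common affine rescaling", {
  sim <- simActivity(panel60, seed = 5)
  ranked <- compareRank(sim$profile, sim$library)
  resc <- AgentLibrary(2.5 * profileValues(sim$library) - 4,
                       moaClass(sim$library))
  prof2 <- ActivityProfile("compound",
                           2.5 * profileValues(sim$profile) - 4)
  ranked2 <- compareRank(prof2, resc)
  expect_equal(ranked2$agent, ranked$agent)
  expect_equal(ranked2$r, ranked$r, tolerance = 1e-12)
})

test_that("the planted mechanism class dominates the COMPARE ranking", {
  top3 <- vapply(1:100, function(s) {
    sim <- simActivity(panel60, seed = s)
    ranked <- compareRank(sim$profile, sim$library)
    all(ranked$moa[1:3] == sim$compoundClass)
  }, logical(1))
  expect_gte(mean(top3), 0.95)
  firstClass <- vapply(1:50, function(s) {
    sim <- simActivity(panel60, seed = s)
    moaEnrichment(compareRank(sim$profile, sim$library))$rankedClasses[1]
  }, character(1))
  expect_gte(mean(firstClass == "microtubule"), 0.95)
})

test_that("moaEnrichment applies thresholds and breaks ties alphabetically", {
  ranked <- data.frame(agent = c("a1", "b1", "c1", "d1"),
                       moa = c("beta", "alpha", "beta", "alpha"),
                       n = 60, r = c(0.1, 0.05, -0.5, 0.2),
                       p = c(0.5, 0.9, 1e-4, 0.4))
  ms <- moaEnrichment(ranked)
  expect_true(all(ms$perClass$nSignificant == 0))   # nothing passes
  expect_equal(ms$rankedClasses, c("alpha", "beta"))  # alphabetical tie
  # negative correlations never count as class hits
  ranked$r[3] <- -0.9; ranked$p[3] <- 1e-9
  expect_equal(moaEnrichment(ranked)$perClass$nSignificant, c(0L, 0L))
  # boundary behavior: r = rMin and p = alpha count (inclusive rule)
  ranked$r[1] <- 0.30; ranked$p[1] <- 0.05
  ms2 <- moaEnrichment(ranked)
  expect_equal(ms2$perClass$nSignificant[ms2$perClass$moa == "beta"], 1L)
})

test_that("null agents are flagged at the two-sided rate implied by alpha", {
  # with r >= 0 required and a two-sided p, independence gives ~alpha/2
  set.seed(202)
  vals <- setNames(rnorm(60), cellLines(panel60))
  prof <- ActivityProfile("null", vals)
  m <- matrix(rnorm(10000 * 60), 10000, 60,
              dimnames = list(sprintf("a%05d", 1:10000),
                              cellLines(panel60)))
  lib <- AgentLibrary(m, setNames(rep("x", 10000), rownames(m)))
  ranked <- compareRank(prof, lib)
  frac <- mean(ranked$r >= 0 & ranked$p <= 0.05)
  expect_equal(frac, 0.025, tolerance = 0.4)   # 0.025 +/- 0.01
  expect_gt(frac, 0.015); expect_lt(frac, 0.035)
})

test_that("oncobiogramVector handles self, undefined and planted references", {
  sim <- simActivity(panel60, seed = 6)
  v <- oncobiogramVector(sim$profile,
                         list(self = sim$profile))
  expect_equal(unname(v["self"]), 1)
  flat <- ActivityProfile("flat",
                          setNames(rep(1, 60), cellLines(panel60)))
  v2 <- oncobiogramVector(sim$profile, list(self = sim$profile,
                                            flat = flat))
  expect_true(is.na(v2["flat"]))
  # tubulin-like references out-correlate unrelated ones
  sep <- vapply(1:50, function(s) {
    sim <- simActivity(panel60, seed = s)
    mt <- profileValues(sim$library)[paste0("microtubule_",
                                            sprintf("%02d", 1:10)), ]
    other <- profileValues(sim$library)[paste0("hormonal_",
                                               sprintf("%02d", 1:7)), ]
    vv <- oncobiogramVector(sim$profile, rbind(mt, other))
    mean(vv[1:10]) > mean(vv[11:17])
  }, logical(1))
  expect_gte(mean(sep), 0.98)
})

test_that("tissueMeanIC50 averages per tissue and validates ids", {
  pan <- CellLinePanel(c("a", "b", "c", "d"),
                       c("colon", "colon", "colon", "breast"))
  prof <- ActivityProfile("x", c(a = -5, b = -6, c = -7, d = -4))
  m <- tissueMeanIC50(prof, pan)
  expect_equal(unname(m["colon"]), -6)
  expect_equal(unname(m["breast"]), -4)   # single line = its own mean
  bad <- ActivityProfile("x", c(a = -5, b = -6, zz = -7))
  expect_error(tissueMeanIC50(bad, pan), "zz")
  # generator default: leukemia lines are the most sensitive tissue in
  # the clear majority of draws (the -0.5 shift competes with profile
  # noise in any single draw)
  leukMin <- vapply(1:30, function(s) {
    sim <- simActivity(panel60, seed = s)
    names(which.min(tissueMeanIC50(sim$profile, panel60))) == "leukemia"
  }, logical(1))
  expect_gte(mean(leukMin), 0.6)
})
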