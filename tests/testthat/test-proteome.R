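test_that("compareProteins recovers exact and planted correlates", {
  sim <- simActivity(panel60, seed = 8)
  v <- profileValues(sim$profile)
  m <- rbind(same = v, neg = -v,
             noise = rnorm(60))
  colnames(m) <- names(v)
  cp <- compareProteins(sim$profile, m)
  expect_equal(cp$r[cp$feature == "same"], 1)
  expect_equal(cp$r[cp$feature == "neg"], -1)
  expect_lt(cp$p[cp$feature == "same"], 1e-12)
  # planted features occupy the extreme ranks
  se <- simProteome(sim$profile, seed = 8)
  cp2 <- compareProteins(sim$profile, se)
  truth <- unlist(S4Vectors::metadata(se)[c("direct", "inverse")])
  extreme <- cp2$feature[order(-abs(cp2$r))][1:40]
  expect_gte(sum(extreme %in% truth), 36)
  expect_error(compareProteins(sim$profile,
                               matrix(1, 1, 2,
                                      dimnames = list("f", c("x", "y")))),
               "overlap")
})

test_that("compareProteins agrees with pairwise pearsonTest under missingness", {
  set.seed(30)
  v <- setNames(rnorm(20), paste0("c", 1:20))
  m <- matrix(rnorm(100), 5, 20,
              dimnames = list(paste0("f", 1:5), names(v)))
  m[1, 1:4] <- NA; m[2, ] <- 5   # gaps and a constant feature
  prof <- ActivityProfile("x", v)
  cp <- compareProteins(prof, m)
  expect_false("f2" %in% cp$feature)   # zero variance excluded
  for (f in cp$feature) {
    want <- pearsonTest(v, m[f, ])
    row <- cp[cp$feature == f, ]
    expect_equal(row$r, want$r, tolerance = 1e-12)
    expect_equal(row$p, want$p, tolerance = 1e-12)
    expect_equal(row$n, want$n)
  }
})

test_that("selectTop is exact-size, disjoint and order-invariant", {
  sim <- simActivity(panel60, seed = 9)
  se <- simProteome(sim$profile, seed = 9)
  cp <- compareProteins(sim$profile, se)
  sel <- selectTop(cp)
  expect_equal(nrow(sel$direct), 20L)
  expect_equal(nrow(sel$inverse), 20L)
  expect_true(all(sel$direct$r > 0))
  expect_true(all(sel$inverse$r < 0))
  expect_length(intersect(sel$direct$feature, sel$inverse$feature), 0L)
  expect_true(all(diff(sel$direct$r) <= 0))
  expect_true(all(diff(sel$inverse$r) >= 0))
  # permuting the correlation rows leaves the selection unchanged
  set.seed(1)
  sel2 <- selectTop(cp[sample(nrow(cp)), ])
  expect_equal(sel2$direct$feature, sel$direct$feature)
  expect_equal(sel2$inverse$feature, sel$inverse$feature)
  # degenerate and shortfall cases
  empty <- selectTop(cp, kDirect = 0, kInverse = 0)
  expect_equal(nrow(empty$direct), 0L)
  expect_error(selectTop(cp[cp$r > 0, ], kInverse = 20), "negatively")
})

test_that("quartileCode produces the five display categories", {
  m <- matrix(c(1, 2, 3, 4, 5), 1,
              dimnames = list("f", paste0("c", 1:5)))
  expect_equal(unname(quartileCode(m)[1, ]),
               c("Q1", "Q2", "MEDIAN", "Q3", "Q4"))
  const <- matrix(7, 1, 5, dimnames = list("f", paste0("c", 1:5)))
  expect_true(all(quartileCode(const) == "MEDIAN"))
  # distinct vectors of length 4k+1: quartile counts differ by <= 1
  set.seed(40)
  for (i in 1:25) {
    v <- sample(100, 9)
    m9 <- matrix(v, 1, dimnames = list("f", paste0("c", 1:9)))
    cnt <- table(factor(quartileCode(m9),
                        levels = c("Q1", "Q2", "Q3", "Q4")))
    expect_lte(diff(range(cnt)), 1)
  }
  expect_error(quartileCode(matrix(c(1, 2, NA, NA, NA), 1)), "non-missing")
})

test_that("quartileCode per-feature equals feature-by-feature coding", {
  set.seed(41)
  m <- matrix(rnorm(60), 6, 10,
              dimnames = list(paste0("f", 1:6), paste0("c", 1:10)))
  whole <- quartileCode(m, axis = "per_feature")
  for (i in 1:6)
    expect_equal(whole[i, ],
                 quartileCode(m[i, , drop = FALSE])[1, ])
  # global coding uses one quantile set for everything
  g <- quartileCode(m, axis = "global")
  expect_true(is.matrix(g) && all(dim(g) == dim(m)))
})

test_that("wardCluster matches the exhaustive variance-recomputation oracle", {
  set.seed(50)
  for (i in 1:5) {
    X <- matrix(rnorm(8 * 5), 8, 5,
                dimnames = list(paste0("f", 1:8), paste0("c", 1:5)))
    hc <- wardCluster(X, axis = "rows", zscore = FALSE)
    expect_equal(sort(hc$height), sort(oracleWard(X)), tolerance = 1e-9)
    expect_true(all(diff(hc$height) >= -1e-12))   # no inversions
  }
})

test_that("wardCluster honors structure, z-scoring and degenerate input", {
  X <- rbind(a = c(0, 0), b = c(0, 0), c = c(10, 10), d = c(10.1, 10))
  colnames(X) <- c("c1", "c2")
  hc <- wardCluster(X, axis = "rows", zscore = FALSE)
  expect_equal(hc$height[1], 0)                   # identical pair first
  # the two tight pairs merge before anything crosses
  cl <- cutTreeK(hc, 2)
  expect_equal(unname(cl[c("a", "b")]), c(1L, 1L))
  expect_equal(unname(cl[c("c", "d")]), c(2L, 2L))
  # column clustering transposes
  hcc <- wardCluster(X, axis = "cols", zscore = FALSE)
  expect_equal(length(hcc$labels), 2L)
  expect_error(wardCluster(X[1, , drop = FALSE], axis = "rows"), ">= 2")
  Xna <- X; Xna[1, ] <- NA
  expect_error(wardCluster(Xna, axis = "rows", zscore = FALSE),
               "no finite")
})

test_that("cutTreeK spans singleton to single-cluster cuts", {
  set.seed(51)
  X <- matrix(rnorm(30), 6, 5,
              dimnames = list(paste0("f", 1:6), paste0("c", 1:5)))
  hc <- wardCluster(X, axis = "rows")
  expect_equal(max(cutTreeK(hc, 6)), 6L)
  expect_equal(unname(cutTreeK(hc, 1)), rep(1L, 6))
  expect_error(cutTreeK(hc, 0), "between")
  expect_error(cutTreeK(hc, 7), "between")
  # labels are 1..K in first-appearance order
  cl <- cutTreeK(hc, 3)
  expect_equal(unique(unname(cl)), 1:3)
})

test_that("classifySensitivity applies the strict median-split rule", {
  sc <- classifySensitivity(
    ActivityProfile("x", c(a = -6, b = -5, c = -4)))
  expect_equal(as.character(sc$calls), c("sensitive", "tie", "resistant"))
  sc2 <- classifySensitivity(
    ActivityProfile("x", c(a = -7, b = -6, c = -5, d = -4)))
  expect_equal(sc2$threshold, -5.5)
  expect_equal(as.character(sc2$calls),
               c("sensitive", "sensitive", "resistant", "resistant"))
  allEq <- classifySensitivity(
    ActivityProfile("x", c(a = -5, b = -5, c = -5)))
  expect_true(all(allEq$calls == "tie"))
})

test_that("clusterResponseChi2 matches closed-form tables and drops ties", {
  cl <- setNames(rep(1:2, each = 10), paste0("c", 1:20))
  even <- setNames(factor(rep(c("sensitive", "resistant"), 10),
                          levels = c("sensitive", "resistant", "tie")),
                   paste0("c", 1:20))
  r0 <- clusterResponseChi2(cl, even)
  expect_equal(r0$statistic, 0)
  expect_equal(r0$p, 1)
  perfect <- setNames(factor(rep(c("sensitive", "resistant"), each = 10),
                             levels = c("sensitive", "resistant", "tie")),
                      paste0("c", 1:20))
  r1 <- clusterResponseChi2(cl, perfect)
  expect_equal(r1$statistic, 20)   # all E = 5, sum (O-E)^2/E
  expect_equal(r1$df, 1L)
  # ties are excluded before building the table
  tied <- perfect; tied[1] <- "tie"
  r2 <- clusterResponseChi2(cl, tied)
  expect_equal(sum(r2$table), 19)
  onecall <- setNames(factor(rep("sensitive", 20),
                             levels = c("sensitive", "resistant", "tie")),
                      paste0("c", 1:20))
  expect_error(clusterResponseChi2(cl, onecall), "margin")
  expect_error(clusterResponseChi2(setNames(rep(1, 20), names(cl)), even),
               ">= 2")
})

test_that("clusterMap runs the display stage end to end", {
  sim <- simActivity(panel60, seed = 12)
  se <- simProteome(sim$profile, seed = 12)
  sel <- selectTop(compareProteins(sim$profile, se))
  cm <- clusterMap(se, sel, sim$profile)
  expect_equal(dim(cm$coded), c(40L, 60L))
  expect_equal(max(cm$rowClusters), 3L)
  expect_equal(max(cm$colClusters), 2L)
  expect_s3_class(cm$chi2, "ChiSquareResult")
  expect_lt(cm$chi2$p, 0.05)   # planted structure is detected
})
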