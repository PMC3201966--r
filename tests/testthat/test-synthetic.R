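test_that("homogeneous single-group webs are Erdos-Renyi at the target fill", {
  fw <- generateWeb(S = 50, nGroups = 1, pIn = 0.15, pOut = 0, lambda = 0,
                    seed = 5)
  fill <- mean(adjacency(fw))
  se <- sqrt(0.15 * 0.85 / 2500)
  expect_lt(abs(fill - 0.15), 3 * se)
  expect_s4_class(fw, "SyntheticFoodWeb")
})

test_that("pOut = 0 forbids between-group links", {
  fw <- generateWeb(S = 30, nGroups = 3, pIn = 0.3, pOut = 0, lambda = 0,
                    seed = 6)
  grp <- plantedGroups(fw)
  a <- adjacency(fw)
  between <- outer(grp, grp, "!=")
  expect_equal(sum(a[between]), 0)
})

test_that("degree heterogeneity raises relative nestedness", {
  deltas <- vapply(1:20, function(seed) {
    hot <- generateWeb(S = 30, nGroups = 2, pIn = 0.25, pOut = 0.05,
                       lambda = 2, seed = seed)
    flat <- generateWeb(S = 30, nGroups = 2, pIn = 0.25, pOut = 0.05,
                        lambda = 0, seed = seed)
    nHot <- suppressWarnings(
      nestednessAnalysis(hot, replicates = 60, seed = seed))
    nFlat <- suppressWarnings(
      nestednessAnalysis(flat, replicates = 60, seed = seed))
    nHot@nStar - nFlat@nStar
  }, numeric(1))
  expect_gt(mean(deltas), 0)
  expect_gt(mean(deltas > 0), 0.6)
})

test_that("generator draws are reproducible and respect invariants", {
  fw1 <- generateWeb(S = 25, seed = 13)
  fw2 <- generateWeb(S = 25, seed = 13)
  expect_identical(adjacency(fw1), adjacency(fw2))
  expect_error(generateWeb(S = 5), "at least 10")
  expect_error(generateWeb(S = 20, pIn = 0.2, pOut = 0.5), "pOut <= pIn")
  expect_warning(generateWeb(S = 20, pIn = 0.9, pOut = 0.9, seed = 1),
                 "fill")
})

test_that("unbiased parasites use hosts uniformly", {
  fw <- generateWeb(S = 20, nGroups = 1, pIn = 0.25, lambda = 0, seed = 17)
  recs <- generateParasites(fw, nParasites = 2000,
                            stageProbs = c(1, 0, 0), beta = 0,
                            hostsPerStage = 1, seed = 17)
  counts <- table(factor(recordsTable(recs)$hosts,
                         levels = speciesLabels(fw)))
  expect_gt(stats::chisq.test(counts)$p.value, 0.01)
})

test_that("strong centrality bias concentrates parasites on central hosts", {
  fw <- generateWeb(S = 50, seed = 19)
  recs <- generateParasites(fw, nParasites = 200, beta = 5,
                            hostsPerStage = 2, seed = 19)
  cs <- centralitySuite(fw)
  ev <- setNames(cs$eigenvector, cs$label)
  hosts <- unlist(strsplit(recordsTable(recs)$hosts, ";"))
  uses <- table(factor(hosts, levels = speciesLabels(fw)))
  qs <- quantile(ev, c(0.1, 0.9))
  topShare <- sum(uses[ev >= qs[2]])
  bottomShare <- sum(uses[ev <= qs[1]])
  expect_gt(topShare, bottomShare)
})

test_that("generated parasites always pass the viability filter", {
  for (beta in c(0, 1, 3)) {
    fw <- generateWeb(S = 30, seed = 23 + beta)
    recs <- suppressWarnings(
      generateParasites(fw, nParasites = 15, beta = beta,
                        seed = 29 + beta))
    v <- filterViableParasites(fw, recs)
    expect_equal(nParasites(v), 15L)
  }
})

test_that("single-stage parasites are viable wherever their host occurs", {
  fw <- generateWeb(S = 20, seed = 31)
  recs <- suppressWarnings(
    generateParasites(fw, nParasites = 10, stageProbs = c(1, 0, 0),
                      seed = 31))
  v <- filterViableParasites(fw, recs)
  expect_equal(nParasites(v), 10L)
})

test_that("parasite generation fails cleanly on a linkless web", {
  a <- labelled(matrix(0L, 12, 12))
  fw <- FoodWeb(a)
  expect_error(generateParasites(fw, nParasites = 3,
                                 stageProbs = c(0, 1, 0), seed = 1))
})

test_that("planted group labels beat random relabelings on generated webs", {
  for (seed in c(3, 8)) {
    fw <- generateWeb(S = 40, nGroups = 4, pIn = 0.35, pOut = 0.04,
                      lambda = 0, seed = seed)
    planted <- groupLoglikAic(fw, plantedGroups(fw))@aic
    set.seed(seed)
    rand <- replicate(100, {
      part <- c(1:4, sample.int(4, 36, replace = TRUE))
      groupLoglikAic(fw, part)@aic
    })
    expect_true(all(planted <= rand))
  }
})
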