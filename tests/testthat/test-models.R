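# Synthetic predictor tables with independent columns, for planted-signal
# recovery without the collinearity of real webs.
syntheticRows <- function(n, seed, signal = c(G = 0)) {
  set.seed(seed)
  rows <- data.frame(
    web = "syn", label = sprintf("r%03d", seq_len(n)),
    eigenvector = runif(n), betweenness = runif(n, 0, 80),
    closeness = runif(n, 0.3, 0.8), degree = sample(1:70, n, TRUE),
    group = factor(sample(paste0("syn.g", 1:5), n, TRUE)),
    coreness = runif(n, 0, 0.4), marsh_diversity = 100,
    G = sample(0:50, n, TRUE), V = sample(0:60, n, TRUE),
    stringsAsFactors = FALSE)
  mu <- rep(0, n)
  for (v in names(signal))
    mu <- mu + signal[[v]] * scale(rows[[v]])[, 1]
  rows$richness <- pmax(0, round(5 + mu + rnorm(n)))
  rows
}

test_that("the predictor table joins all metrics per (web, species)", {
  fw1 <- generateWeb(S = 25, seed = 1)
  fw2 <- generateWeb(S = 30, seed = 2)
  recs <- generateParasites(fw1, nParasites = 8, seed = 3)
  rows <- buildPredictorTable(
    list(a = fw1, b = fw2),
    partitions = list(a = plantedGroups(fw1), b = plantedGroups(fw2)),
    records = recs)
  expect_equal(nrow(rows), 55)
  expect_setequal(unique(rows$marsh_diversity), c(25, 30))
  expect_true(all(tapply(rows$marsh_diversity, rows$web,
                         function(x) length(unique(x))) == 1))
  # groups are web-qualified: group 1 of web a is not group 1 of web b
  expect_false(any(levels(rows$group) %in%
                     intersect(paste0("a.g", 1:9), paste0("b.g", 1:9))))
  expect_false(anyNA(rows))
})

test_that("a species missing from a component table is a hard error", {
  fw <- generateWeb(S = 25, seed = 4)
  inc <- hostRichness(fw, generateParasites(fw, nParasites = 5, seed = 5))
  incBad <- inc[-3, ]
  expect_error(
    buildPredictorTable(list(w = fw),
                        partitions = list(w = plantedGroups(fw)),
                        incidences = list(w = incBad)),
    "missing from a component table.*sp003")
  expect_error(
    buildPredictorTable(list(w = fw), partitions = list(),
                        incidences = list(w = inc)),
    "no partition")
})

test_that("a constant response yields a stump with zero pseudo-R2", {
  rows <- syntheticRows(60, seed = 1)
  rows$richness <- 4
  tf <- fitRegressionTree(rows, seed = 1)
  expect_equal(sum(tf$tree$frame$var == "<leaf>"), 1)
  expect_equal(tf$pseudoR2, 0)
})

test_that("a planted linear signal is recovered by the tree", {
  rows <- syntheticRows(300, seed = 2, signal = c(G = 3))
  tf <- fitRegressionTree(rows, seed = 2)
  expect_equal(as.character(tf$tree$frame$var[1]), "G")
  expect_equal(names(which.max(tf$importance)), "G")
  expect_gt(tf$pseudoR2, 0.5)
  expect_named(tf$importance, c("eigenvector", "betweenness", "closeness",
                                "degree", "group", "coreness",
                                "marsh_diversity", "G", "V"))
})

test_that("training error never increases along the tree's growing path", {
  rows <- syntheticRows(200, seed = 3, signal = c(G = 2, eigenvector = 1))
  tf <- fitRegressionTree(rows, seed = 3, pruneRule = "min")
  expect_true(all(diff(tf$cpTable[, "rel error"]) <= 1e-12))
  # the 1-SE tree is never larger than the CV-minimum tree
  t1 <- fitRegressionTree(rows, seed = 3, pruneRule = "1se")
  expect_lte(sum(t1$tree$frame$var == "<leaf>"),
             sum(tf$tree$frame$var == "<leaf>"))
})

test_that("pure-noise forests have importances indistinguishable from zero", {
  # per-tree SEs understate sampling noise (trees share the data), so the
  # null check is error-relative: permuting any predictor moves the OOB MSE
  # by only a few percent, and the forest has no OOB skill
  rows <- syntheticRows(300, seed = 4)
  ff <- fitRandomForest(rows, nTrees = 500, seed = 4)
  oobMse <- ff$forest$mse[ff$nTrees]
  expect_true(all(abs(ff$importancePermutation) <= 0.1 * oobMse))
  expect_lte(ff$pseudoR2, 0.05)
})

test_that("forests rank planted signals by effect size", {
  rows <- syntheticRows(300, seed = 5, signal = c(G = 3, eigenvector = 1))
  ff <- fitRandomForest(rows, nTrees = 500, seed = 5)
  imp <- ff$importancePermutation
  expect_equal(names(sort(imp, decreasing = TRUE))[1:2],
               c("G", "eigenvector"))
  expect_gt(ff$pseudoR2, 0.4)
  expect_warning(fitRandomForest(rows, nTrees = 30, seed = 1), "unstable")
})

test_that("forest skill grows with signal-to-noise ratio", {
  r2 <- vapply(c(0.5, 2, 6), function(effect) {
    rows <- syntheticRows(250, seed = 6, signal = c(G = effect))
    fitRandomForest(rows, nTrees = 300, seed = 6)$pseudoR2
  }, numeric(1))
  expect_true(all(diff(r2) > 0))
})

test_that("tree and forest fits are reproducible from their seeds", {
  rows <- syntheticRows(120, seed = 7, signal = c(G = 2))
  f1 <- fitRandomForest(rows, nTrees = 200, seed = 11)
  f2 <- fitRandomForest(rows, nTrees = 200, seed = 11)
  expect_identical(f1$importancePermutation, f2$importancePermutation)
  expect_identical(f1$pseudoR2, f2$pseudoR2)
  t1 <- fitRegressionTree(rows, seed = 11)
  t2 <- fitRegressionTree(rows, seed = 11)
  expect_identical(t1$cp, t2$cp)
  expect_identical(t1$importance, t2$importance)
})

test_that("the importance report flags variables shared by both models", {
  rows <- syntheticRows(300, seed = 8, signal = c(G = 3, eigenvector = 2))
  tf <- fitRegressionTree(rows, seed = 8)
  ff <- fitRandomForest(rows, nTrees = 300, seed = 8)
  rep <- importanceReport(treeFits = list(all = tf),
                          forestFits = list(all = ff))
  expect_equal(nrow(rep$report), 2)
  expect_named(rep$report, c("model_type", "site", "r2", "top4_variables"))
  top4 <- strsplit(rep$report$top4_variables[1], ", ")[[1]]
  expect_length(top4, 4)
  expect_true(all(top4 %in% names(tf$importance)))
  expect_true(all(c("G", "eigenvector") %in% rep$importantInBoth$all))
})
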