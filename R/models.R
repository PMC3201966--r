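# Predicting per-host parasite richness from topological predictors:
# the per-host predictor table, cost-complexity-pruned regression trees,
# 1000-tree random forests, and the two variable-importance measures.

.PREDICTORS <- c("eigenvector", "betweenness", "closeness", "degree",
                 "group", "coreness", "marsh_diversity", "G", "V")

#' Assemble the per-host predictor table
#'
#' Joins, per web and species, the nine topological predictors -- eigenvector,
#' betweenness, closeness, degree, group membership, coreness, marsh
#' diversity (the S of the host's web), trophic generality G and trophic
#' vulnerability V -- with the per-host parasite richness response.  Group
#' membership is encoded as a web-qualified unordered factor (group 3 of one
#' marsh is unrelated to group 3 of another).  Any species missing from a
#' supplied component table is a hard error, never an NA.
#'
#' @param webs named list of [FoodWeb-class] objects (names are web labels).
#' @param partitions named list of per-species group indices (one per web),
#'   e.g. from [annealPartition()] partitions or [plantedGroups()].
#' @param records a [ParasiteRecords-class] applied to every web (filtered
#'   for viability per web), or `NULL` when `incidences` is given.
#' @param incidences optional named list of per-web incidence tables
#'   (data.frames with `label`, `richness`, as from [hostRichness()]).
#' @param centralities,corenesses optional named lists of precomputed
#'   [centralitySuite()] tables / [CorePeripheryResult-class] objects;
#'   computed from the webs when `NULL`.
#' @return data.frame with one row per (web, label): the nine predictors and
#'   the `richness` response.
#' @export
buildPredictorTable <- function(webs, partitions, records = NULL,
                                incidences = NULL, centralities = NULL,
                                corenesses = NULL) {
  stopifnot(is.list(webs), length(webs) > 0, !is.null(names(webs)))
  if (is.null(records) && is.null(incidences))
    stop("supply either parasite records or per-web incidence tables")
  out <- lapply(names(webs), function(wn) {
    web <- webs[[wn]]
    labels <- speciesLabels(web)
    cs <- if (is.null(centralities)) centralitySuite(web)
          else centralities[[wn]]
    cp <- if (is.null(corenesses)) corenessMinres(web) else corenesses[[wn]]
    gv <- generalityVulnerability(web)
    part <- partitions[[wn]]
    if (is.null(part)) stop("no partition supplied for web '", wn, "'")
    pp <- .checkPartition(part, labels)
    inc <- if (!is.null(incidences)) incidences[[wn]]
           else hostRichness(web, filterViableParasites(web, records,
                                                        warnUnknown = FALSE))
    for (tab in list(cs, gv, inc)) {
      missing <- setdiff(labels, tab$label)
      if (length(missing))
        stop("species missing from a component table for web '", wn, "': ",
             paste(missing, collapse = ", "))
    }
    cor_ <- cp@coreness[labels]
    if (any(is.na(cor_)))
      stop("species missing coreness for web '", wn, "'")
    data.frame(
      web = wn, label = labels,
      eigenvector = cs$eigenvector[match(labels, cs$label)],
      betweenness = cs$betweenness[match(labels, cs$label)],
      closeness = cs$closeness[match(labels, cs$label)],
      degree = cs$degree[match(labels, cs$label)],
      group = paste0(wn, ".g", pp$partition),
      coreness = unname(cor_),
      marsh_diversity = nSpecies(web),
      G = gv$G[match(labels, gv$label)],
      V = gv$V[match(labels, gv$label)],
      richness = inc$richness[match(labels, inc$label)],
      stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  res$group <- factor(res$group)
  rownames(res) <- NULL
  res
}

#' Cost-complexity-pruned regression tree of parasite richness
#'
#' A CART regression (squared-error loss) of per-host parasite richness on
#' the nine topological predictors, grown deep and pruned along the
#' cost-complexity path by 10-fold cross-validation.  The default pruning
#' rule is the 1-SE rule (the smallest tree whose CV error is within one
#' standard error of the minimum); `pruneRule = "min"` selects the
#' CV-minimum tree instead.  Surrogate splits are disabled: the table has no
#' missing values by construction, and importance is the pure per-variable
#' summed loss reduction over the splits that use it.
#'
#' @param rows predictor table from [buildPredictorTable()] (>= 20 rows).
#' @param cvFolds cross-validation folds.
#' @param seed integer seed for the CV fold assignment.
#' @param pruneRule `"1se"` (default) or `"min"`.
#' @return object of class `"treeFit"`: list with the pruned `rpart` tree,
#'   `pseudoR2` (training 1 - SSE/SST), `importance` over all nine
#'   predictors, the `cpTable` and the selected `cp`.
#' @export
fitRegressionTree <- function(rows, cvFolds = 10L, seed = 1L,
                              pruneRule = c("1se", "min")) {
  pruneRule <- match.arg(pruneRule)
  if (nrow(rows) < 20L) stop("need at least 20 rows to fit a tree")
  if (any(rows$richness < 0)) stop("richness must be non-negative")
  old <- .saveSeed(); on.exit(.restoreSeed(old))
  set.seed(as.integer(seed))
  dat <- rows[, c(.PREDICTORS, "richness")]
  dat$group <- droplevels(factor(dat$group))
  fit <- rpart::rpart(richness ~ ., data = dat, method = "anova",
                      control = rpart::rpart.control(
                        cp = 1e-4, xval = cvFolds, maxsurrogate = 0,
                        usesurrogate = 0))
  cpt <- fit$cptable
  if (nrow(cpt) > 1L) {
    minIdx <- which.min(cpt[, "xerror"])
    cpSel <- if (pruneRule == "min") cpt[minIdx, "CP"] else {
      thr <- cpt[minIdx, "xerror"] + cpt[minIdx, "xstd"]
      cpt[which(cpt[, "xerror"] <= thr)[1L], "CP"]
    }
    fit <- rpart::prune(fit, cp = cpSel)
  } else cpSel <- cpt[1L, "CP"]
  y <- dat$richness
  sst <- sum((y - mean(y))^2)
  sse <- sum((y - stats::predict(fit))^2)
  imp <- stats::setNames(numeric(length(.PREDICTORS)), .PREDICTORS)
  if (!is.null(fit$variable.importance)) {
    vi <- fit$variable.importance
    imp[names(vi)] <- vi
  }
  structure(list(tree = fit, pseudoR2 = if (sst > 0) 1 - sse / sst else 0,
                 importance = imp, cpTable = cpt, cp = cpSel,
                 seed = as.integer(seed)),
            class = "treeFit")
}

#' Random forest of parasite richness
#'
#' Bootstrap-aggregated regression trees (default 1000) with
#' `mtry = ceiling(p / 3)` over the nine topological predictors.  Reports
#' the out-of-bag pseudo-R2 (1 - MSE_oob / Var(y)) and both importance
#' measures: the raw permutation increase in out-of-bag MSE, and the total
#' decrease in node impurity averaged over trees.
#'
#' @param rows predictor table from [buildPredictorTable()] (>= 20 rows).
#' @param nTrees number of trees (a warning below 50: importances are then
#'   unstable).
#' @param seed integer RNG seed.
#' @param mtry predictors tried per split (default `ceiling(p / 3)`).
#' @return object of class `"forestFit"`: list with the `randomForest`
#'   object, `pseudoR2` (OOB), `importancePermutation`,
#'   `importanceImpurity`, `nTrees`, `mtry`, `seed`.
#' @export
fitRandomForest <- function(rows, nTrees = 1000L, seed = 1L, mtry = NULL) {
  if (nrow(rows) < 20L) stop("need at least 20 rows to fit a forest")
  if (any(rows$richness < 0)) stop("richness must be non-negative")
  if (nTrees < 50L) warning("fewer than 50 trees gives unstable importances")
  old <- .saveSeed(); on.exit(.restoreSeed(old))
  set.seed(as.integer(seed))
  x <- rows[, .PREDICTORS]
  x$group <- droplevels(factor(x$group))
  y <- rows$richness
  if (is.null(mtry)) mtry <- ceiling(length(.PREDICTORS) / 3)
  fit <- randomForest::randomForest(x = x, y = y, ntree = nTrees,
                                    mtry = mtry, importance = TRUE)
  imp <- randomForest::importance(fit, scale = FALSE)
  structure(list(forest = fit, pseudoR2 = fit$rsq[nTrees],
                 importancePermutation = imp[, "%IncMSE"],
                 importanceImpurity = imp[, "IncNodePurity"],
                 nTrees = as.integer(nTrees), mtry = mtry,
                 seed = as.integer(seed)),
            class = "forestFit")
}

#' @export
print.treeFit <- function(x, ...) {
  cat(sprintf("Regression tree: %d terminal nodes, pseudo-R2 = %.3f\n",
              sum(x$tree$frame$var == "<leaf>"), x$pseudoR2))
  invisible(x)
}

#' @export
print.forestFit <- function(x, ...) {
  cat(sprintf("Random forest: %d trees, mtry = %d, OOB pseudo-R2 = %.3f\n",
              x$nTrees, x$mtry, x$pseudoR2))
  invisible(x)
}

.top4 <- function(imp) names(sort(imp, decreasing = TRUE))[1:4]

#' Ranked variable-importance report
#'
#' Mirrors the standard presentation of tree/forest results: per model the
#' pseudo-R2 and the four most important predictors, plus -- when a site has
#' both a tree and a forest -- the set of variables considered important in
#' both (appearing in both top-4 lists).
#'
#' @param treeFits named list of `"treeFit"` objects (names are sites).
#' @param forestFits named list of `"forestFit"` objects.
#' @return list with `report` (data.frame: model_type, site, r2,
#'   top4_variables) and `importantInBoth` (named list per shared site).
#' @export
importanceReport <- function(treeFits = list(), forestFits = list()) {
  rep1 <- lapply(names(treeFits), function(s) data.frame(
    model_type = "regression_tree", site = s,
    r2 = treeFits[[s]]$pseudoR2,
    top4_variables = paste(.top4(treeFits[[s]]$importance),
                           collapse = ", "),
    stringsAsFactors = FALSE))
  rep2 <- lapply(names(forestFits), function(s) data.frame(
    model_type = "random_forest", site = s,
    r2 = forestFits[[s]]$pseudoR2,
    top4_variables = paste(.top4(forestFits[[s]]$importancePermutation),
                           collapse = ", "),
    stringsAsFactors = FALSE))
  both <- lapply(stats::setNames(nm = intersect(names(treeFits),
                                                names(forestFits))),
                 function(s) intersect(.top4(treeFits[[s]]$importance),
                                       .top4(forestFits[[s]]$importancePermutation)))
  list(report = do.call(rbind, c(rep1, rep2)), importantInBoth = both)
}
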