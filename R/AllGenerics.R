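# Generics for the FoodWeb verbs.  Methods live next to their implementations.

#' @export
setGeneric("basicMetrics", function(web, ...) standardGeneric("basicMetrics"))

#' @export
setGeneric("generalityVulnerability", function(web, ...)
  standardGeneric("generalityVulnerability"))

#' @export
setGeneric("cumulativeDegreeDistribution", function(web, ...)
  standardGeneric("cumulativeDegreeDistribution"))

#' @export
setGeneric("matrixTemperature", function(x, ...)
  standardGeneric("matrixTemperature"))

#' @export
setGeneric("nestednessAnalysis", function(web, ...)
  standardGeneric("nestednessAnalysis"))

#' @export
setGeneric("centralitySuite", function(web, ...)
  standardGeneric("centralitySuite"))

#' @export
setGeneric("corenessMinres", function(web, ...)
  standardGeneric("corenessMinres"))

#' @export
setGeneric("groupLoglikAic", function(web, partition, ...)
  standardGeneric("groupLoglikAic"))

#' @export
setGeneric("annealPartition", function(web, g, ...)
  standardGeneric("annealPartition"))

#' @export
setGeneric("scanGroupSizes", function(web, gRange, ...)
  standardGeneric("scanGroupSizes"))

#' @export
setGeneric("writeAdjacency", function(web, path, ...)
  standardGeneric("writeAdjacency"))

# -- accessors ---------------------------------------------------------------

#' Species labels of a food web
#' @param web a [FoodWeb-class]
#' @return character vector of labels in matrix order.
#' @export
setGeneric("speciesLabels", function(web) standardGeneric("speciesLabels"))

#' @describeIn speciesLabels method for FoodWeb
#' @export
setMethod("speciesLabels", "FoodWeb", function(web) rownames(web@adj))

#' Adjacency matrix of a food web
#' @param web a [FoodWeb-class]
#' @return the integer consumer-by-resource matrix.
#' @export
setGeneric("adjacency", function(web) standardGeneric("adjacency"))

#' @describeIn adjacency method for FoodWeb
#' @export
setMethod("adjacency", "FoodWeb", function(web) web@adj)

#' Number of species S
#' @param web a [FoodWeb-class]
#' @export
setGeneric("nSpecies", function(web) standardGeneric("nSpecies"))

#' @describeIn nSpecies method for FoodWeb
#' @export
setMethod("nSpecies", "FoodWeb", function(web) nrow(web@adj))

#' Number of observed links L_o
#' @param web a [FoodWeb-class]
#' @export
setGeneric("linkCount", function(web) standardGeneric("linkCount"))

#' @describeIn linkCount method for FoodWeb
#' @export
setMethod("linkCount", "FoodWeb", function(web) sum(web@adj))

#' Species categories
#' @param web a [FoodWeb-class]
#' @return named character vector of tags (possibly empty).
#' @export
setGeneric("speciesCategories", function(web)
  standardGeneric("speciesCategories"))

#' @describeIn speciesCategories method for FoodWeb
#' @export
setMethod("speciesCategories", "FoodWeb", function(web) web@category)

#' Planted group labels of a synthetic web
#' @param web a [SyntheticFoodWeb-class]
#' @export
setGeneric("plantedGroups", function(web) standardGeneric("plantedGroups"))

#' @describeIn plantedGroups method for SyntheticFoodWeb
#' @export
setMethod("plantedGroups", "SyntheticFoodWeb", function(web)
  web@plantedGroups)

#' Records table of a ParasiteRecords object
#' @param x a [ParasiteRecords-class]
#' @return the long-format data.frame (one row per parasite stage).
#' @export
setGeneric("recordsTable", function(x) standardGeneric("recordsTable"))

#' @describeIn recordsTable method for ParasiteRecords
#' @export
setMethod("recordsTable", "ParasiteRecords", function(x) x@table)

#' Number of parasites in a record set
#' @param x a [ParasiteRecords-class]
#' @export
setGeneric("nParasites", function(x) standardGeneric("nParasites"))

#' @describeIn nParasites method for ParasiteRecords
#' @export
setMethod("nParasites", "ParasiteRecords", function(x)
  length(unique(x@table$parasite)))

# -- show methods ------------------------------------------------------------

setMethod("show", "FoodWeb", function(object) {
  n <- nrow(object@adj)
  lo <- sum(object@adj)
  cat(class(object), "with", n, "species and", lo, "links",
      sprintf("(connectance %.4f)\n", lo / n^2))
  lab <- rownames(object@adj)
  cat("  species:", paste(utils::head(lab, 5), collapse = ", "),
      if (n > 5) sprintf("... (%d more)", n - 5) else "", "\n")
})

setMethod("show", "NestednessResult", function(object) {
  cat("NestednessResult for", object@web, "\n")
  cat(sprintf("  T = %.2f  N = %.4f  null N = %.4f (sd %.4f)\n",
              object@temperature, object@nestedness, object@nullMean,
              object@nullSd))
  cat(sprintf("  n* = %.3f  p = %.4g  (%d null replicates, seed %d)\n",
              object@nStar, object@pValue, object@replicates, object@seed))
})

setMethod("show", "GroupModelResult", function(object) {
  cat(sprintf("GroupModelResult: g = %d, loglik = %.3f, AIC = %.3f (%d parameters)\n",
              object@g, object@loglik, object@aic, object@nParams))
  cat("  group sizes:", paste(tabulate(object@partition, object@g),
                              collapse = ", "), "\n")
})

setMethod("show", "CorePeripheryResult", function(object) {
  cat(sprintf("CorePeripheryResult: fit = %.3f, %d iterations (%s)\n",
              object@fit, object@iterations,
              if (object@converged) "converged" else "not converged"))
  cat(sprintf("  coreness range: %.4f - %.4f\n",
              min(object@coreness), max(object@coreness)))
})

setMethod("show", "ParasiteRecords", function(object) {
  tab <- object@table
  np <- length(unique(tab$parasite))
  cat("ParasiteRecords:", np, "parasites,", nrow(tab), "stages\n")
  if (np) {
    ns <- table(table(tab$parasite))
    cat("  stage counts:",
        paste(sprintf("%s-stage: %d", names(ns), ns), collapse = ", "), "\n")
  }
})
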