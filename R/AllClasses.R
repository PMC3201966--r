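#' @import methods
NULL

#' FoodWeb: a labelled binary predator-prey matrix
#'
#' The central data container: a square binary adjacency matrix in which
#' `A[i, j] == 1` means species `i` (the consumer) eats species `j` (the
#' resource).  Rows are consumers, columns are resources; every module in the
#' package depends on this single orientation.  Diagonal entries are permitted
#' and represent cannibalism; a cannibalistic link is counted once in the link
#' total and contributes to both the generality and the vulnerability of the
#' species.
#'
#' @slot adj square integer matrix with entries in \{0, 1\}; identical,
#'   unique, non-empty row and column names give the species labels.
#' @slot category optional per-species tags (e.g. basal / invertebrate /
#'   fish / bird), named by species label; may be empty.
#'
#' @seealso [FoodWeb()], [readAdjacency()], [basicMetrics()]
#' @exportClass FoodWeb
setClass("FoodWeb", representation(adj = "matrix", category = "character"))

setValidity("FoodWeb", function(object) {
  a <- object@adj
  if (!is.numeric(a) && !is.integer(a))
    return("adjacency matrix must be numeric")
  if (nrow(a) != ncol(a))
    return(sprintf("adjacency matrix must be square (got %d x %d)",
                   nrow(a), ncol(a)))
  if (nrow(a) < 1L)
    return("food web must contain at least one species")
  rl <- rownames(a); cl <- colnames(a)
  if (is.null(rl) || is.null(cl))
    return("adjacency matrix must carry species labels as dimnames")
  if (!identical(rl, cl))
    return("row labels and column labels must match in order")
  if (anyDuplicated(rl))
    return(sprintf("duplicate species labels: %s",
                   paste(unique(rl[duplicated(rl)]), collapse = ", ")))
  if (any(!nzchar(rl)))
    return("species labels must be non-empty strings")
  if (!all(a %in% c(0, 1)))
    return("adjacency entries must be 0 or 1")
  if (length(object@category) &&
      (is.null(names(object@category)) ||
       !all(names(object@category) %in% rl)))
    return("category tags must be named by species labels present in the web")
  TRUE
})

#' Construct a FoodWeb
#'
#' @param adj square 0/1 matrix with identical row and column names (the
#'   species labels).  Logical matrices are coerced.  Rows are consumers,
#'   columns resources.
#' @param category optional character vector of per-species tags, named by
#'   species label.
#' @return a validated [FoodWeb-class] object.
#' @examples
#' a <- matrix(c(0, 1, 0, 0), 2, 2, byrow = TRUE,
#'             dimnames = list(c("fish", "snail"), c("fish", "snail")))
#' fw <- FoodWeb(a)
#' linkCount(fw)
#' @export
FoodWeb <- function(adj, category = character()) {
  if (is.logical(adj)) adj[] <- as.integer(adj)
  storage.mode(adj) <- "integer"
  new("FoodWeb", adj = adj, category = category)
}

#' Synthetic food web with planted structure
#'
#' A [FoodWeb-class] that additionally records the generating block structure
#' of [generateWeb()]: the planted group label of every species and the
#' degree-heterogeneity propensity used when the web was drawn.
#'
#' @slot plantedGroups integer group index per species, named by label.
#' @slot propensity numeric per-species link propensity, named by label.
#' @exportClass SyntheticFoodWeb
setClass("SyntheticFoodWeb", contains = "FoodWeb",
         representation(plantedGroups = "integer", propensity = "numeric"))

setValidity("SyntheticFoodWeb", function(object) {
  n <- nrow(object@adj)
  if (length(object@plantedGroups) != n)
    return("plantedGroups must have one entry per species")
  if (length(object@propensity) != n)
    return("propensity must have one entry per species")
  TRUE
})

#' Nestedness analysis result
#'
#' Output of [nestednessAnalysis()]: the observed matrix temperature T (0 =
#' perfectly nested, 100 = maximally disordered), nestedness N = (100 - T) /
#' 100, the null-ensemble summary under the row/column-fill (Ce) null model,
#' the one-sided p-value and the relative nestedness
#' n* = (N - Nbar) / Nbar.
#'
#' @slot web label of the analysed web.
#' @slot temperature observed matrix temperature in \[0, 100\].
#' @slot nestedness N = (100 - T) / 100.
#' @slot nullMean,nullSd mean and SD of N over the null ensemble.
#' @slot pValue pseudo-count p-value: fraction of null matrices at least as
#'   nested (temperature less than or equal to the observed one).
#' @slot nStar relative nestedness (N - nullMean) / nullMean.
#' @slot replicates,seed ensemble size and RNG seed.
#' @exportClass NestednessResult
setClass("NestednessResult",
         representation(web = "character", temperature = "numeric",
                        nestedness = "numeric", nullMean = "numeric",
                        nullSd = "numeric", pValue = "numeric",
                        nStar = "numeric", replicates = "integer",
                        seed = "integer"))

setValidity("NestednessResult", function(object) {
  if (object@temperature < 0 || object@temperature > 100)
    return("temperature must lie in [0, 100]")
  if (object@pValue < 0 || object@pValue > 1)
    return("pValue must lie in [0, 1]")
  TRUE
})

#' Group (block) model fit
#'
#' A partition of the species into g groups together with the maximum
#' likelihood block link probabilities p_kl = L_kl / N_kl, the Bernoulli
#' log-likelihood of the directed web under the block model, and its AIC.
#'
#' @slot partition integer group index (1..g) per species, named by label.
#' @slot g number of groups.
#' @slot pkl g x g matrix of estimated link probabilities (consumer group k
#'   eating resource group l).
#' @slot loglik,nParams,aic fit statistics; aic = -2 loglik + 2 nParams.
#' @slot seed,restarts provenance of the annealing search (NA for a direct
#'   likelihood evaluation).
#' @exportClass GroupModelResult
setClass("GroupModelResult",
         representation(partition = "integer", g = "integer", pkl = "matrix",
                        loglik = "numeric", nParams = "integer",
                        aic = "numeric", seed = "integer",
                        restarts = "integer"))

setValidity("GroupModelResult", function(object) {
  if (any(object@pkl < 0 | object@pkl > 1))
    return("block probabilities must lie in [0, 1]")
  if (!isTRUE(all.equal(object@aic,
                        -2 * object@loglik + 2 * object@nParams)))
    return("aic must equal -2 loglik + 2 nParams")
  TRUE
})

#' Continuous core/periphery (MINRES) fit
#'
#' Per-species coreness scores c >= 0 minimising the off-diagonal residual
#' sum of squares between the symmetrised adjacency matrix and the
#' outer-product pattern c c'.
#'
#' @slot coreness non-negative score per species, named by label.
#' @slot fit Pearson correlation between the off-diagonal entries of the
#'   symmetrised adjacency and of the fitted pattern.
#' @slot iterations,converged optimisation diagnostics.
#' @exportClass CorePeripheryResult
setClass("CorePeripheryResult",
         representation(coreness = "numeric", fit = "numeric",
                        iterations = "integer", converged = "logical"))

setValidity("CorePeripheryResult", function(object) {
  if (any(!is.finite(object@coreness)) || any(object@coreness < 0))
    return("coreness scores must be finite and non-negative")
  if (is.finite(object@fit) && abs(object@fit) > 1 + 1e-8)
    return("fit must be a correlation in [-1, 1]")
  TRUE
})

#' Parasite life-cycle records
#'
#' An ordered-stage representation of parasite life cycles: one row per
#' (parasite, stage), stage 1 being the first intermediate host stage and the
#' final stage the definitive host.  Each stage carries the set of suitable
#' host labels (semicolon separated in the tabular form) and the transmission
#' mode by which that stage is acquired (`trophic`, `direct` or `vector`).
#' The reserved host label `"environment"` marks free-living stages and is
#' treated as present in every web.
#'
#' @slot table data.frame with columns parasite, stage_index, stage_role,
#'   transmission, hosts, source.
#' @seealso [parasiteRecords()], [filterViableParasites()]
#' @exportClass ParasiteRecords
setClass("ParasiteRecords", representation(table = "data.frame"))

setValidity("ParasiteRecords", function(object) {
  tab <- object@table
  need <- c("parasite", "stage_index", "stage_role", "transmission",
            "hosts", "source")
  if (!all(need %in% names(tab)))
    return(sprintf("records table must have columns: %s",
                   paste(need, collapse = ", ")))
  if (nrow(tab)) {
    if (!all(tab$transmission %in% c("trophic", "direct", "vector")))
      return("transmission must be one of trophic, direct, vector")
    if (any(!nzchar(tab$hosts)))
      return("every stage must list at least one suitable host")
    bad <- vapply(split(tab$stage_index, tab$parasite), function(s)
      !identical(sort(as.integer(s)), seq_along(s)), logical(1))
    if (any(bad))
      return(sprintf("stages must be numbered 1..k without gaps: %s",
                     paste(names(bad)[bad], collapse = ", ")))
  }
  TRUE
})
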