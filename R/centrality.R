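# Species-level positional metrics: eigenvector, betweenness, closeness
# (via igraph, on the symmetrised web) and a continuous MINRES
# core/periphery fit.

#' Eigenvector, betweenness, closeness and degree per species
#'
#' All three centralities are computed on the symmetrised (undirected,
#' loop-free) web: feeding direction is kept only in generality and
#' vulnerability, while positional importance treats a trophic interaction
#' as mutual contact.  Eigenvector centrality is the leading eigenvector of
#' the symmetrised adjacency, scaled so the maximum is exactly 1.
#' Betweenness is shortest-path betweenness with fractional credit among tied
#' geodesics and endpoints excluded, reported as raw pair counts (each
#' unordered pair counted once).  Closeness is (n - 1) / sum of geodesic
#' distances; on a disconnected web it is computed within components, with a
#' warning.  Degree is k = G + V from the directed matrix (a cannibalistic
#' link counts in both).
#'
#' @param web a [FoodWeb-class] with at least 2 species and at least 1 link.
#' @return data.frame with columns `label`, `eigenvector`, `betweenness`,
#'   `closeness`, `degree`.
#' @examples
#' fw <- generateWeb(S = 25, seed = 3)
#' head(centralitySuite(fw))
#' @export
setMethod("centralitySuite", "FoodWeb", function(web) {
  a <- web@adj
  if (nrow(a) < 2L) stop("centrality needs at least 2 species")
  if (sum(a) == 0L) stop("centrality is undefined on a web with no links")
  sym <- pmax(a, t(a))
  g <- igraph::graph_from_adjacency_matrix(sym, mode = "undirected",
                                           diag = FALSE)
  if (igraph::components(g)$no > 1L)
    warning("web is disconnected; closeness computed within components")
  # ARPACK draws its start vector from the RNG; pin it so scores are a
  # deterministic function of the web
  old <- .saveSeed(); on.exit(.restoreSeed(old))
  set.seed(1L)
  ev <- igraph::eigen_centrality(g)$vector
  ev <- ev / max(ev)
  btw <- igraph::betweenness(g, directed = FALSE)
  clo <- suppressWarnings(igraph::closeness(g, normalized = TRUE))
  clo[is.nan(clo)] <- 0  # isolated species: no reachable partners
  data.frame(label = rownames(a), eigenvector = unname(ev),
             betweenness = unname(btw), closeness = unname(clo),
             degree = unname(rowSums(a) + colSums(a)),
             stringsAsFactors = FALSE)
})

# Off-diagonal residual sum of squares of the core/periphery model.
.minresObjective <- function(a, cv) {
  e <- a - outer(cv, cv)
  sum(e^2) - sum(diag(e)^2)
}

#' Continuous core/periphery fit by MINRES
#'
#' Fits the continuous core/periphery model of a symmetrised web: find
#' non-negative coreness scores c minimising the off-diagonal residual
#' `sum_{i != j} (A_ij - c_i c_j)^2` (the diagonal is ignored).  Solved by
#' coordinate-wise least squares: each sweep updates
#' `c_i <- sum_{j != i} A_ij c_j / sum_{j != i} c_j^2` one species at a time,
#' so the objective never increases.  Species in the densely interacting
#' centre of the web get large scores; peripheral specialists get scores
#' near zero.
#'
#' @param web a [FoodWeb-class] (or binary matrix); symmetrised internally.
#' @param maxIter maximum number of sweeps.
#' @param tol relative objective-change convergence tolerance.
#' @param seed optional integer seed; when given, the starting vector is
#'   randomly perturbed (useful to check insensitivity to initialisation).
#' @return a [CorePeripheryResult-class]; if `maxIter` is exhausted the best
#'   iterate so far is returned with `converged = FALSE`.
#' @export
setMethod("corenessMinres", "FoodWeb",
          function(web, maxIter = 500L, tol = 1e-8, seed = NULL) {
  a <- pmax(web@adj, t(web@adj))
  diag(a) <- 0
  n <- nrow(a)
  if (sum(a) == 0) stop("core/periphery fit is undefined on a web with no links")
  deg <- rowSums(a)
  cv <- sqrt(deg / max(deg))
  cv[cv == 0] <- 1e-6
  if (!is.null(seed)) {
    old <- .saveSeed(); on.exit(.restoreSeed(old))
    set.seed(as.integer(seed))
    cv <- cv * stats::runif(n, 0.5, 1.5)
  }
  obj <- .minresObjective(a, cv)
  converged <- FALSE
  iter <- 0L
  for (iter in seq_len(maxIter)) {
    for (i in seq_len(n)) {
      denom <- sum(cv^2) - cv[i]^2
      if (denom > 0) cv[i] <- sum(a[i, ] * cv) / denom  # a[i,i]=0 drops j=i
    }
    newObj <- .minresObjective(a, cv)
    if (abs(obj - newObj) <= tol * max(1, abs(obj))) {
      obj <- newObj
      converged <- TRUE
      break
    }
    obj <- newObj
  }
  pattern <- outer(cv, cv)
  off <- upper.tri(a) | lower.tri(a)
  fitCor <- suppressWarnings(stats::cor(a[off], pattern[off]))
  names(cv) <- rownames(web@adj)
  new("CorePeripheryResult", coreness = cv,
      fit = if (is.na(fitCor)) NA_real_ else fitCor,
      iterations = iter, converged = converged)
})
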