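# Web-level summary statistics and degree-distribution model selection.

#' Basic food-web statistics
#'
#' Computes the classical web-level descriptors: species richness S, potential
#' links S^2 (every ordered pair of species including self-pairs), observed
#' links L_o, linkage density d = L_o / S and directed connectance
#' C = L_o / S^2.
#'
#' @param web a [FoodWeb-class].
#' @return one-row data.frame with columns `S`, `S2`, `Lo`, `d`, `C`.
#' @examples
#' fw <- generateWeb(S = 20, seed = 1)
#' basicMetrics(fw)
#' @export
setMethod("basicMetrics", "FoodWeb", function(web) {
  s <- nrow(web@adj)
  lo <- sum(web@adj)
  data.frame(S = s, S2 = s^2, Lo = lo, d = lo / s, C = lo / s^2)
})

#' Per-species trophic generality and vulnerability
#'
#' Generality G_i is the number of resources of species i (row sum);
#' vulnerability V_i is its number of consumers (column sum).  Both include a
#' cannibalistic self-link, and each sums to L_o over the web.
#'
#' @param web a [FoodWeb-class].
#' @return data.frame with columns `label`, `G`, `V`.
#' @export
setMethod("generalityVulnerability", "FoodWeb", function(web) {
  a <- web@adj
  data.frame(label = rownames(a), G = unname(rowSums(a)),
             V = unname(colSums(a)), stringsAsFactors = FALSE)
})

#' Cumulative degree distribution
#'
#' The total degree of species i is k_i = G_i + V_i (a cannibalistic link
#' counts in both).  P(k) is the fraction of species with degree k or more,
#' evaluated at every distinct observed degree; it is non-increasing and its
#' first value is 1.  Isolated species (k = 0) stay in the support.
#'
#' @param web a [FoodWeb-class].
#' @return data.frame with columns `k` (ascending distinct degrees) and `Pk`.
#' @export
setMethod("cumulativeDegreeDistribution", "FoodWeb", function(web) {
  a <- web@adj
  k <- rowSums(a) + colSums(a)
  ks <- sort(unique(k))
  pk <- vapply(ks, function(x) mean(k >= x), numeric(1))
  data.frame(k = as.numeric(ks), Pk = pk)
})

# Model functions for the three candidate degree distributions.  Each has a
# free amplitude; K (for AICc) counts amplitude + shape parameter(s) + 1 for
# the residual variance.  Warm starts come from log-linear regressions; the
# truncated model (which nests both others and is often barely identifiable)
# gets one start from each limit.
.degreeModels <- list(
  exponential = list(
    fn = function(k, par) par["a"] * exp(-par["gamma"] * k), K = 3L,
    starts = function(k, p) {
      co <- stats::coef(stats::lm(log(p) ~ k))
      list(c(a = exp(unname(co[1])), gamma = max(1e-6, -unname(co[2]))))
    }),
  power_law = list(
    fn = function(k, par) par["a"] * k^(-par["gamma"]), K = 3L,
    starts = function(k, p) {
      co <- stats::coef(stats::lm(log(p) ~ log(k)))
      c(list(c(a = exp(unname(co[1])), gamma = max(1e-6, -unname(co[2])))),
        lapply(c(0.5, 1, 2), function(g)
          c(a = p[1] * k[1]^g, gamma = g)))
    }),
  truncated_power_law = list(
    fn = function(k, par)
      par["a"] * k^(-par["gamma"]) * exp(-k / par["kx"]), K = 4L,
    starts = function(k, p) {
      cp <- stats::coef(stats::lm(log(p) ~ log(k)))
      ce <- stats::coef(stats::lm(log(p) ~ k))
      list(c(a = exp(unname(cp[1])), gamma = max(1e-6, -unname(cp[2])),
             kx = 2 * max(k)),
           c(a = exp(unname(ce[1])), gamma = 1e-3,
             kx = 1 / max(1e-6, -unname(ce[2]))),
           c(a = p[1] * k[1], gamma = 1, kx = max(k)))
    })
)

# Least-squares fit of one model by Levenberg-Marquardt over all warm
# starts; best (lowest RSS among converged starts) wins.
.fitDegreeModel <- function(m, k, p) {
  best <- NULL
  for (start in m$starts(k, p)) {
    res <- tryCatch(
      minpack.lm::nls.lm(par = start,
                         fn = function(par) p - m$fn(k, par),
                         lower = rep(1e-12, length(start)),
                         control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    # info 1-3: step/value convergence; 4: gradient orthogonal to residual
    if (is.null(res) || !res$info %in% 1:4) next
    rss <- sum(res$fvec^2)
    if (is.null(best) || rss < best$rss)
      best <- list(par = res$par, rss = rss)
  }
  best
}

#' Fit and rank degree-distribution models
#'
#' Fits the cumulative degree distribution by nonlinear least squares under
#' three candidate models -- exponential `P(k) ~ exp(-gamma k)`, power law
#' `P(k) ~ k^-gamma`, and truncated power law `P(k) ~ k^-gamma exp(-k/kx)` --
#' and ranks them by the small-sample Akaike criterion
#' `AICc = n ln(RSS/n) + 2K + 2K(K+1)/(n-K-1)` computed from the Gaussian
#' residual likelihood.  Observations are the distinct-degree support points
#' of the cumulative distribution.  Degree-0 support points are dropped
#' before fitting (the power-law forms are undefined at k = 0).
#'
#' @param dist data.frame as returned by [cumulativeDegreeDistribution()].
#' @param models subset of the three model names to fit.
#' @return data.frame sorted by ascending AICc with columns `model`, `a`,
#'   `gamma`, `kx`, `r2`, `AICc`, `deltaAIC`, `n_points`, `converged`.
#'   Models that fail to converge are flagged (`converged = FALSE`), carry NA
#'   statistics and sort last, with a warning.
#' @export
fitDegreeModels <- function(dist, models = names(.degreeModels)) {
  models <- match.arg(models, names(.degreeModels), several.ok = TRUE)
  stopifnot(all(c("k", "Pk") %in% names(dist)))
  dist <- dist[dist$k > 0, , drop = FALSE]
  if (nrow(dist) < 4L)
    stop("need at least 4 distinct positive degrees to fit; got ", nrow(dist))
  if (any(dist$Pk <= 0)) stop("P(k) must be positive")
  n <- nrow(dist)
  rows <- lapply(models, function(mn) {
    m <- .degreeModels[[mn]]
    fit <- .fitDegreeModel(m, dist$k, dist$Pk)
    out <- data.frame(model = mn, a = NA_real_, gamma = NA_real_,
                      kx = NA_real_, r2 = NA_real_, AICc = NA_real_,
                      n_points = n, converged = FALSE,
                      stringsAsFactors = FALSE)
    if (is.null(fit)) return(out)
    co <- fit$par
    rss <- fit$rss
    tss <- sum((dist$Pk - mean(dist$Pk))^2)
    K <- m$K
    out$a <- unname(co["a"])
    out$gamma <- unname(co["gamma"])
    out$kx <- if ("kx" %in% names(co)) unname(co["kx"]) else NA_real_
    out$r2 <- 1 - rss / tss
    out$AICc <- if (n > K + 1)
      n * log(rss / n) + 2 * K + 2 * K * (K + 1) / (n - K - 1)
    else NA_real_
    out$converged <- TRUE
    out
  })
  res <- do.call(rbind, rows)
  if (any(!res$converged))
    warning("model(s) failed to converge and were excluded from ranking: ",
            paste(res$model[!res$converged], collapse = ", "))
  res <- res[order(is.na(res$AICc), res$AICc), , drop = FALSE]
  res$deltaAIC <- res$AICc - min(res$AICc, na.rm = TRUE)
  if (any(!is.na(res$AICc)))
    res$deltaAIC[which.min(res$AICc)] <- 0  # exact fits give AICc = -Inf
  rownames(res) <- NULL
  res
}
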