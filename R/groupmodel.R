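# Directed group (block) model: species are partitioned into g groups and
# every ordered group pair (k, l) gets its own Bernoulli link probability
# p_kl = L_kl / N_kl (links from consumers in k to resources in l over
# N_kl = n_k * n_l ordered cells, diagonal self-cells included, consistent
# with the S^2 potential-link convention).  Partitions are scored by the
# Bernoulli log-likelihood and AIC and searched by simulated annealing.

# Log-likelihood contribution of blocks with link counts L and cell counts N
# at the MLE p = L/N, with 0 ln 0 := 0.
.blockLoglik <- function(L, N) {
  p <- ifelse(N > 0, L / N, 0)
  t1 <- ifelse(L > 0, L * log(p), 0)
  t2 <- ifelse(N - L > 0, (N - L) * log(1 - p), 0)
  sum(t1 + t2)
}

.checkPartition <- function(partition, labels, g = NULL) {
  n <- length(labels)
  if (is.factor(partition)) partition <- as.integer(partition)
  if (!is.null(names(partition))) {
    if (!setequal(names(partition), labels))
      stop("partition names do not match the web's species labels")
    partition <- partition[labels]
  }
  if (length(partition) != n)
    stop("partition must assign every species to a group")
  partition <- as.integer(partition)
  if (is.null(g)) g <- max(partition)
  if (any(partition < 1L | partition > g))
    stop("group indices must lie in 1..g")
  if (any(tabulate(partition, g) == 0L))
    stop("empty group in partition (groups must be 1..g, all non-empty)")
  list(partition = partition, g = as.integer(g))
}

#' Group-model likelihood and AIC for a fixed partition
#'
#' Evaluates the directed block model at a given partition: block link counts
#' `L_kl`, maximum-likelihood probabilities `p_kl = L_kl / N_kl`, Bernoulli
#' log-likelihood, and `AIC = -2 loglik + 2 nParams`.
#'
#' @param web a [FoodWeb-class].
#' @param partition integer (or factor) group index per species, optionally
#'   named by label; groups must be 1..g with no empty group.
#' @param paramCount `"blocks"` counts the g^2 block probabilities as model
#'   parameters (the convention used throughout the package); the
#'   `"blocks_plus_assign"` alternative additionally counts the S group
#'   memberships.
#' @return a [GroupModelResult-class].
#' @examples
#' fw <- generateWeb(S = 30, nGroups = 3, seed = 2)
#' groupLoglikAic(fw, plantedGroups(fw))
#' @export
setMethod("groupLoglikAic", "FoodWeb",
          function(web, partition,
                   paramCount = c("blocks", "blocks_plus_assign")) {
  paramCount <- match.arg(paramCount)
  a <- web@adj
  labels <- rownames(a)
  pp <- .checkPartition(partition, labels)
  grp <- pp$partition; g <- pp$g
  z <- matrix(0, nrow(a), g)
  z[cbind(seq_len(nrow(a)), grp)] <- 1
  L <- t(z) %*% a %*% z
  nk <- tabulate(grp, g)
  N <- outer(nk, nk)
  ll <- .blockLoglik(L, N)
  nPar <- if (paramCount == "blocks") g^2 else g^2 + nrow(a)
  names(grp) <- labels
  new("GroupModelResult", partition = grp, g = g,
      pkl = ifelse(N > 0, L / N, 0), loglik = ll, nParams = as.integer(nPar),
      aic = -2 * ll + 2 * nPar, seed = NA_integer_, restarts = NA_integer_)
})

# Incremental annealing state: grp, nk, L (g x g block link counts),
# R[i, l] = out-links of species i into group l, Cin[i, k] = in-links of
# species i from group k.  Moving species s from group a to group b touches
# only block rows/columns a and b, so the log-likelihood delta is O(g).
.moveDelta <- function(state, A, s, b) {
  g <- state$g
  a <- state$grp[s]
  d <- A[s, s]
  ea <- rep(0, g); ea[a] <- d
  rowTo <- state$R[s, ] - ea       # out-links of s, excluding the self-loop
  colFrom <- state$Cin[s, ] - ea   # in-links of s, excluding the self-loop
  L2 <- state$L
  L2[a, ] <- L2[a, ] - rowTo; L2[b, ] <- L2[b, ] + rowTo
  L2[, a] <- L2[, a] - colFrom; L2[, b] <- L2[, b] + colFrom
  L2[a, a] <- L2[a, a] - d; L2[b, b] <- L2[b, b] + d
  nk2 <- state$nk
  nk2[a] <- nk2[a] - 1L; nk2[b] <- nk2[b] + 1L
  # blocks whose L or N changed: rows/cols a and b (each cell exactly once)
  others <- seq_len(g)[-c(a, b)]
  idx <- rbind(
    cbind(rep(c(a, b), each = g), rep(seq_len(g), 2L)),
    cbind(rep(others, 2L), rep(c(a, b), each = length(others))))
  Nold <- outer(state$nk, state$nk)[idx]
  Nnew <- outer(nk2, nk2)[idx]
  dll <- .blockLoglik(L2[idx], Nnew) - .blockLoglik(state$L[idx], Nold)
  list(dll = dll, L = L2, nk = nk2)
}

.applyMove <- function(state, A, s, b, delta) {
  a <- state$grp[s]
  state$grp[s] <- b
  state$nk <- delta$nk
  state$L <- delta$L
  state$R[, a] <- state$R[, a] - A[, s]
  state$R[, b] <- state$R[, b] + A[, s]
  state$Cin[, a] <- state$Cin[, a] - A[s, ]
  state$Cin[, b] <- state$Cin[, b] + A[s, ]
  state
}

.initState <- function(A, grp, g) {
  z <- matrix(0, nrow(A), g)
  z[cbind(seq_len(nrow(A)), grp)] <- 1
  list(grp = grp, g = g, nk = tabulate(grp, g),
       L = t(z) %*% A %*% z, R = A %*% z, Cin = t(A) %*% z)
}

.stateLoglik <- function(state) {
  .blockLoglik(state$L, outer(state$nk, state$nk))
}

# One annealing restart.  Returns list(grp, loglik).
.annealOnce <- function(A, g, coolingFactor, stepsPerLevel, maxLevels,
                        initTemp, minTempFrac) {
  n <- nrow(A)
  # random initial partition with no empty group
  grp <- c(seq_len(g), sample.int(g, n - g, replace = TRUE))[sample.int(n)]
  state <- .initState(A, as.integer(grp), g)
  ll <- .stateLoglik(state)
  # calibrate the initial temperature so ~50% of uphill moves accept
  if (is.null(initTemp)) {
    ups <- numeric(0)
    for (i in seq_len(100L)) {
      s <- sample.int(n, 1L)
      b <- sample.int(g, 1L)
      if (b == state$grp[s] || state$nk[state$grp[s]] == 1L) next
      dAic <- -2 * .moveDelta(state, A, s, b)$dll
      if (dAic > 0) ups <- c(ups, dAic)
    }
    initTemp <- if (length(ups)) stats::median(ups) / log(2) else 1
  }
  temp <- initTemp
  minTemp <- initTemp * minTempFrac
  best <- list(grp = state$grp, loglik = ll)
  level <- 0L
  while (temp > minTemp && level < maxLevels) {
    level <- level + 1L
    for (i in seq_len(stepsPerLevel)) {
      s <- sample.int(n, 1L)
      b <- sample.int(g, 1L)
      if (b == state$grp[s] || state$nk[state$grp[s]] == 1L) next
      delta <- .moveDelta(state, A, s, b)
      dAic <- -2 * delta$dll
      if (dAic <= 0 || stats::runif(1) < exp(-dAic / temp)) {
        state <- .applyMove(state, A, s, b, delta)
        ll <- ll + delta$dll
        if (ll > best$loglik) best <- list(grp = state$grp, loglik = ll)
      }
    }
    temp <- temp * coolingFactor
  }
  # greedy polish: accept only strictly improving single-species moves
  state <- .initState(A, best$grp, g)
  ll <- best$loglik
  improved <- TRUE
  while (improved) {
    improved <- FALSE
    for (s in seq_len(n)) {
      if (state$nk[state$grp[s]] == 1L) next
      for (b in seq_len(g)) {
        if (b == state$grp[s]) next
        delta <- .moveDelta(state, A, s, b)
        if (delta$dll > 1e-12) {
          state <- .applyMove(state, A, s, b, delta)
          ll <- ll + delta$dll
          improved <- TRUE
        }
      }
    }
  }
  list(grp = state$grp, loglik = .stateLoglik(state))
}

#' Search partitions by simulated annealing
#'
#' Minimises the group-model AIC over partitions into `g` groups.  Proposals
#' move one uniformly chosen species to a uniformly chosen different group
#' (moves that would empty a group are rejected); a proposal is accepted if
#' it does not increase the AIC, and otherwise with probability
#' `exp(-deltaAIC / temp)`.  The temperature starts at a value calibrated so
#' that about half of the uphill moves on a 100-proposal prefix would be
#' accepted, and cools geometrically; each restart ends with a greedy descent
#' to the nearest local optimum.  The best partition over all restarts is
#' returned; the whole search is reproducible from `seed`.
#'
#' @param web a [FoodWeb-class].
#' @param g number of groups (1..S).
#' @param restarts independent annealing restarts.
#' @param coolingFactor geometric cooling factor per temperature level.
#' @param stepsPerLevel proposals per temperature level (default: S).
#' @param maxLevels cap on the number of temperature levels.
#' @param initTemp starting temperature (default: auto-calibrated).
#' @param minTempFrac stop when the temperature falls below this fraction of
#'   the starting temperature.
#' @param seed integer RNG seed.
#' @param paramCount AIC parameter-count convention, see [groupLoglikAic()].
#' @return a [GroupModelResult-class] for the best partition found.
#' @export
setMethod("annealPartition", "FoodWeb",
          function(web, g, restarts = 10L, coolingFactor = 0.995,
                   stepsPerLevel = NULL, maxLevels = 400L, initTemp = NULL,
                   minTempFrac = 1e-3, seed = 1L,
                   paramCount = c("blocks", "blocks_plus_assign")) {
  paramCount <- match.arg(paramCount)
  A <- web@adj
  n <- nrow(A)
  g <- as.integer(g)
  if (g < 1L || g > n) stop("g must lie in 1..S")
  if (is.null(stepsPerLevel)) stepsPerLevel <- n
  if (g == 1L) {
    res <- groupLoglikAic(web, rep(1L, n), paramCount = paramCount)
    res@seed <- as.integer(seed); res@restarts <- as.integer(restarts)
    return(res)
  }
  old <- .saveSeed(); on.exit(.restoreSeed(old))
  set.seed(as.integer(seed))
  best <- NULL
  for (r in seq_len(restarts)) {
    cand <- .annealOnce(A, g, coolingFactor, stepsPerLevel, maxLevels,
                        initTemp, minTempFrac)
    if (is.null(best) || cand$loglik > best$loglik) best <- cand
  }
  res <- groupLoglikAic(web, best$grp, paramCount = paramCount)
  res@seed <- as.integer(seed)
  res@restarts <- as.integer(restarts)
  res
})

#' Scan the number of groups
#'
#' Runs [annealPartition()] for every g in `gRange` and selects the g with
#' the minimum AIC.
#'
#' @param web a [FoodWeb-class].
#' @param gRange integer vector of group numbers to try.
#' @param restarts,seed,... passed to [annealPartition()]; per-g seeds are
#'   derived reproducibly from `seed`.
#' @return list with elements `bestG`, `best` (the winning
#'   [GroupModelResult-class]), `scan` (data.frame g, loglik, aic, seed) and
#'   `results` (all per-g results).
#' @export
setMethod("scanGroupSizes", "FoodWeb",
          function(web, gRange, restarts = 10L, seed = 1L, ...) {
  gRange <- as.integer(gRange)
  if (any(gRange < 1L | gRange > nSpecies(web)))
    stop("gRange must lie within 1..S")
  seeds <- .derivedSeeds(seed, length(gRange))
  results <- vector("list", length(gRange))
  for (i in seq_along(gRange))
    results[[i]] <- annealPartition(web, gRange[i], restarts = restarts,
                                    seed = seeds[i], ...)
  scan <- data.frame(g = gRange,
                     loglik = vapply(results, slot, numeric(1), "loglik"),
                     aic = vapply(results, slot, numeric(1), "aic"),
                     seed = seeds)
  bestIdx <- which.min(scan$aic)
  list(bestG = gRange[bestIdx], best = results[[bestIdx]], scan = scan,
       results = results)
})
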