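# Independent brute-force oracles (no igraph, no package internals).

# All-pairs shortest-path distances on a symmetric 0/1 matrix by BFS.
bfsDistances <- function(sym) {
  n <- nrow(sym)
  d <- matrix(Inf, n, n)
  for (s in seq_len(n)) {
    d[s, s] <- 0
    frontier <- s
    depth <- 0
    while (length(frontier)) {
      depth <- depth + 1
      nxt <- unique(unlist(lapply(frontier, function(v) which(sym[v, ] == 1))))
      nxt <- nxt[d[s, nxt] == Inf]
      d[s, nxt] <- depth
      frontier <- nxt
    }
  }
  d
}

# Enumerate every shortest path between every unordered pair by recursive
# backtracking over the BFS distance field; credit interior vertices
# fractionally.  Exponential, only for tiny graphs.
bruteBetweenness <- function(sym) {
  n <- nrow(sym)
  d <- bfsDistances(sym)
  btw <- numeric(n)
  pathsTo <- function(s, t) {
    # all shortest s->t paths as vectors of vertices
    if (s == t) return(list(s))
    preds <- which(sym[, t] == 1 & d[s, ] == d[s, t] - 1)
    out <- list()
    for (p in preds)
      for (pp in pathsTo(s, p)) out[[length(out) + 1]] <- c(pp, t)
    out
  }
  for (s in seq_len(n - 1)) for (t in (s + 1):n) {
    if (!is.finite(d[s, t])) next
    paths <- pathsTo(s, t)
    for (pth in paths) {
      interior <- setdiff(pth, c(s, t))
      btw[interior] <- btw[interior] + 1 / length(paths)
    }
  }
  btw
}

# Closeness as (n_reachable - 1) / sum of distances to reachable vertices,
# rescaled by component share to match the per-component convention.
bruteCloseness <- function(sym) {
  d <- bfsDistances(sym)
  n <- nrow(sym)
  vapply(seq_len(n), function(i) {
    reach <- which(is.finite(d[i, ]) & seq_len(n) != i)
    if (!length(reach)) return(0)
    length(reach) / sum(d[i, reach])
  }, numeric(1))
}
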