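# Web constructors used across the suite.

labelled <- function(a, prefix = "s") {
  labs <- sprintf("%s%02d", prefix, seq_len(nrow(a)))
  dimnames(a) <- list(labs, labs)
  a
}

randomWeb <- function(n, p = 0.2, seed = 1) {
  set.seed(seed)
  FoodWeb(labelled(matrix(rbinom(n * n, 1, p), n, n)))
}

# Perfectly nested staircase: consumer i eats resources 1..i.
staircaseWeb <- function(n) {
  a <- matrix(0L, n, n)
  for (i in seq_len(n)) a[i, 1:i] <- 1L
  FoodWeb(labelled(a))
}

# Hub (species 1) eats the other n-1 species.
starWeb <- function(nLeaves = 4) {
  a <- matrix(0L, nLeaves + 1, nLeaves + 1)
  a[1, -1] <- 1L
  FoodWeb(labelled(a))
}

# Undirected path graph encoded as a directed web (i eats i+1).
pathWeb <- function(n = 3) {
  a <- matrix(0L, n, n)
  for (i in seq_len(n - 1)) a[i, i + 1] <- 1L
  FoodWeb(labelled(a))
}

# Ideal core/periphery: core clique, all core-periphery links, no
# periphery-periphery links.
idealCorePeriphery <- function(nCore = 4, nPeriph = 8) {
  n <- nCore + nPeriph
  a <- matrix(0L, n, n)
  a[1:nCore, 1:nCore] <- 1L
  diag(a) <- 0L
  a[1:nCore, (nCore + 1):n] <- 1L
  FoodWeb(labelled(a))
}

# Web with an exact number of links, for reconstructing published summary
# statistics from printed (S, Lo) counts.
webWithCounts <- function(S, Lo, seed = 1) {
  set.seed(seed)
  a <- matrix(0L, S, S)
  a[sample.int(S * S, Lo)] <- 1L
  FoodWeb(labelled(a))
}

# Build a parasite records object from a compact stage list:
# stages = list(c("h1", "h2"), ...), transmissions aligned with stages.
makeRecord <- function(parasite, stages, transmission = NULL) {
  m <- length(stages)
  if (is.null(transmission))
    transmission <- c("direct", rep("trophic", m - 1))
  data.frame(parasite = parasite, stage_index = seq_len(m),
             stage_role = c(rep("intermediate", m - 1), "definitive"),
             transmission = transmission,
             hosts = vapply(stages, paste, character(1), collapse = ";"),
             source = "literature", stringsAsFactors = FALSE)
}

makeRecords <- function(...) parasiteRecords(do.call(rbind, list(...)))
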